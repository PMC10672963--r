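#' Extract the active subnetwork around a metabolite
#'
#' Breadth-first traversal of the flux-carrying directed network, starting
#' from one metabolite. Reaction direction is the sign of its flux in the
#' supplied state. For a production pathway the traversal runs backwards
#' (reactions producing the metabolite, then reactions producing their
#' substrates, ...); for a consumption pathway it runs forwards. Distance is
#' counted in reaction steps. For non-cofactor target metabolites, edges
#' through cofactor metabolites are not traversed, which prevents spurious
#' connections through shared currency pools; when the target itself is a
#' cofactor only the target is exempt from stripping.
#'
#' @param model A [flux_model()] (cofactors flagged via [flag_cofactors()]).
#' @param state A `flux_state` from [solve_flux_state()].
#' @param metabolite_id Target metabolite id.
#' @param direction `"production"` or `"consumption"`.
#' @param D Traversal depth in reaction steps (>= 1). Default 3.
#' @param tolerance Activity threshold on `|v|`; defaults to the state's
#'   `zero_tolerance`.
#' @return A `subnetwork` object: `metabolite_id`, `direction`, `distance`,
#'   `reaction_ids`, `sub_flux` (named), `boundary` (tibble, filled by
#'   [close_mass_balance()]), `closed` flag.
#' @export
extract_subnetwork <- function(model, state, metabolite_id,
                               direction = c("production", "consumption"),
                               D = 3, tolerance = state$zero_tolerance) {
  stopifnot(inherits(model, "flux_model"), inherits(state, "flux_state"))
  direction <- match.arg(direction)
  if (!metabolite_id %in% model$metabolites$id)
    stopf("metabolite '%s' not in model", metabolite_id)
  if (!is.numeric(D) || D < 1) stopf("D must be a positive integer")

  active <- active_reactions(state, tolerance)
  Sa <- model$S[, active, drop = FALSE]
  sgn <- sign(state$v[active])
  # oriented stoichiometry: positive entry = net production under the flux
  So <- Sa %*% Matrix::Diagonal(x = sgn)
  colnames(So) <- active

  cof <- model$metabolites$is_cofactor
  names(cof) <- model$metabolites$id
  cof[metabolite_id] <- FALSE  # target always traversable

  visited_m <- character(0)
  frontier <- metabolite_id
  reached <- character(0)
  for (level in seq_len(D)) {
    if (!length(frontier)) break
    rows <- So[frontier, , drop = FALSE]
    # reactions producing (production) / consuming (consumption) a frontier met
    hit <- if (direction == "production") {
      colnames(So)[Matrix::colSums(rows > 1e-12) > 0]
    } else {
      colnames(So)[Matrix::colSums(rows < -1e-12) > 0]
    }
    new_r <- setdiff(hit, reached)
    reached <- c(reached, new_r)
    visited_m <- c(visited_m, frontier)
    if (!length(new_r)) break
    cols <- So[, new_r, drop = FALSE]
    # next frontier: substrates of the new reactions (production) or their
    # products (consumption), excluding cofactors and already-visited mets
    nxt <- if (direction == "production") {
      rownames(cols)[Matrix::rowSums(cols < -1e-12) > 0]
    } else {
      rownames(cols)[Matrix::rowSums(cols > 1e-12) > 0]
    }
    frontier <- setdiff(nxt[!cof[nxt]], visited_m)
  }

  # keep model reaction order for determinism
  reached <- model$reactions$id[model$reactions$id %in% reached]
  if (!length(reached))
    inform(sprintf("no active %s reactions within distance %d of '%s'; pathway undefined for this condition",
                   direction, D, metabolite_id))
  structure(
    list(metabolite_id = metabolite_id, direction = direction, distance = D,
         condition_name = state$condition_name,
         reaction_ids = reached,
         sub_flux = state$v[reached],
         boundary = tibble::tibble(reaction_id = character(),
                                   metabolite_id = character(),
                                   coefficient = numeric(), flux = numeric()),
         closed = FALSE),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %s (%s, D=%d): %d reactions, %d boundary, %s\n",
              x$metabolite_id, x$direction, x$distance, length(x$reaction_ids),
              nrow(x$boundary), if (x$closed) "closed" else "open"))
  invisible(x)
}

# Internal stoichiometric rows of a subnetwork: non-cofactor metabolites
# touched by its reactions, plus the target even when it is a cofactor.
# Cofactor species are removed from the subnetwork entirely, consistent
# with their removal before traversal.
subnetwork_mets <- function(sub, model) {
  if (!length(sub$reaction_ids)) return(character(0))
  Ssub <- model$S[, sub$reaction_ids, drop = FALSE]
  touched <- rownames(Ssub)[Matrix::rowSums(Ssub != 0) > 0]
  cof <- setNames(model$metabolites$is_cofactor, model$metabolites$id)
  cof[sub$metabolite_id] <- FALSE
  touched[!cof[touched]]
}

#' Close a subnetwork to mass balance
#'
#' For every internal metabolite with nonzero net production or consumption
#' under the subnetwork fluxes, adds a synthetic boundary reaction carrying
#' exactly the imbalance, so that the closed subnetwork satisfies
#' `S_sub v_sub = 0`. Boundary reaction ids are prefixed `"BND_"` and are
#' disjoint from model reaction ids.
#'
#' @param sub A `subnetwork` from [extract_subnetwork()].
#' @param model The parent [flux_model()].
#' @param tol Imbalances below this magnitude are ignored (default 1e-9).
#' @return The subnetwork with its `boundary` table filled and `closed = TRUE`.
#' @export
close_mass_balance <- function(sub, model, tol = 1e-9) {
  stopifnot(inherits(sub, "subnetwork"))
  if (!length(sub$reaction_ids)) stopf("cannot close an empty subnetwork")
  mets <- subnetwork_mets(sub, model)
  Ssub <- model$S[mets, sub$reaction_ids, drop = FALSE]
  imb <- as.numeric(Ssub %*% sub$sub_flux)
  names(imb) <- mets

  rows <- purrr::map(mets[abs(imb) > tol], function(m) {
    b <- imb[[m]]
    # net production (b > 0) needs a drain (coefficient -1, flux b);
    # net consumption needs a supply (+1, flux -b)
    tibble::tibble(
      reaction_id = sprintf("BND_%s_%s", m, if (b > 0) "out" else "in"),
      metabolite_id = m,
      coefficient = if (b > 0) -1 else 1,
      flux = abs(b)
    )
  })
  sub$boundary <- dplyr::bind_rows(rows)
  if (nrow(sub$boundary) == 0)
    sub$boundary <- tibble::tibble(reaction_id = character(),
                                   metabolite_id = character(),
                                   coefficient = numeric(), flux = numeric())
  sub$closed <- TRUE
  sub
}

# Dense stoichiometric matrix of a closed subnetwork (internal mets x
# [model reactions + boundary reactions]) and its flux vector.
closed_matrix <- function(sub, model) {
  mets <- subnetwork_mets(sub, model)
  M <- as.matrix(model$S[mets, sub$reaction_ids, drop = FALSE])
  if (nrow(sub$boundary)) {
    B <- matrix(0, length(mets), nrow(sub$boundary),
                dimnames = list(mets, sub$boundary$reaction_id))
    for (k in seq_len(nrow(sub$boundary)))
      B[sub$boundary$metabolite_id[k], k] <- sub$boundary$coefficient[k]
    M <- cbind(M, B)
  }
  list(M = M,
       flux = c(sub$sub_flux, setNames(sub$boundary$flux, sub$boundary$reaction_id)),
       is_boundary = c(rep(FALSE, length(sub$reaction_ids)),
                       rep(TRUE, nrow(sub$boundary))))
}
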