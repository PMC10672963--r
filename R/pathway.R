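#' Assemble a weighted metabolite pathway from elementary modes
#'
#' Keeps only the modes in which the target metabolite is actually produced
#' (for a production pathway) or consumed (for a consumption pathway) by a
#' model reaction, sums their weighted flux patterns, drops the synthetic
#' boundary reactions, folds the direction-split columns back onto signed
#' model reactions, and normalizes the resulting flux contributions to sum
#' to one. The weights are thus the relative flux contribution of each
#' reaction to the metabolite's production or consumption in the estimated
#' flux state.
#'
#' @param modes List of `elementary_mode`s from
#'   [decompose_elementary_modes()].
#' @param sub The closed `subnetwork` the modes were computed on.
#' @param model The parent [flux_model()].
#' @return A `met_pathway`: `metabolite_id`, `direction`, `condition`,
#'   `distance`, and `weights` (tibble `reaction_id`, `weight`, summing to 1).
#' @export
assemble_pathway <- function(modes, sub, model) {
  stopifnot(inherits(sub, "subnetwork"))
  target <- sub$metabolite_id
  coeffs <- setNames(numeric(length(sub$reaction_ids)), sub$reaction_ids)
  st_col <- model$S[target, sub$reaction_ids, drop = FALSE]
  coeffs[] <- as.numeric(st_col)

  kept_total <- setNames(numeric(length(sub$reaction_ids)), sub$reaction_ids)
  n_kept <- 0L
  for (m in modes) {
    ids <- names(m$support)
    model_ids <- ids[!startsWith(ids, "BND_")]
    if (!length(model_ids)) next
    # oriented target coefficient of each split column
    ctgt <- coeffs[model_ids] * m$split_sign[model_ids]
    touches <- if (sub$direction == "production") {
      any(ctgt > 1e-12 & m$support[model_ids] > 0)
    } else {
      any(ctgt < -1e-12 & m$support[model_ids] > 0)
    }
    if (!touches) next
    n_kept <- n_kept + 1L
    kept_total[model_ids] <- kept_total[model_ids] + m$weight * m$support[model_ids]
  }

  w <- kept_total[kept_total > 1e-12]
  if (!length(w)) {
    inform(sprintf("no elementary mode contributes to %s of '%s'; empty pathway",
                   sub$direction, target))
    weights <- tibble::tibble(reaction_id = character(), weight = numeric())
  } else {
    w <- w / sum(w)
    weights <- tibble::tibble(reaction_id = names(w), weight = unname(w)) %>%
      dplyr::arrange(.data$reaction_id)
  }
  structure(
    list(metabolite_id = target, direction = sub$direction,
         condition = sub$condition_name, distance = sub$distance,
         weights = weights, n_modes = n_kept,
         provenance = sub$condition_name),
    class = "met_pathway"
  )
}

#' Extract one weighted production or consumption pathway
#'
#' Convenience wrapper chaining [extract_subnetwork()],
#' [close_mass_balance()], [decompose_elementary_modes()] and
#' [assemble_pathway()].
#'
#' @inheritParams extract_subnetwork
#' @param tol Decomposition residual tolerance.
#' @return A `met_pathway`.
#' @export
extract_pathway <- function(model, state, metabolite_id,
                            direction = c("production", "consumption"),
                            D = 3, tolerance = state$zero_tolerance,
                            tol = 1e-8) {
  direction <- match.arg(direction)
  sub <- extract_subnetwork(model, state, metabolite_id, direction, D, tolerance)
  if (!length(sub$reaction_ids)) {
    return(structure(
      list(metabolite_id = metabolite_id, direction = direction,
           condition = state$condition_name, distance = D,
           weights = tibble::tibble(reaction_id = character(), weight = numeric()),
           n_modes = 0L, provenance = state$condition_name),
      class = "met_pathway"))
  }
  sub <- close_mass_balance(sub, model)
  modes <- decompose_elementary_modes(sub, model, tol = tol)
  assemble_pathway(modes, sub, model)
}

#' Extract pathways for many metabolites at once
#'
#' @inheritParams extract_pathway
#' @param metabolites Metabolite ids; defaults to all non-cofactor
#'   metabolites that touch at least one active reaction.
#' @param directions One or both of `"production"`, `"consumption"`.
#' @return A named list of `met_pathway` objects (empty pathways omitted),
#'   names `"<metabolite>|<direction>"`.
#' @export
extract_pathways <- function(model, state, metabolites = NULL,
                             directions = c("production", "consumption"),
                             D = 3, tolerance = state$zero_tolerance) {
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.null(metabolites)) {
    act <- active_reactions(state, tolerance)
    touched <- rownames(model$S)[Matrix::rowSums(model$S[, act, drop = FALSE] != 0) > 0]
    metabolites <- setdiff(touched,
                           model$metabolites$id[model$metabolites$is_cofactor])
  }
  out <- list()
  for (m in metabolites) {
    for (d in directions) {
      p <- suppressMessages(extract_pathway(model, state, m, d, D, tolerance))
      if (nrow(p$weights)) out[[paste(m, d, sep = "|")]] <- p
    }
  }
  out
}

#' @export
print.met_pathway <- function(x, ...) {
  cat(sprintf("<met_pathway> %s %s (D=%d, condition %s): %d reactions\n",
              x$metabolite_id, x$direction, x$distance,
              paste(x$provenance, collapse = "+"), nrow(x$weights)))
  if (nrow(x$weights))
    print(utils::head(dplyr::arrange(x$weights, dplyr::desc(.data$weight)), 10))
  invisible(x)
}

#' Flatten pathways into a tibble
#'
#' @param pathways A `met_pathway` or list thereof.
#' @return Tibble with columns `metabolite_id`, `direction`, `reaction_id`,
#'   `weight`, `condition`.
#' @export
pathways_table <- function(pathways) {
  if (inherits(pathways, "met_pathway")) pathways <- list(pathways)
  dplyr::bind_rows(purrr::map(pathways, function(p) {
    if (!nrow(p$weights)) return(NULL)
    tibble::tibble(metabolite_id = p$metabolite_id, direction = p$direction,
                   reaction_id = p$weights$reaction_id,
                   weight = p$weights$weight,
                   condition = paste(p$provenance, collapse = ";"))
  }))
}

#' @export
tidy.met_pathway <- function(x, ...) pathways_table(x)

#' @export
glance.met_pathway <- function(x, ...) {
  tibble::tibble(metabolite_id = x$metabolite_id, direction = x$direction,
                 distance = x$distance, n_reactions = nrow(x$weights),
                 n_modes = x$n_modes,
                 weight_sum = sum(x$weights$weight))
}
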