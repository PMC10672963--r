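#' Estimate a condition-specific flux state
#'
#' Solves the flux balance problem with a quadratic flux-length penalty:
#' maximize `c'v - F_scale * ||v||^2` subject to `S v = 0` and the reaction
#' bounds. The penalty (default weight 1e-6) selects, among alternate linear
#' optima, the flux vector of minimal Euclidean length -- the parsimonious
#' state a cell would realize with the least enzyme expenditure -- and makes
#' the optimum unique on the bounded feasible set.
#'
#' When the condition's growth constraint has type `"max_capacity"`, the
#' biomass flux is first maximized, fixed as a lower bound (with a small
#' numerical slack), and only then is the stated objective solved.
#'
#' @param problem A `flux_problem` from [apply_condition()].
#' @param zero_tolerance Flux magnitude below which a reaction is considered
#'   inactive (default `1e-9`); recorded in the result for
#'   [active_reactions()].
#' @return A `flux_state` object: `v` (named flux vector, mmol/gDW/h),
#'   `objective_value` (`c'v - F||v||^2`), `condition_name`,
#'   `zero_tolerance`.
#' @export
solve_flux_state <- function(problem, zero_tolerance = 1e-9) {
  stopifnot(inherits(problem, "flux_problem"))
  model <- problem$model
  g <- problem$condition$growth

  if (!is.null(g) && g$type == "max_capacity") {
    cbio <- setNames(numeric(nrow(model$reactions)), model$reactions$id)
    if (!g$reaction %in% names(cbio))
      stopf("growth reaction '%s' not in model", g$reaction)
    cbio[g$reaction] <- 1
    v1 <- solve_qp_fba(model, cbio, problem$F_scale)
    vmax <- v1[g$reaction]
    j <- match(g$reaction, model$reactions$id)
    # impose the achieved maximum as a minimum, with slack for solver noise
    model$reactions$lower_bound[j] <- vmax - 1e-6 * max(1, abs(vmax))
  }

  v <- solve_qp_fba(model, problem$c, problem$F_scale)
  obj <- sum(problem$c * v) - problem$F_scale * sum(v^2)
  structure(
    list(v = v, objective_value = obj,
         condition_name = problem$condition$name,
         zero_tolerance = zero_tolerance),
    class = "flux_state"
  )
}

# Core QP solve via the package's ADMM solver (see qp-solver.R).
solve_qp_fba <- function(model, cvec, F_scale) {
  lb <- pmax(model$reactions$lower_bound, -BIG_BOUND)
  ub <- pmin(model$reactions$upper_bound, BIG_BOUND)
  if (any(lb > ub)) {
    j <- which(lb > ub)[1]
    stopf("infeasible bounds on reaction '%s' (lower %g > upper %g)",
          model$reactions$id[j], model$reactions$lower_bound[j],
          model$reactions$upper_bound[j])
  }
  S <- as.matrix(model$S)
  res <- qp_flux(S, lb, ub, cvec, F_scale)
  if (!res$converged)
    stopf("flux solver did not converge; the problem may be infeasible (check exchange bounds and growth constraints)")
  v <- setNames(res$x, model$reactions$id)

  resid <- max(abs(S %*% v))
  if (!is.finite(resid) || resid > 1e-6)
    stopf("solver failed to reach steady state (||S v||_inf = %.3g); check exchange bounds", resid)
  btol <- 1e-6 * max(1, max(abs(c(lb, ub))))
  if (any(v < lb - btol) || any(v > ub + btol))
    stopf("solver returned fluxes outside bounds; flux problem is likely infeasible")
  # With all-infinite exchange bounds the penalty caps |v| near |c|/(2F);
  # hitting that cap means the linear program is effectively unbounded.
  cap <- max(abs(cvec)) / (2 * F_scale)
  if (cap > BIG_BOUND && max(abs(v)) > 0.5 * cap)
    stopf("flux problem appears unbounded; add finite bounds on exchange reactions")
  v
}

#' Reactions carrying flux in a flux state
#'
#' @param state A `flux_state`.
#' @param tolerance Positive threshold on `|v|`; defaults to the state's
#'   `zero_tolerance`.
#' @return Character vector of reaction ids with `|v| >` tolerance.
#' @export
active_reactions <- function(state, tolerance = state$zero_tolerance) {
  stopifnot(inherits(state, "flux_state"), tolerance > 0)
  names(state$v)[abs(state$v) > tolerance]
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> %s: %d/%d reactions active, objective %.6g\n",
              x$condition_name, length(active_reactions(x)), length(x$v),
              x$objective_value))
  invisible(x)
}

#' Tidy a flux state into a tibble
#'
#' @param x A `flux_state`.
#' @param ... Unused.
#' @return A tibble with columns `reaction_id`, `flux`, `active`.
#' @export
tidy.flux_state <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$v), flux = unname(x$v),
                 active = abs(x$v) > x$zero_tolerance)
}

#' @export
glance.flux_state <- function(x, ...) {
  tibble::tibble(condition = x$condition_name,
                 objective_value = x$objective_value,
                 n_reactions = length(x$v),
                 n_active = length(active_reactions(x)))
}

#' Write a flux state as TSV (reaction_id, flux)
#' @param state A `flux_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(state, path) {
  readr::write_tsv(tidy.flux_state(state)[, c("reaction_id", "flux")], path)
  invisible(path)
}
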