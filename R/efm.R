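#' Decompose a closed subnetwork flux into elementary modes
#'
#' Splits the closed subnetwork by flux sign so all fluxes are non-negative,
#' then repeatedly extracts a support-minimal steady-state mode from within
#' the support of the residual flux and subtracts the largest multiple that
#' keeps the residual non-negative. Each step zeroes at least one reaction,
#' so the loop terminates in at most `|support|` steps, and the weighted
#' modes sum exactly back to the subnetwork flux distribution.
#'
#' Each mode is found by null-space compression: starting from the residual
#' itself (a steady-state vector), the candidate is pushed along directions
#' of the support-restricted null space, zeroing at least one reaction per
#' step while staying non-negative, until the null space restricted to its
#' support is one-dimensional -- at which point the candidate spans it and
#' is support-minimal (any steady-state vector with a strictly smaller
#' support would be a non-proportional null vector, contradicting nullity
#' one). All steps are deterministic (SVD-based null bases, first
#' independent direction, fixed sign convention), so the decomposition is
#' reproducible.
#'
#' @param sub A closed `subnetwork` (see [close_mass_balance()]).
#' @param model The parent [flux_model()].
#' @param tol Residual tolerance (default 1e-8): fluxes below it are treated
#'   as zero, and the final residual must be below it.
#' @return A list of `elementary_mode` objects, each with `support` (named
#'   non-negative coefficients on the direction-split network, boundary
#'   reactions included), `weight` (the subtracted multiple), and
#'   `split_sign` (named signs mapping split columns back to signed model
#'   fluxes).
#' @export
decompose_elementary_modes <- function(sub, model, tol = 1e-8) {
  stopifnot(inherits(sub, "subnetwork"))
  if (!sub$closed) stopf("subnetwork must be closed first (see close_mass_balance)")
  cm <- closed_matrix(sub, model)
  M <- cm$M
  f <- cm$flux

  # direction split: orient every column along its flux
  sgn <- ifelse(f < 0, -1, 1)
  M <- M %*% diag(sgn, length(sgn))
  colnames(M) <- names(f)
  f <- abs(f)

  drop0 <- f <= tol
  if (any(drop0)) {
    M <- M[, !drop0, drop = FALSE]
    f <- f[!drop0]
    sgn <- sgn[!drop0]
  }
  if (!length(f)) return(list())

  modes <- list()
  residual <- f
  eps0 <- 1e-12  # support floor; must stay far below the flux tolerance so
                 # the residual remains an exactly steady-state vector
  for (iter in seq_len(length(f) + 5L)) {
    if (max(residual) <= tol) break
    supp <- which(residual > eps0)

    e <- minimal_mode(M[, supp, drop = FALSE], residual[supp])
    if (is.null(e))
      stopf("failed to extract an elementary mode from the residual flux; subnetwork closure is inconsistent")
    e_full <- setNames(numeric(length(residual)), names(residual))
    e_full[supp] <- e
    on <- e_full > eps0
    lambda <- min(residual[on] / e_full[on])
    modes[[length(modes) + 1L]] <- structure(
      list(support = e_full[on], weight = lambda,
           split_sign = setNames(sgn, names(residual))[on]),
      class = "elementary_mode"
    )
    residual <- residual - lambda * e_full
    residual[abs(residual) < eps0] <- 0  # exact zero for the leaving reaction
    residual[residual < 0] <- 0          # guard against roundoff
  }
  if (max(residual) > tol)
    stopf("elementary-mode decomposition did not terminate (max residual %.3g)",
          max(residual))

  recon <- Reduce(`+`, lapply(modes, function(m) {
    v <- setNames(numeric(length(f)), names(f))
    v[names(m$support)] <- m$weight * m$support
    v
  }), setNames(numeric(length(f)), names(f)))
  if (max(abs(recon - f)) > 1e-8 * max(1, max(f)))
    stopf("elementary-mode decomposition residual %.3g exceeds tolerance; subnetwork not closed?",
          max(abs(recon - f)))
  modes
}

# Support-minimal steady-state mode within the support of a non-negative
# steady-state vector, by null-space compression (see the roxygen block of
# decompose_elementary_modes for why the termination state certifies
# support minimality). Returns a vector on the columns of M, normalized so
# the maximum coefficient is 1, or NULL on numerical failure.
minimal_mode <- function(M, start, tol = 1e-10) {
  k <- ncol(M)
  x <- start / max(start)
  for (guard in seq_len(k + 2L)) {
    J <- which(x > tol)
    if (!length(J)) return(NULL)
    N <- nullspace_of(M[, J, drop = FALSE], 1e-9)
    if (is.null(N)) return(NULL)
    if (ncol(N) == 1L) {
      # x restricted to J spans the null space: elementary mode
      e <- numeric(k)
      e[J] <- x[J] / max(x[J])
      return(e)
    }
    xJ <- x[J]
    # first null direction not proportional to x (Gram-Schmidt against x)
    d <- NULL
    for (cc in seq_len(ncol(N))) {
      cand <- N[, cc] - xJ * sum(xJ * N[, cc]) / sum(xJ * xJ)
      if (max(abs(cand)) > 1e-8) { d <- cand; break }
    }
    if (is.null(d)) {  # numerically proportional basis: accept x as mode
      e <- numeric(k)
      e[J] <- xJ / max(xJ)
      return(e)
    }
    d <- d / max(abs(d))
    if (all(d >= -tol)) d <- -d
    neg <- which(d < -tol)
    step <- min(xJ[neg] / (-d[neg]))
    xJ <- xJ + step * d
    xJ[xJ < tol] <- 0
    x <- numeric(k)
    x[J] <- xJ
  }
  NULL
}

#' Exhaustively enumerate elementary flux modes
#'
#' Brute-force oracle for small (<= ~16 column) non-negative (direction
#' split) networks: for every support subset in increasing size order, the
#' subset is an elementary-mode support iff the restricted stoichiometric
#' matrix has a one-dimensional null space spanned by a strictly
#' sign-uniform, fully supported vector, and no smaller recorded support is
#' contained in it. Intended as an independent test oracle, not for
#' genome-scale use.
#'
#' @param M Dense stoichiometric matrix (internal metabolites x reactions)
#'   of a network in which all reactions are irreversible (flux >= 0).
#' @param tol Numerical tolerance.
#' @return A list of named non-negative vectors (normalized so the maximum
#'   coefficient is 1), one per elementary mode.
#' @export
enumerate_efms <- function(M, tol = 1e-9) {
  n <- ncol(M)
  if (n > 16) stopf("exhaustive enumeration limited to 16 reactions (got %d)", n)
  ids <- colnames(M) %||% as.character(seq_len(n))
  efms <- list()
  supports <- list()
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      J <- combs[, ci]
      if (length(supports) &&
          any(vapply(supports, function(s) all(s %in% J), logical(1)))) next
      NJ <- M[, J, drop = FALSE]
      ns <- nullspace_of(NJ, tol)
      if (is.null(ns) || ncol(ns) != 1L) next
      v <- ns[, 1]
      if (any(abs(v) <= tol)) next            # not fully supported
      if (all(v > 0) || all(v < 0)) {
        v <- abs(v) / max(abs(v))
        efms[[length(efms) + 1L]] <- setNames(v, ids[J])
        supports[[length(supports) + 1L]] <- J
      }
    }
  }
  efms
}

nullspace_of <- function(A, tol = 1e-9) {
  if (nrow(A) == 0) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  null_idx <- which(c(sv$d, rep(0, ncol(A) - length(sv$d))) <= tol * max(1, sv$d[1]))
  if (!length(null_idx)) return(NULL)
  sv$v[, null_idx, drop = FALSE]
}

# Direction-split copy of a model-level stoichiometric matrix for the
# enumeration oracle: reversible reactions contribute a forward and a
# reverse column ("<id>_rev"); reactions bounded negative-only contribute
# the reversed column alone. Cofactor rows may be stripped by the caller.
split_network <- function(model) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cols <- list(); nm <- character(0)
  for (j in seq_len(ncol(S))) {
    if (ub[j] > 0) { cols <- c(cols, list(S[, j])); nm <- c(nm, colnames(S)[j]) }
    if (lb[j] < 0) { cols <- c(cols, list(-S[, j]))
                     nm <- c(nm, paste0(colnames(S)[j], "_rev")) }
  }
  M <- do.call(cbind, cols)
  colnames(M) <- nm
  M
}
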