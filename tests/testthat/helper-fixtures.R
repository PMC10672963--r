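# Shared fixtures and small oracles for the suite.

toy_state <- function(toy, ...) {
  solve_flux_state(apply_condition(toy$model, toy_condition(toy, ...)))
}

closed_sub <- function(model, state, met, dir, D) {
  close_mass_balance(extract_subnetwork(model, state, met, dir, D), model)
}

# Direction-split closed subnetwork matrix and non-negative flux vector,
# mirroring the preprocessing inside decompose_elementary_modes, for
# independent conservation / oracle checks.
split_closed <- function(sub, model, tol = 1e-8) {
  cm <- fluxpath:::closed_matrix(sub, model)
  f <- cm$flux
  sgn <- ifelse(f < 0, -1, 1)
  M <- cm$M %*% diag(sgn, length(sgn))
  colnames(M) <- names(f)
  f <- abs(f)
  keep <- f > tol
  list(M = M[, keep, drop = FALSE], flux = f[keep])
}

# Weighted sum of modes as a named vector over `ids`.
recon_modes <- function(modes, ids) {
  out <- setNames(numeric(length(ids)), ids)
  for (m in modes) out[names(m$support)] <- out[names(m$support)] +
      m$weight * m$support
  out
}

mode_supports <- function(modes) {
  lapply(modes, function(m) sort(names(m$support)))
}

efm_supports <- function(efms) {
  lapply(efms, function(e) sort(names(e)))
}

# A linear chain model with one gene per conversion step, used for
# permutation-calibration runs: production of the middle metabolite covers
# about half the gene universe.
calibration_chain <- function(n = 10) {
  make_toy_model("chain", n_reactions = n)
}

# Model with many single-reaction "pathways": k reactions sharing a trivial
# conversion, each carrying g genes, to exercise scoring on wide gene sets.
many_gene_model <- function(k = 200, genes_per_rxn = 5) {
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_X", stoichiometry = list(c(X_c = -1)),
                   lower_bound = -1, upper_bound = -1,
                   genes = list(character()), subsystem = ""),
    purrr::map_dfr(seq_len(k), function(i) {
      tibble::tibble(
        id = sprintf("R%03d", i),
        stoichiometry = list(c(X_c = -1, Y_c = 1)),
        lower_bound = 0, upper_bound = 1000,
        genes = list(sprintf("gene%04d", (i - 1) * genes_per_rxn +
                               seq_len(genes_per_rxn))),
        subsystem = "Bulk")
    }),
    tibble::tibble(id = "EX_Y", stoichiometry = list(c(Y_c = -1)),
                   lower_bound = 0, upper_bound = 1000,
                   genes = list(character()), subsystem = "")
  )
  flux_model(tibble::tibble(id = c("X_c", "Y_c")), rxns)
}

make_pathway <- function(metabolite, direction, weights,
                         condition = "manual") {
  structure(
    list(metabolite_id = metabolite, direction = direction,
         condition = condition, distance = NA_integer_,
         weights = tibble::tibble(reaction_id = names(weights),
                                  weight = unname(weights)),
         n_modes = NA_integer_, provenance = condition),
    class = "met_pathway")
}
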