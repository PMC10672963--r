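toy9 <- load_model(system.file("extdata", "toy_model.json", package = "fluxpath"))

test_that("reaction scores average fold changes over genes with data", {
  expr <- tibble::tibble(gene = c("g2", "g3", "g1"), fold_change = c(2, 4, 1))
  rs <- reaction_scores(toy9, expr)
  expect_equal(rs$score[rs$reaction_id == "R2"], 3)       # mean(2, 4)
  expect_equal(rs$n_genes[rs$reaction_id == "R2"], 2)
  expect_equal(rs$score[rs$reaction_id == "R1"], 1)       # unchanged gene
  # g4 has no data: R3 is unscored, not imputed
  expect_false("R3" %in% rs$reaction_id)
  # missing one of two genes: average over the one present
  expr2 <- tibble::tibble(gene = "g2", fold_change = 2)
  rs2 <- reaction_scores(toy9, expr2)
  expect_equal(rs2$score[rs2$reaction_id == "R2"], 2)
  expect_equal(rs2$n_genes[rs2$reaction_id == "R2"], 1)
})

test_that("the flux-weighted pathway score matches the worked example", {
  p <- make_pathway("m_c", "production", c(r1 = 0.75, r2 = 0.25))
  rs <- tibble::tibble(reaction_id = c("r1", "r2"), score = c(2, 4),
                       n_genes = c(1L, 1L))
  res <- pathway_score(p, rs)
  expect_identical(res$score, 2.5)
  expect_equal(res$n_reactions_scored, 2)

  # any weighting of all-neutral reaction scores is neutral
  rs1 <- tibble::tibble(reaction_id = c("r1", "r2"), score = c(1, 1),
                        n_genes = c(1L, 1L))
  expect_identical(pathway_score(p, rs1)$score, 1)

  # unscored reactions are dropped and weights renormalized
  p5 <- make_pathway("m_c", "production", c(r1 = 0.5, r2 = 0.5))
  rs_half <- tibble::tibble(reaction_id = "r1", score = 3, n_genes = 1L)
  expect_identical(pathway_score(p5, rs_half)$score, 3)

  # no scored reaction: flagged unscorable
  rs_none <- tibble::tibble(reaction_id = character(), score = numeric(),
                            n_genes = integer())
  expect_true(pathway_score(p, rs_none)$unscorable)
})

test_that("neutral expression gives pathway scores and p-values of exactly 1", {
  toy <- make_toy_model("diamond")
  st <- toy_state(toy)
  paths <- extract_pathways(toy$model, st, D = 3)
  expr <- tibble::tibble(gene = toy$model$genes, fold_change = 1)
  scores <- score_pathways(paths, toy$model, expr, n_perm = 200, seed = 11)
  scored <- dplyr::filter(scores, !is.na(score))
  expect_gt(nrow(scored), 0)  # gene-less exchange-only pathways are unscorable
  expect_true(all(scored$score == 1))
  expect_true(all(scored$p_value == 1))
})

test_that("pathway scores are linear in a global fold-change rescaling", {
  toy <- make_toy_model("diamond")
  st <- toy_state(toy)
  paths <- extract_pathways(toy$model, st, D = 3)
  expr <- simulate_expression(toy$model, seed = 5)
  s1 <- score_pathways(paths, toy$model, expr)
  expr_k <- dplyr::mutate(expr, fold_change = fold_change * 2.7)
  s2 <- score_pathways(paths, toy$model, expr_k)
  merged <- dplyr::left_join(
    s1, s2, by = c("metabolite_id", "direction"), suffix = c("", "_k"))
  expect_equal(merged$score_k, merged$score * 2.7, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic and detect enrichment", {
  model <- many_gene_model(k = 200, genes_per_rxn = 5)  # 1000 genes
  p <- make_pathway("Y_c", "production", c(R001 = 1))
  set.seed(42)
  fc <- rlnorm(1000, 0, 0.3)
  genes <- sort(unlist(model$reactions$genes))
  expr <- tibble::tibble(gene = genes, fold_change = sort(fc))
  # genes of R001 (gene0001..gene0005) now hold the 5 smallest fold changes;
  # give them the 5 largest instead to mark the pathway as perturbed
  expr$fold_change[expr$gene %in% model$reactions$genes[[
    match("R001", model$reactions$id)]]] <- sort(fc, decreasing = TRUE)[1:5]
  pv <- permutation_test(p, model, expr, n_perm = 1000, seed = 7)
  expect_lt(pv, 0.01)
  pv2 <- permutation_test(p, model, expr, n_perm = 1000, seed = 7)
  expect_identical(pv, pv2)

  # identical fold changes everywhere: the null equals the observed score
  expr1 <- tibble::tibble(gene = genes, fold_change = 1.7)
  expect_equal(permutation_test(p, model, expr1, n_perm = 200, seed = 3), 1)
})

test_that("incomplete expression coverage uses the general permutation path", {
  toy <- make_toy_model("chain", n_reactions = 3)
  st <- toy_state(toy)
  p <- extract_pathway(toy$model, st, "C_c", "production", D = 3)
  expr <- tibble::tibble(gene = c("g_R1", "g_R2"), fold_change = c(3, 2))
  pv <- permutation_test(p, toy$model, expr, n_perm = 500, seed = 9)
  expect_true(is.na(pv) || (pv >= 0 && pv <= 1))
  pv2 <- permutation_test(p, toy$model, expr, n_perm = 500, seed = 9)
  expect_identical(pv, pv2)
})

test_that("subsystem hit scores multiply counts by scores and average", {
  core <- synthetic_ecoli_core()
  sc <- tibble::tibble(
    metabolite_id = c("m1", "m2"), direction = "production",
    condition = "x", score = c(2, 2), p_value = NA_real_,
    n_reactions_scored = c(3L, 1L),
    per_reaction = list(
      tibble::tibble(reaction_id = c("CS", "ACONTa", "ICDHyr")),
      tibble::tibble(reaction_id = "CS")))
  class(sc) <- c("pathway_scores", class(sc))
  out <- subsystem_scores(sc, core)
  # pathway 1 contributes 3 x 2 = 6, pathway 2 contributes 1 x 2 = 2
  expect_equal(out$score[out$subsystem == "Citric Acid Cycle"], 4)
  expect_equal(out$n_pathways[out$subsystem == "Citric Acid Cycle"], 2)

  # a pathway with no annotated reactions leaves the table unchanged
  sc2 <- sc[1, ]
  sc2$per_reaction <- list(tibble::tibble(reaction_id = "NO_SUCH"))
  class(sc2) <- c("pathway_scores", class(sc2))
  expect_equal(nrow(subsystem_scores(sc2, core)), 0)
})

test_that("rank normalization is ascending with lexicographic tie-breaks", {
  expr <- tibble::tibble(gene = c("a", "b", "c"), expression = c(5, 2, 9))
  rn <- rank_normalize(expr)
  expect_equal(setNames(rn$rank, rn$gene), c(b = 1, a = 2, c = 3))
  expect_equal(rank_normalize(tibble::tibble(gene = "z", expression = 3))$rank, 1)
  tie <- rank_normalize(tibble::tibble(gene = c("b", "a"), expression = c(2, 2)))
  expect_equal(setNames(tie$rank, tie$gene), c(a = 1, b = 2))
})

test_that("score_pathways ranks by log-perturbation and supports BH", {
  toy <- make_toy_model("diamond")
  st <- toy_state(toy)
  paths <- extract_pathways(toy$model, st, D = 3)
  expr <- simulate_expression(toy$model, perturbed_reactions = "R1",
                              effect = 4, seed = 2)
  scores <- score_pathways(paths, toy$model, expr, n_perm = 200, seed = 2,
                           fdr = TRUE)
  scored <- dplyr::filter(scores, !is.na(score))
  expect_true(all(diff(abs(log(scored$score))) <= 1e-12))
  expect_true(all(scored$q_value >= scored$p_value - 1e-12, na.rm = TRUE))
})
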