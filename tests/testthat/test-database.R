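test_that("pathway MCC follows the confusion-matrix formula", {
  u <- paste0("r", 1:10)
  a <- make_pathway("m_c", "production", setNames(rep(1/3, 3), u[1:3]), "c1")
  b <- make_pathway("m_c", "production", setNames(rep(1/3, 3), u[1:3]), "c2")
  expect_equal(pathway_mcc(a, b, u), 1)

  # disjoint equal-size sets: TP=0, FP=3, FN=3, TN=4
  d <- make_pathway("m_c", "production", setNames(rep(1/3, 3), u[4:6]), "c2")
  expect_equal(pathway_mcc(a, d, u),
               (0 * 4 - 3 * 3) / sqrt(3 * 3 * 7 * 7))

  # nested sets |a|=2 within |b|=4: TP=2, FP=2, FN=0, TN=6
  s2 <- make_pathway("m_c", "production", setNames(rep(0.5, 2), u[1:2]), "c1")
  s4 <- make_pathway("m_c", "production", setNames(rep(0.25, 4), u[1:4]), "c2")
  expect_equal(pathway_mcc(s2, s4, u),
               (2 * 6 - 2 * 0) / sqrt(4 * 2 * 8 * 6))

  empty <- make_pathway("m_c", "production", setNames(numeric(0), character(0)), "c3")
  expect_equal(pathway_mcc(a, empty, u), 0)
  expect_error(pathway_mcc(a, make_pathway("other_c", "production",
                                           c(r1 = 1), "c2"), u),
               "share metabolite and direction")
})

test_that("merging collapses near-identical pathways and keeps provenance", {
  u <- paste0("r", 1:10)
  a <- make_pathway("m_c", "production", c(r1 = 0.6, r2 = 0.4), "cond_a")
  b <- make_pathway("m_c", "production", c(r1 = 0.2, r2 = 0.8), "cond_b")
  db <- merge_database(list(a, b), threshold = 0.9, universe = u)
  expect_length(db$entries, 1)
  e <- db$entries[[1]]
  expect_equal(e$provenance, c("cond_a", "cond_b"))
  # mean weights renormalized: r1 = (0.6+0.2)/2 = 0.4, r2 = 0.6
  w <- setNames(e$weights$weight, e$weights$reaction_id)
  expect_equal(unname(w[c("r1", "r2")]), c(0.4, 0.6), tolerance = 1e-12)

  # dissimilar supports stay separate
  cdis <- make_pathway("m_c", "production",
                       setNames(rep(1/3, 3), c("r7", "r8", "r9")), "cond_c")
  db2 <- merge_database(list(a, cdis), threshold = 0.9, universe = u)
  expect_length(db2$entries, 2)

  # strict inequality at the threshold: identical supports have MCC exactly
  # 1 and do merge at threshold 0.9, but at threshold 1.0 nothing exceeds it
  db3 <- merge_database(list(a, b), threshold = 1.0, universe = u)
  expect_length(db3$entries, 2)
})

test_that("merging is order-independent", {
  u <- paste0("r", 1:12)
  paths <- list(
    make_pathway("m_c", "production", c(r1 = 0.5, r2 = 0.5), "c1"),
    make_pathway("m_c", "production", c(r1 = 0.3, r2 = 0.7), "c2"),
    make_pathway("m_c", "production", setNames(rep(1/3, 3), c("r5", "r6", "r7")), "c3"),
    make_pathway("x_c", "consumption", c(r1 = 1), "c1"),
    make_pathway("x_c", "consumption", c(r1 = 0.9, r12 = 0.1), "c2"))
  db_ref <- merge_database(paths, threshold = 0.9, universe = u)
  for (perm in list(c(5, 3, 1, 4, 2), c(2, 1, 4, 3, 5), rev(seq_along(paths)))) {
    db_p <- merge_database(paths[perm], threshold = 0.9, universe = u)
    expect_equal(tidy(db_p), tidy(db_ref))
  }
})

test_that("the preset builder reconstructs the 64 growth conditions", {
  conds <- builtin_conditions("iJO1366")
  expect_length(conds, 64)
  nms <- vapply(conds, function(x) x$name, character(1))
  expect_equal(anyDuplicated(nms), 0)

  trp <- conds[[which(nms == "aa_trp__L_aerobic")]]
  expect_equal(trp$exchange_bounds$EX_trp__L_e[1], -0.5)
  expect_equal(trp$objective, "ATPM")
  expect_equal(trp$growth$type, "max_capacity")

  # 8 carbon sources including glycolate, crossed with three oxygen states
  expect_true(any(grepl("c_glyclt_", nms)))
  expect_equal(sum(grepl("^c_", nms)), 23)  # 8 x 3 minus the standard duplicate
  expect_equal(sum(grepl("^aa_", nms)), 40)
  anox <- conds[[which(nms == "c_fum_anoxia_no3")]]
  expect_equal(anox$exchange_bounds$EX_o2_e[1], 0)
  expect_equal(anox$exchange_bounds$EX_no3_e[1], -10)

  expect_error(builtin_conditions("unknown_model"), "available: iJO1366")
})

test_that("a toy database build is deterministic and serializes stably", {
  toy <- make_toy_model("diamond")
  conds <- list(
    toy_condition(toy, "uptake_one"),
    toy_condition(toy, "uptake_two", exchange_bounds = list(EX_A = c(-2, -2))))
  db <- build_pathway_database(toy$model, conds, D = 2)
  expect_gt(length(db$entries), 0)
  for (e in db$entries)
    expect_lt(abs(sum(e$weights$weight) - 1), 1e-9)

  db2 <- build_pathway_database(toy$model, conds, D = 2)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_db_json(db, f1); write_db_json(db2, f2)
  expect_identical(readLines(f1), readLines(f2))

  rt <- read_db_json(f1)
  expect_equal(tidy(rt), tidy(db), tolerance = 1e-12)
  expect_equal(rt$merge_threshold, db$merge_threshold)
})

test_that("consensus scoring averages variants and picks the best fit", {
  db <- structure(list(
    entries = list(
      make_pathway("m_c", "production", c(r1 = 1), "c1"),
      make_pathway("m_c", "production", c(r2 = 1), "c2"),
      make_pathway("solo_c", "consumption", c(r1 = 1), "c1")),
    conditions = list(), merge_threshold = 0.9), class = "pathway_db")
  model <- flux_model(
    tibble::tibble(id = c("a_c", "b_c")),
    tibble::tibble(id = c("r1", "r2"),
                   stoichiometry = list(c(a_c = -1, b_c = 1), c(a_c = -1, b_c = 1)),
                   lower_bound = 0, upper_bound = 1,
                   genes = list("gA", "gB"), subsystem = ""))
  expr <- tibble::tibble(gene = c("gA", "gB"), fold_change = c(1.2, 1.8))
  out <- consensus_score(db, model, expr)
  row <- out[out$metabolite_id == "m_c", ]
  expect_equal(row$consensus_score, 1.5)
  expect_equal(row$n_variants, 2L)
  expect_equal(row$reactions[[1]], "r2")   # the higher-scoring variant
  expect_equal(out$consensus_score[out$metabolite_id == "solo_c"], 1.2)

  neutral <- tibble::tibble(gene = c("gA", "gB"), fold_change = 1)
  expect_true(all(consensus_score(db, model, neutral)$consensus_score == 1))
})

test_that("condition presets round-trip through JSON", {
  conds <- builtin_conditions("iJO1366")[c(1, 5, 50)]
  tmp <- withr::local_tempfile(fileext = ".json")
  write_conditions_json(conds, tmp)
  back <- read_conditions_json(tmp)
  expect_length(back, 3)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$name, conds[[i]]$name)
    expect_equal(back[[i]]$objective, conds[[i]]$objective)
    expect_equal(back[[i]]$exchange_bounds, conds[[i]]$exchange_bounds,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$growth$type, conds[[i]]$growth$type)
  }
})
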