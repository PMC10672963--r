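test_that("model construction assembles S column-by-column and validates input", {
  toy <- make_toy_model("diamond")
  m <- toy$model
  # S column j must equal reaction j's stoichiometry map, exactly
  for (j in seq_len(nrow(m$reactions))) {
    st <- m$reactions$stoichiometry[[j]]
    col <- m$S[, j]
    expect_identical(unname(col[names(st)]), unname(st))
    expect_true(all(col[setdiff(rownames(m$S), names(st))] == 0))
  }
  expect_error(
    flux_model(tibble::tibble(id = "a_c"),
               tibble::tibble(id = "R1", stoichiometry = list(c(ghost_c = 1)),
                              lower_bound = 0, upper_bound = 1)),
    "undeclared metabolite 'ghost_c'")
  expect_error(
    flux_model(tibble::tibble(id = "a_c"),
               tibble::tibble(id = "R1", stoichiometry = list(c(a_c = 1)),
                              lower_bound = 2, upper_bound = 1)),
    "lower_bound exceeds upper_bound")
})

test_that("bundled toy JSON loads and the JSON dialect round-trips", {
  path <- system.file("extdata", "toy_model.json", package = "fluxpath")
  m <- load_model(path)
  expect_equal(ncol(m$S), 9)
  expect_equal(nrow(m$metabolites), 7)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, tmp)
  m2 <- read_model_json(tmp)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$genes, m$reactions$genes)
  expect_equal(m2$genes, m$genes)
})

test_that("SBML-FBC reader agrees with the equivalent in-code model", {
  path <- system.file("extdata", "toy_chain.xml", package = "fluxpath")
  m <- load_model(path)
  ref <- make_toy_model("chain", n_reactions = 2)$model
  expect_setequal(m$metabolites$id, ref$metabolites$id)
  expect_setequal(m$reactions$id, ref$reactions$id)
  ord_m <- match(ref$reactions$id, m$reactions$id)
  expect_equal(as.matrix(m$S[ref$metabolites$id, ord_m]),
               as.matrix(ref$S), ignore_attr = TRUE)
  expect_equal(m$reactions$lower_bound[ord_m], ref$reactions$lower_bound)
  expect_equal(m$reactions$upper_bound[ord_m], ref$reactions$upper_bound)
  expect_equal(m$reactions$genes[ord_m], ref$reactions$genes)
  expect_error(load_model("no_such_model.json"), "not found")
})

test_that("GPR rules are flattened to the participating gene set", {
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    metabolites = list(list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(list(id = "EX_a", name = "EX_a",
                          metabolites = list(a_c = -1),
                          lower_bound = -1, upper_bound = 1,
                          gene_reaction_rule = "(b0001 and b0002) or b0003",
                          subsystem = "")),
    genes = list()
  )
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  m <- read_model_json(tmp)
  expect_equal(m$reactions$genes[[1]], c("b0001", "b0002", "b0003"))
})

test_that("cofactor flagging is by compartment-stripped base name", {
  toy <- make_toy_model("cofactor_trap")
  m <- flag_cofactors(toy$model, "atp")
  expect_true(m$metabolites$is_cofactor[m$metabolites$id == "atp_c"])
  expect_false(any(m$metabolites$is_cofactor[m$metabolites$id != "atp_c"]))

  m0 <- flag_cofactors(m, character())
  expect_false(any(m0$metabolites$is_cofactor))

  # succinate is a carrier substrate, not a currency metabolite
  core <- synthetic_ecoli_core()
  expect_false(core$metabolites$is_cofactor[core$metabolites$id == "succ_c"])
  expect_true(core$metabolites$is_cofactor[core$metabolites$id == "atp_c"])
  expect_warning(flag_cofactors(toy$model, c("atp", "unobtainium")),
                 "unobtainium")
})

test_that("expression tables load with validation", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tfold_change", "g1\t2.0", "g2\t0.5"), tmp)
  expr <- load_expression(tmp)
  expect_equal(nrow(expr), 2)
  expect_equal(expr$fold_change, c(2, 0.5))

  writeLines(c("gene\tfold_change", "g1\t0"), tmp)
  expect_error(load_expression(tmp), "non-positive fold change for gene 'g1'")

  writeLines(c("gene\tfold_change", "g1\t2", "g1\t3"), tmp)
  expect_error(load_expression(tmp), "duplicated gene id.*g1")

  writeLines(c("gene\tfold_change", "g1\t1", "g2\t-1"), tmp)
  expr <- load_expression(tmp, log2 = TRUE)  # log2 input exponentiated
  expect_equal(expr$fold_change, c(2, 0.5))
})
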