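test_that("a fixed uptake forces the chain flux (-1, 1, 1)", {
  toy <- make_toy_model("chain", n_reactions = 1)
  st <- toy_state(toy)
  expect_equal(unname(st$v[c("EX_A", "R1", "EX_B")]), c(-1, 1, 1),
               tolerance = 1e-8)
})

test_that("the quadratic penalty splits degenerate parallel branches evenly", {
  toy <- make_toy_model("diamond")
  st <- toy_state(toy)
  expect_equal(unname(st$v[["R1"]]), 0.5, tolerance = 1e-8)
  expect_equal(unname(st$v[["R2"]]), 0.5, tolerance = 1e-8)

  # independent oracle: the feasible set has one degree of freedom
  # (R1 = t, R2 = 1 - t); grid search over t confirms t = 0.5 minimizes
  # the flux length among objective-equivalent solutions
  norms <- vapply(seq(0, 1, by = 0.01), function(t)
    sum(c(1, t, 1 - t, t, 1 - t, 1)^2), numeric(1))
  expect_equal(seq(0, 1, by = 0.01)[which.min(norms)], 0.5)
  v_alt <- c(-1, 0.3, 0.7, 0.3, 0.7, 1)  # a feasible degenerate alternative
  expect_lt(sum(st$v^2), sum(v_alt^2))
})

test_that("flux states satisfy steady state and bounds on every fixture", {
  for (tp in c("chain", "diamond", "cycle", "cofactor_trap", "branch")) {
    toy <- make_toy_model(tp)
    st <- toy_state(toy)
    expect_lt(max(abs(toy$model$S %*% st$v)), 1e-6)
    expect_true(all(st$v >= toy$model$reactions$lower_bound - 1e-6))
    expect_true(all(st$v <= toy$model$reactions$upper_bound + 1e-6))
  }
  core <- synthetic_ecoli_core()
  for (w in c("aerobic", "anaerobic")) {
    st <- solve_flux_state(apply_condition(core, core_condition(w)))
    expect_lt(max(abs(core$S %*% st$v)), 1e-6)
    expect_gt(st$v[["ATPM"]], 0)
  }
})

test_that("repeated solves are deterministic", {
  core <- synthetic_ecoli_core()
  st1 <- solve_flux_state(apply_condition(core, core_condition("aerobic")))
  st2 <- solve_flux_state(apply_condition(core, core_condition("aerobic")))
  expect_true(all(abs(st1$v - st2$v) <= 1e-8))
})

test_that("apply_condition rewrites exchange bounds and the objective", {
  core <- synthetic_ecoli_core()
  cond <- condition_spec("trp_like",
                         exchange_bounds = list(EX_succ_e = c(-0.5, 1000)),
                         objective = "ATPM")
  prob <- apply_condition(core, cond)
  j <- match("EX_succ_e", prob$model$reactions$id)
  expect_equal(prob$model$reactions$lower_bound[j], -0.5)
  expect_equal(sum(prob$c != 0), 1)
  expect_equal(unname(prob$c[["ATPM"]]), 1)

  # empty bound map leaves the model untouched
  prob0 <- apply_condition(core, condition_spec("id", objective = "ATPM"))
  expect_equal(prob0$model$reactions$lower_bound,
               core$reactions$lower_bound)

  expect_error(
    apply_condition(core, condition_spec(
      "bad", exchange_bounds = list(EX_ghost_e = c(-1, 1)),
      objective = "ATPM")),
    "unknown exchange.*valid exchange ids")
})

test_that("two-stage solve pushes biomass to capacity before the objective", {
  core <- synthetic_ecoli_core()
  cond <- condition_spec("maxcap",
                         exchange_bounds = list(EX_glc__D_e = c(-10, 1000)),
                         objective = "ATPM",
                         growth = list(reaction = "BIOMASS_core_synth",
                                       type = "max_capacity"))
  st <- solve_flux_state(apply_condition(core, cond))
  # biomass capacity solve, then ATP maximization at that growth
  cond_bio <- condition_spec("bio", exchange_bounds = list(EX_glc__D_e = c(-10, 1000)),
                             objective = "BIOMASS_core_synth")
  st_bio <- solve_flux_state(apply_condition(core, cond_bio))
  expect_equal(st$v[["BIOMASS_core_synth"]], st_bio$v[["BIOMASS_core_synth"]],
               tolerance = 1e-4)
})

test_that("active_reactions thresholds on |v| and is deterministic", {
  toy <- make_toy_model("chain", n_reactions = 1)
  st <- toy_state(toy)
  expect_setequal(active_reactions(st, 1e-9), c("EX_A", "R1", "EX_B"))

  zero_state <- structure(
    list(v = setNames(numeric(3), c("a", "b", "c")), objective_value = 0,
         condition_name = "none", zero_tolerance = 1e-9),
    class = "flux_state")
  expect_length(active_reactions(zero_state), 0)

  # inferior parallel branch is left unused by the optimal state
  br <- make_toy_model("branch")
  stb <- toy_state(br)
  expect_false("R2" %in% active_reactions(stb))
  expect_true("R1" %in% active_reactions(stb))
})

test_that("infeasible bound combinations raise a condition error", {
  toy <- make_toy_model("chain", n_reactions = 1)
  m <- toy$model
  m$reactions$lower_bound[1] <- 5  # uptake forced against its own upper bound
  m$reactions$upper_bound[1] <- 2
  m$reactions$lower_bound[3] <- 3
  prob <- apply_condition(m, condition_spec("bad", objective = "EX_B"))
  expect_error(solve_flux_state(prob), "infeasible|converge")
})
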