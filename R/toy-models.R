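#' Synthetic toy metabolic models with known elementary modes
#'
#' Small (<= 12 reaction) models whose full elementary-flux-mode set is
#' computable by exhaustive enumeration, used as fixtures and oracles
#' throughout the test suite:
#'
#' * `chain`: a linear pathway `-> A -> B -> ... ->` with a fixed uptake of
#'   1; exactly one elementary mode.
#' * `diamond`: uptake of A splitting over two equal parallel branches that
#'   rejoin at D; the quadratic flux-length penalty uniquely splits the flux
#'   0.5/0.5; exactly two through-modes.
#' * `branch`: two alternative routes A -> D of unequal yield (the second
#'   wastes half the carbon), so the optimal flux state leaves one branch
#'   unused.
#' * `cycle`: a catalytic loop (carrier X is consumed and regenerated) with
#'   net throughput, exercising decomposition of looped flux.
#' * `cofactor_trap`: two otherwise-disconnected linear pathways coupled
#'   only through an atp/adp pool; with cofactors stripped, traversal from
#'   either pathway must not leak into the other.
#'
#' Each internal reaction carries one synthetic gene `g_<reaction>`, and
#' toy reactions are annotated with small subsystem labels.
#'
#' @param topology One of `"chain"`, `"diamond"`, `"cycle"`,
#'   `"cofactor_trap"`, `"branch"`.
#' @param n_reactions For `chain`: number of internal conversion steps
#'   (default 2, giving the 3-metabolite chain `A -> B -> C`).
#' @return A list with elements `model` (a [flux_model()], cofactors
#'   flagged), `objective` (reaction id to maximize), and `efms` (the
#'   exhaustively enumerated elementary modes of the direction-split
#'   network, from [enumerate_efms()]).
#' @export
make_toy_model <- function(topology = c("chain", "diamond", "cycle",
                                        "cofactor_trap", "branch"),
                           n_reactions = 2) {
  topology <- match.arg(topology)
  rx <- function(id, st, lb = 0, ub = 1000, genes = character(), sub = "Toy") {
    tibble::tibble(id = id, stoichiometry = list(st), lower_bound = lb,
                   upper_bound = ub, genes = list(genes), subsystem = sub)
  }
  g <- function(id) paste0("g_", id)

  build <- switch(topology,
    chain = {
      stopifnot(n_reactions >= 1)
      mets <- paste0(LETTERS[seq_len(n_reactions + 1)], "_c")
      rxns <- rx("EX_A", setNames(-1, mets[1]), lb = -1, ub = -1)
      for (i in seq_len(n_reactions)) {
        id <- paste0("R", i)
        rxns <- dplyr::bind_rows(
          rxns, rx(id, setNames(c(-1, 1), mets[c(i, i + 1)]), genes = g(id)))
      }
      last <- paste0("EX_", LETTERS[n_reactions + 1])
      rxns <- dplyr::bind_rows(rxns, rx(last, setNames(-1, mets[n_reactions + 1])))
      list(mets = mets, rxns = rxns, objective = last)
    },
    diamond = {
      mets <- c("A_c", "B_c", "C_c", "D_c")
      rxns <- dplyr::bind_rows(
        rx("EX_A", c(A_c = -1), lb = -1, ub = -1),
        rx("R1", c(A_c = -1, B_c = 1), genes = g("R1"), sub = "BranchUp"),
        rx("R2", c(A_c = -1, C_c = 1), genes = g("R2"), sub = "BranchDown"),
        rx("R3", c(B_c = -1, D_c = 1), genes = g("R3"), sub = "BranchUp"),
        rx("R4", c(C_c = -1, D_c = 1), genes = g("R4"), sub = "BranchDown"),
        rx("EX_D", c(D_c = -1)))
      list(mets = mets, rxns = rxns, objective = "EX_D")
    },
    branch = {
      mets <- c("A_c", "D_c")
      rxns <- dplyr::bind_rows(
        rx("EX_A", c(A_c = -1), lb = -1, ub = -1),
        rx("R1", c(A_c = -1, D_c = 1), genes = g("R1")),
        rx("R2", c(A_c = -1, D_c = 0.5), genes = g("R2")),
        rx("EX_D", c(D_c = -1)))
      list(mets = mets, rxns = rxns, objective = "EX_D")
    },
    cycle = {
      # A + X -> Y ; Y -> Z ; Z -> X + B : the carrier X cycles while
      # A is converted to B
      mets <- c("A_c", "B_c", "X_c", "Y_c", "Z_c")
      rxns <- dplyr::bind_rows(
        rx("EX_A", c(A_c = -1), lb = -1, ub = -1),
        rx("R1", c(A_c = -1, X_c = -1, Y_c = 1), genes = g("R1"), sub = "Loop"),
        rx("R2", c(Y_c = -1, Z_c = 1), genes = g("R2"), sub = "Loop"),
        rx("R3", c(Z_c = -1, X_c = 1, B_c = 1), genes = g("R3"), sub = "Loop"),
        rx("EX_B", c(B_c = -1)))
      list(mets = mets, rxns = rxns, objective = "EX_B")
    },
    cofactor_trap = {
      # pathway 1: A -> B (atp-consuming); pathway 2: C -> D (atp-producing);
      # the two share only the atp/adp pool
      mets <- c("A_c", "B_c", "C_c", "D_c", "atp_c", "adp_c")
      rxns <- dplyr::bind_rows(
        rx("EX_A", c(A_c = -1), lb = -1, ub = -1),
        rx("R1", c(A_c = -1, atp_c = -1, B_c = 1, adp_c = 1),
           genes = g("R1"), sub = "PathOne"),
        rx("EX_B", c(B_c = -1)),
        rx("EX_C", c(C_c = -1), lb = -1, ub = -1),
        rx("R2", c(C_c = -1, adp_c = -1, D_c = 1, atp_c = 1),
           genes = g("R2"), sub = "PathTwo"),
        rx("EX_D", c(D_c = -1)))
      list(mets = mets, rxns = rxns, objective = "EX_B")
    }
  )

  model <- flux_model(tibble::tibble(id = build$mets), build$rxns)
  model <- suppressWarnings(flag_cofactors(model))
  efms <- enumerate_efms(split_network(model))
  list(model = model, objective = build$objective, efms = efms)
}

#' Standard condition for a toy model
#'
#' @param toy Result of [make_toy_model()].
#' @param name Condition name.
#' @param exchange_bounds Optional bound overrides.
#' @return A [condition_spec()].
#' @export
toy_condition <- function(toy, name = "toy_standard", exchange_bounds = list()) {
  condition_spec(name, exchange_bounds = exchange_bounds,
                 objective = toy$objective)
}

#' Simulate expression fold changes for a model
#'
#' Draws log-normal fold changes (`exp(N(0, sdlog))`) for every gene of the
#' model, then multiplies the genes of `perturbed_reactions` by `effect`.
#' With `effect = 1` this is an i.i.d. null; used for calibration tests and
#' worked examples.
#'
#' @param model A [flux_model()].
#' @param perturbed_reactions Reaction ids whose genes receive the effect.
#' @param effect Multiplicative fold-change effect (default 1 = null).
#' @param sdlog Standard deviation of the log fold changes (default 0.25).
#' @param seed Integer seed.
#' @return Expression tibble (`gene`, `fold_change`).
#' @export
simulate_expression <- function(model, perturbed_reactions = character(),
                                effect = 1, sdlog = 0.25, seed) {
  if (missing(seed)) stopf("a seed is required")
  genes <- model$genes
  hit <- unique(unlist(setNames(model$reactions$genes, model$reactions$id)[
    perturbed_reactions]))
  withr::with_seed(seed, {
    fc <- stats::rlnorm(length(genes), meanlog = 0, sdlog = sdlog)
    names(fc) <- genes
    fc[names(fc) %in% hit] <- fc[names(fc) %in% hit] * effect
    tibble::tibble(gene = genes, fold_change = unname(fc))
  })
}
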