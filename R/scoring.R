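#' Per-reaction expression fold-change scores
#'
#' The score of a reaction is the arithmetic mean of the fold changes of the
#' genes catalyzing it, over the genes for which data are available.
#' Reactions with no gene data are unscored (absent from the result);
#' pathway weights are renormalized over scored reactions downstream.
#'
#' @param model A [flux_model()].
#' @param expr Expression tibble with columns `gene`, `fold_change`
#'   (see [load_expression()]).
#' @return Tibble with columns `reaction_id`, `score`, `n_genes`.
#' @export
reaction_scores <- function(model, expr) {
  stopifnot(inherits(model, "flux_model"))
  fc <- setNames(expr$fold_change, expr$gene)
  rows <- purrr::map2(model$reactions$id, model$reactions$genes, function(id, g) {
    vals <- fc[g[g %in% names(fc)]]
    if (!length(vals)) return(NULL)
    tibble::tibble(reaction_id = id, score = mean(vals), n_genes = length(vals))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    out <- tibble::tibble(reaction_id = character(), score = numeric(),
                          n_genes = integer())
  out
}

#' Flux-weighted pathway perturbation score
#'
#' Restricts the pathway's flux weights to the scored reactions,
#' renormalizes them to sum to one, and returns the weighted average of the
#' reaction scores. A value of 1 indicates unchanged expression along the
#' pathway; values above/below 1 indicate coordinated up-/down-regulation,
#' emphasized according to each reaction's flux contribution.
#'
#' @param pathway A `met_pathway`.
#' @param rscores Reaction-score tibble from [reaction_scores()].
#' @return A `pathway_score_result`: `metabolite_id`, `direction`, `score`,
#'   `p_value` (`NA` until [permutation_test()] is run),
#'   `n_reactions_scored`, `unscorable`, and `per_reaction` (tibble
#'   `reaction_id`, `weight`, `weight_scored`, `score`).
#' @export
pathway_score <- function(pathway, rscores) {
  stopifnot(inherits(pathway, "met_pathway"))
  per <- dplyr::left_join(pathway$weights, rscores, by = "reaction_id")
  scored <- !is.na(per$score)
  per$weight_scored <- NA_real_
  if (any(scored)) {
    per$weight_scored[scored] <- per$weight[scored] / sum(per$weight[scored])
    s <- sum(per$weight_scored[scored] * per$score[scored])
  } else {
    s <- NA_real_
  }
  structure(
    list(metabolite_id = pathway$metabolite_id, direction = pathway$direction,
         condition = pathway$condition, score = s, p_value = NA_real_,
         n_reactions_scored = sum(scored), unscorable = !any(scored),
         per_reaction = per[, c("reaction_id", "weight", "weight_scored",
                                "score", "n_genes")]),
    class = "pathway_score_result"
  )
}

#' @export
print.pathway_score_result <- function(x, ...) {
  cat(sprintf("<pathway_score> %s %s: score %.4g (%d reactions scored%s)\n",
              x$metabolite_id, x$direction,
              if (x$unscorable) NA else x$score, x$n_reactions_scored,
              if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  invisible(x)
}

#' @export
tidy.pathway_score_result <- function(x, ...) x$per_reaction

#' @export
glance.pathway_score_result <- function(x, ...) {
  tibble::tibble(metabolite_id = x$metabolite_id, direction = x$direction,
                 score = x$score, p_value = x$p_value,
                 n_reactions_scored = x$n_reactions_scored)
}

#' Permutation p-value for a pathway perturbation score
#'
#' Builds a null distribution by permuting the gene/fold-change assignment
#' across all model genes and recomputing reaction and pathway scores each
#' round. The p-value is two-sided on the log scale:
#' `p = (1 + #{|log null| >= |log observed|}) / (n_perm + 1)`.
#' Permutation rounds in which no pathway gene receives data contribute a
#' neutral null score of 1.
#'
#' @param pathway A `met_pathway`.
#' @param model The [flux_model()] (supplies the gene universe and
#'   reaction-gene sets).
#' @param expr Expression tibble (`gene`, `fold_change`).
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return The p-value (scalar in \[0,1\]), or `NA` if the pathway is
#'   unscorable under the observed data.
#' @export
permutation_test <- function(pathway, model, expr, n_perm = 10000, seed) {
  stopifnot(inherits(pathway, "met_pathway"))
  if (missing(seed)) stopf("a seed is required for permutation testing")
  if (n_perm < 100) stopf("n_perm must be >= 100")

  obs <- pathway_score(pathway, reaction_scores(model, expr))
  if (obs$unscorable) return(NA_real_)

  universe <- model$genes
  in_model <- expr$gene %in% universe
  values <- expr$fold_change[in_model]
  if (!length(values)) return(NA_real_)

  genesets <- setNames(model$reactions$genes, model$reactions$id)
  genesets <- genesets[pathway$weights$reaction_id]
  w <- setNames(pathway$weights$weight, pathway$weights$reaction_id)

  null_scores <- withr::with_seed(seed, {
    if (length(values) == length(universe)) {
      # complete data: which-genes-have-data never changes, so the score is
      # a fixed linear map of the permuted value vector
      G <- matrix(0, length(genesets), length(universe),
                  dimnames = list(names(genesets), universe))
      for (r in names(genesets)) {
        g <- genesets[[r]]
        if (length(g)) G[r, g] <- 1 / length(g)
      }
      has_genes <- rowSums(G) > 0
      wn <- w[has_genes] / sum(w[has_genes])
      a <- as.numeric(wn %*% G[has_genes, , drop = FALSE])
      vapply(seq_len(n_perm), function(i) sum(a * values[sample.int(length(values))]),
             numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        carrier <- sample(universe, length(values))
        fc <- setNames(values, carrier)
        sc <- vapply(genesets, function(g) {
          vals <- fc[g[g %in% carrier]]
          if (!length(vals)) NA_real_ else mean(vals)
        }, numeric(1))
        ok <- !is.na(sc)
        if (!any(ok)) return(1)
        sum(w[ok] / sum(w[ok]) * sc[ok])
      }, numeric(1))
    }
  })

  lobs <- abs(log(obs$score))
  (1 + sum(abs(log(null_scores)) >= lobs - 1e-12)) / (n_perm + 1)
}

#' Score a set of pathways against expression data
#'
#' Computes the flux-weighted perturbation score for every pathway and,
#' optionally, permutation p-values. Results are ranked by descending
#' `|log score|` (both up- and down-regulated pathways are "perturbed").
#'
#' @param pathways List of `met_pathway` objects (e.g. from
#'   [extract_pathways()]).
#' @param model The [flux_model()].
#' @param expr Expression tibble.
#' @param n_perm Number of permutations per pathway (0 = skip testing).
#' @param seed Integer seed; required when `n_perm > 0`.
#' @param fdr If `TRUE`, append Benjamini-Hochberg adjusted p-values.
#' @return A tibble (class `pathway_scores`) with columns `metabolite_id`,
#'   `direction`, `condition`, `score`, `p_value`, `n_reactions_scored`,
#'   and list column `per_reaction`.
#' @export
score_pathways <- function(pathways, model, expr, n_perm = 0, seed = NULL,
                           fdr = FALSE) {
  if (inherits(pathways, "met_pathway")) pathways <- list(pathways)
  rs <- reaction_scores(model, expr)
  rows <- purrr::map(pathways, function(p) {
    res <- pathway_score(p, rs)
    if (n_perm > 0 && !res$unscorable)
      res$p_value <- permutation_test(p, model, expr, n_perm = n_perm, seed = seed)
    tibble::tibble(metabolite_id = res$metabolite_id, direction = res$direction,
                   condition = res$condition, score = res$score,
                   p_value = res$p_value,
                   n_reactions_scored = res$n_reactions_scored,
                   per_reaction = list(res$per_reaction))
  })
  out <- dplyr::bind_rows(rows) %>%
    dplyr::arrange(dplyr::desc(abs(log(.data$score))))
  if (fdr) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("pathway_scores", class(out))
  out
}

#' Subsystem hit scores
#'
#' For each pathway, the hit count of a subsystem is the number of pathway
#' reactions annotated to it; the pathway contributes `hits x pathway
#' score`. Contributions are averaged over the pathways that hit the
#' subsystem.
#'
#' @param scores A `pathway_scores` tibble from [score_pathways()].
#' @param model The [flux_model()] (supplies subsystem annotations).
#' @return Tibble with columns `subsystem`, `score`, `n_pathways`.
#' @export
subsystem_scores <- function(scores, model) {
  ann <- setNames(model$reactions$subsystem, model$reactions$id)
  rows <- purrr::pmap(
    list(scores$score, scores$per_reaction),
    function(s, per) {
      if (is.na(s)) return(NULL)
      sub <- ann[per$reaction_id]
      sub <- sub[!is.na(sub) & nzchar(sub)]
      if (!length(sub)) return(NULL)
      tab <- table(sub)
      tibble::tibble(subsystem = names(tab),
                     contribution = as.numeric(tab) * s)
    })
  hits <- dplyr::bind_rows(rows)
  if (!nrow(hits))
    return(tibble::tibble(subsystem = character(), score = numeric(),
                          n_pathways = integer()))
  hits %>%
    dplyr::group_by(.data$subsystem) %>%
    dplyr::summarise(score = mean(.data$contribution),
                     n_pathways = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Rank-normalize expression values
#'
#' Replaces each gene's expression value by its 1-based position in the
#' ascending ranking, with ties broken by gene id (lexicographic) for
#' determinism. Used to put array-based and RNA-seq expression values on a
#' common scale before scoring against a database built from a different
#' platform.
#'
#' @param expr A data frame with a `gene` column and one value column.
#' @param value Name of the value column (default `"expression"`; falls
#'   back to `"fold_change"` if absent).
#' @return Tibble with columns `gene`, `rank`.
#' @export
rank_normalize <- function(expr, value = "expression") {
  if (!value %in% names(expr) && "fold_change" %in% names(expr))
    value <- "fold_change"
  if (!value %in% names(expr)) stopf("no '%s' column in expression table", value)
  ord <- order(expr[[value]], expr$gene)
  tibble::tibble(gene = expr$gene[ord],
                 rank = seq_along(ord))
}
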