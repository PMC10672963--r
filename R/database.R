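#' Matthews correlation between two pathways
#'
#' MCC of the binary reaction-membership vectors of two pathways for the
#' same metabolite and direction, over a reaction universe. Used to decide
#' whether pathways computed under different conditions are "the same"
#' pathway. Degenerate cases (an empty pathway, or a zero denominator) give
#' an MCC of 0.
#'
#' @param a,b `met_pathway` objects for the same metabolite and direction.
#' @param universe Character vector of reaction ids defining the universe.
#' @return Scalar in \[-1, 1\].
#' @export
pathway_mcc <- function(a, b, universe) {
  stopifnot(inherits(a, "met_pathway"), inherits(b, "met_pathway"))
  if (a$metabolite_id != b$metabolite_id || a$direction != b$direction)
    stopf("pathways must share metabolite and direction (%s %s vs %s %s)",
          a$metabolite_id, a$direction, b$metabolite_id, b$direction)
  sa <- universe %in% a$weights$reaction_id
  sb <- universe %in% b$weights$reaction_id
  if (!any(sa) || !any(sb)) return(0)
  tp <- sum(sa & sb); tn <- sum(!sa & !sb)
  fp <- sum(!sa & sb); fn <- sum(sa & !sb)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Merge per-condition pathways into a database
#'
#' Greedy single-linkage grouping per (metabolite, direction): pathways
#' whose pairwise MCC exceeds `threshold` end up in the same group
#' (processing order is lexicographic in condition name, and single linkage
#' makes the resulting partition order-independent). Each group becomes one
#' database entry whose weights are the arithmetic mean of the member
#' weights per reaction, renormalized to sum to one, and whose provenance
#' lists all contributing conditions.
#'
#' @param per_condition List of `met_pathway` objects across conditions.
#' @param threshold Strict MCC threshold in (0, 1\]; default 0.9 (pathways
#'   with MCC exactly equal to the threshold are kept separate).
#' @param universe Reaction-id universe for the MCC; defaults to the union
#'   of reaction ids over all input pathways.
#' @param conditions Optional list of [condition_spec()]s to record.
#' @return A `pathway_db`: `entries` (list of merged `met_pathway`s with a
#'   `provenance` vector), `conditions`, `merge_threshold`.
#' @export
merge_database <- function(per_condition, threshold = 0.9, universe = NULL,
                           conditions = list()) {
  if (inherits(per_condition, "met_pathway")) per_condition <- list(per_condition)
  per_condition <- purrr::keep(per_condition, ~ nrow(.x$weights) > 0)
  if (!length(per_condition))
    return(structure(list(entries = list(), conditions = conditions,
                          merge_threshold = threshold),
                     class = "pathway_db"))
  if (!(threshold > 0 && threshold <= 1)) stopf("threshold must be in (0, 1]")
  if (is.null(universe))
    universe <- sort(unique(unlist(purrr::map(per_condition,
                                              ~ .x$weights$reaction_id))))

  keys <- vapply(per_condition,
                 function(p) paste(p$metabolite_id, p$direction, sep = "|"),
                 character(1))
  entries <- list()
  for (key in sort(unique(keys))) {
    grp <- per_condition[keys == key]
    ord <- order(vapply(grp, function(p) p$condition %||% "", character(1)))
    grp <- grp[ord]
    # single-linkage connected components over the MCC > threshold graph
    comp <- seq_along(grp)
    if (length(grp) > 1) {
      for (i in seq_len(length(grp) - 1)) {
        for (j in seq(i + 1, length(grp))) {
          if (pathway_mcc(grp[[i]], grp[[j]], universe) > threshold) {
            old <- comp[j]; new <- comp[i]
            comp[comp == old] <- new
          }
        }
      }
    }
    for (cc in sort(unique(comp))) {
      members <- grp[comp == cc]
      merged <- merge_pathway_group(members)
      entries[[length(entries) + 1L]] <- merged
    }
  }
  # deterministic entry order: metabolite, direction, first provenance
  ord <- order(vapply(entries, function(e)
    paste(e$metabolite_id, e$direction, e$provenance[1]), character(1)))
  structure(list(entries = entries[ord], conditions = conditions,
                 merge_threshold = threshold),
            class = "pathway_db")
}

# Mean of member weights per reaction, renormalized; provenance union.
merge_pathway_group <- function(members) {
  tab <- dplyr::bind_rows(purrr::map(members, function(p)
    tibble::tibble(reaction_id = p$weights$reaction_id,
                   weight = p$weights$weight)))
  k <- length(members)
  w <- tab %>%
    dplyr::group_by(.data$reaction_id) %>%
    dplyr::summarise(weight = sum(.data$weight) / k, .groups = "drop") %>%
    dplyr::arrange(.data$reaction_id)
  w$weight <- w$weight / sum(w$weight)
  p0 <- members[[1]]
  structure(
    list(metabolite_id = p0$metabolite_id, direction = p0$direction,
         condition = p0$condition, distance = p0$distance, weights = w,
         n_modes = NA_integer_,
         provenance = sort(unique(unlist(purrr::map(members, "provenance"))))),
    class = "met_pathway"
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d entries, %d conditions, merge threshold %.2f\n",
              length(x$entries), length(x$conditions), x$merge_threshold))
  invisible(x)
}

#' @export
tidy.pathway_db <- function(x, ...) pathways_table(x$entries)

#' @export
glance.pathway_db <- function(x, ...) {
  tibble::tibble(n_entries = length(x$entries),
                 n_conditions = length(x$conditions),
                 n_metabolites = length(unique(vapply(
                   x$entries, function(e) e$metabolite_id, character(1)))),
                 merge_threshold = x$merge_threshold)
}

#' Build a multi-condition pathway database
#'
#' Runs flux estimation and pathway extraction for every condition, then
#' merges near-identical pathways across conditions by Matthews correlation.
#'
#' @param model A [flux_model()] with cofactors flagged.
#' @param conditions List of [condition_spec()]s (e.g.
#'   [builtin_conditions()]).
#' @param metabolites Metabolites to extract (default: all non-cofactor
#'   metabolites active under each condition).
#' @param directions Directions to extract.
#' @param D Traversal depth.
#' @param threshold MCC merge threshold.
#' @return A `pathway_db`.
#' @export
build_pathway_database <- function(model, conditions, metabolites = NULL,
                                   directions = c("production", "consumption"),
                                   D = 3, threshold = 0.9) {
  all_paths <- list()
  for (cond in conditions) {
    state <- solve_flux_state(apply_condition(model, cond))
    paths <- extract_pathways(model, state, metabolites = metabolites,
                              directions = directions, D = D)
    all_paths <- c(all_paths, unname(paths))
  }
  merge_database(all_paths, threshold = threshold,
                 universe = model$reactions$id, conditions = conditions)
}

#' Consensus scores across database variants
#'
#' Scores every database entry against the expression data and collapses
#' the condition variants of each (metabolite, direction): the consensus
#' score is the mean score across variants, and the reported reaction set is
#' that of the maximal-scoring variant (the variant that best fits the
#' expression data).
#'
#' @param database A `pathway_db`.
#' @param model The [flux_model()].
#' @param expr Expression tibble (`gene`, `fold_change`).
#' @return Tibble with columns `metabolite_id`, `direction`,
#'   `consensus_score`, `n_variants`, `best_provenance`, `reactions`
#'   (list column), ranked by descending `|log consensus_score|`.
#' @export
consensus_score <- function(database, model, expr) {
  stopifnot(inherits(database, "pathway_db"))
  rs <- reaction_scores(model, expr)
  rows <- purrr::map(database$entries, function(p) {
    res <- pathway_score(p, rs)
    tibble::tibble(metabolite_id = p$metabolite_id, direction = p$direction,
                   score = res$score,
                   provenance = paste(p$provenance, collapse = ";"),
                   reactions = list(p$weights$reaction_id))
  })
  dplyr::bind_rows(rows) %>%
    dplyr::filter(!is.na(.data$score)) %>%
    dplyr::group_by(.data$metabolite_id, .data$direction) %>%
    dplyr::summarise(
      consensus_score = mean(.data$score),
      n_variants = dplyr::n(),
      best_provenance = .data$provenance[which.max(.data$score)],
      reactions = .data$reactions[which.max(.data$score)],
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(abs(log(.data$consensus_score))))
}

#' Serialize / deserialize a pathway database as JSON
#'
#' The serialization is deterministic (fixed entry order, fixed digit
#' count), so identical databases produce byte-identical files.
#'
#' @param database A `pathway_db`.
#' @param path Output path.
#' @return `path` (write) or a `pathway_db` (read).
#' @export
write_db_json <- function(database, path) {
  stopifnot(inherits(database, "pathway_db"))
  doc <- list(
    merge_threshold = database$merge_threshold,
    conditions = purrr::map(database$conditions, function(cs)
      list(name = cs$name, objective = cs$objective,
           exchange_bounds = purrr::map(cs$exchange_bounds, as.list),
           growth = cs$growth,
           flux_length_penalty = cs$flux_length_penalty)),
    entries = purrr::map(database$entries, function(p)
      list(metabolite_id = p$metabolite_id, direction = p$direction,
           distance = p$distance, provenance = as.list(p$provenance),
           reaction_weights = setNames(as.list(signif(p$weights$weight, 12)),
                                       p$weights$reaction_id)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_db_json
#' @export
read_db_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- purrr::map(doc$entries, function(e) {
    w <- unlist(e$reaction_weights)
    structure(
      list(metabolite_id = e$metabolite_id, direction = e$direction,
           condition = e$provenance[[1]], distance = e$distance,
           weights = tibble::tibble(reaction_id = names(w), weight = unname(w)),
           n_modes = NA_integer_,
           provenance = unlist(e$provenance)),
      class = "met_pathway")
  })
  conditions <- purrr::map(doc$conditions, function(cs)
    condition_spec(cs$name,
                   exchange_bounds = purrr::map(cs$exchange_bounds,
                                                ~ as.numeric(unlist(.x))),
                   objective = cs$objective,
                   growth = if (length(cs$growth)) cs$growth,
                   flux_length_penalty = cs$flux_length_penalty))
  structure(list(entries = entries, conditions = conditions,
                 merge_threshold = doc$merge_threshold),
            class = "pathway_db")
}
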