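#' Construct a metabolic network model
#'
#' A `flux_model` bundles the metabolite and reaction tables of a
#' constraint-based metabolic model together with the sparse stoichiometric
#' matrix `S` (metabolites x reactions) assembled from them. All downstream
#' steps -- flux estimation, subnetwork traversal, elementary-mode
#' decomposition and expression scoring -- consume this object.
#'
#' @param metabolites A data frame with columns `id`, and optionally `name`,
#'   `compartment`, `is_cofactor`. Ids are compartment-suffixed BiGG-style
#'   identifiers (e.g. `"succ_c"`).
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, metabolite id -> signed coefficient),
#'   `lower_bound`, `upper_bound`, and optionally `name`, `genes` (list column
#'   of character vectors) and `subsystem`.
#'
#' @return An object of class `flux_model` with elements `metabolites`
#'   (tibble), `reactions` (tibble), `S` (sparse `Matrix`), and `genes`
#'   (character vector of all gene ids).
#' @examples
#' mets <- tibble::tibble(id = c("a_c", "b_c"))
#' rxns <- tibble::tibble(
#'   id = c("EX_a", "R1", "EX_b"),
#'   stoichiometry = list(c(a_c = -1), c(a_c = -1, b_c = 1), c(b_c = -1)),
#'   lower_bound = c(-1, 0, 0), upper_bound = c(-1, 1000, 1000)
#' )
#' flux_model(mets, rxns)
#' @export
flux_model <- function(metabolites, reactions) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"id" %in% names(metabolites)) stopf("metabolites must have an 'id' column")
  if (anyDuplicated(metabolites$id))
    stopf("duplicated metabolite id: %s",
          metabolites$id[duplicated(metabolites$id)][1])
  if (!all(c("id", "stoichiometry", "lower_bound", "upper_bound") %in% names(reactions)))
    stopf("reactions must have columns id, stoichiometry, lower_bound, upper_bound")
  if (anyDuplicated(reactions$id))
    stopf("duplicated reaction id: %s", reactions$id[duplicated(reactions$id)][1])

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites))
    metabolites$compartment <- met_compartment(metabolites$id)
  if (!"is_cofactor" %in% names(metabolites)) metabolites$is_cofactor <- FALSE
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"genes" %in% names(reactions))
    reactions$genes <- rep(list(character()), nrow(reactions))
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  bad <- which(reactions$lower_bound > reactions$upper_bound)
  if (length(bad))
    stopf("reaction '%s': lower_bound exceeds upper_bound", reactions$id[bad[1]])
  empty <- which(lengths(reactions$stoichiometry) == 0)
  if (length(empty))
    stopf("reaction '%s' has empty stoichiometry", reactions$id[empty[1]])

  # Validate metabolite references and assemble S column by column.
  met_index <- setNames(seq_len(nrow(metabolites)), metabolites$id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[j]]
    hit <- met_index[names(st)]
    if (anyNA(hit))
      stopf("reaction '%s' references undeclared metabolite '%s'",
            reactions$id[j], names(st)[is.na(hit)][1])
    ii <- c(ii, unname(hit)); jj <- c(jj, rep(j, length(st))); xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(nrow(metabolites), nrow(reactions)),
    dimnames = list(metabolites$id, reactions$id)
  )

  structure(
    list(
      metabolites = metabolites[, c("id", "name", "compartment", "is_cofactor")],
      reactions = reactions[, c("id", "name", "stoichiometry", "lower_bound",
                                "upper_bound", "genes", "subsystem")],
      S = S,
      genes = sort(unique(unlist(reactions$genes)))
    ),
    class = "flux_model"
  )
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("<flux_model> %d metabolites x %d reactions, %d genes\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  cat(sprintf("  cofactors flagged: %d\n", sum(x$metabolites$is_cofactor)))
  invisible(x)
}

#' Default currency-metabolite (cofactor) list
#'
#' Compartment-free base names of the ubiquitous carrier metabolites that are
#' removed from the network before pathway traversal, to prevent spurious
#' shortcuts through shared cofactor pools.
#'
#' @return Character vector of metabolite base names.
#' @export
default_cofactors <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "fad", "fadh2",
    "coa", "h", "h2o", "pi", "ppi", "co2", "o2", "nh4", "q8", "q8h2")
}

#' Flag cofactor metabolites in a model
#'
#' Marks every metabolite whose compartment-stripped base id is in
#' `cofactor_ids` as a cofactor (in every compartment); all other metabolites
#' are unflagged. Unknown base names are ignored with a warning.
#'
#' @param model A [flux_model()].
#' @param cofactor_ids Character vector of compartment-free base names
#'   (e.g. `"atp"`). Defaults to [default_cofactors()].
#' @return The model with the `is_cofactor` column updated.
#' @export
flag_cofactors <- function(model, cofactor_ids = default_cofactors()) {
  stopifnot(inherits(model, "flux_model"))
  base <- met_base_id(model$metabolites$id)
  model$metabolites$is_cofactor <- base %in% cofactor_ids
  unknown <- setdiff(cofactor_ids, base)
  if (length(unknown))
    warnf("cofactor base name(s) not present in model: %s",
          paste(unknown, collapse = ", "))
  model
}

#' Read a cofactor list from a text file (one base name per line)
#'
#' Lines starting with `#` and blank lines are ignored.
#' @param path File path.
#' @return Character vector of base names.
#' @export
read_cofactor_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# All reactions touching exactly one metabolite (exchange/demand/sink).
exchange_ids <- function(model) {
  model$reactions$id[lengths(model$reactions$stoichiometry) == 1L]
}
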