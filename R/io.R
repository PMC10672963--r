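#' Load a metabolic model from file
#'
#' Reads a genome-scale model in the BiGG-style JSON dialect or SBML Level 3
#' with the FBC package and returns a [flux_model()]. Gene-protein-reaction
#' rules are flattened to the set of all genes appearing in the rule.
#'
#' @param path Path to the model file.
#' @param format `"json"`, `"sbml"`, or `"auto"` (guessed from the extension).
#' @return A [flux_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("model file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
}

# Tokens that are GPR syntax rather than gene ids.
gpr_genes <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(character())
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  sort(unique(toks[!tolower(toks) %in% c("and", "or")]))
}

#' @rdname load_model
#' @export
read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stopf("failed to parse JSON model '%s': %s", path,
                              conditionMessage(e))
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stopf("'%s' is not a BiGG-style model JSON (missing metabolites/reactions)",
          path)
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% met_compartment(m$id)), character(1))
  )
  rxns <- tibble::tibble(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    name = vapply(doc$reactions, function(r) r$name %||% r$id, character(1)),
    stoichiometry = lapply(doc$reactions, function(r) {
      if (is.null(r$metabolites) || !length(r$metabolites))
        stopf("reaction '%s' has no stoichiometry", r$id)
      vapply(r$metabolites, as.numeric, numeric(1))
    }),
    lower_bound = vapply(doc$reactions, function(r)
      as.numeric(r$lower_bound %||% -BIG_BOUND), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r)
      as.numeric(r$upper_bound %||% BIG_BOUND), numeric(1)),
    genes = lapply(doc$reactions, function(r) gpr_genes(r$gene_reaction_rule)),
    subsystem = vapply(doc$reactions, function(r)
      as.character(r$subsystem %||% ""), character(1))
  )
  flux_model(mets, rxns)
}

#' Write a model to BiGG-style JSON
#'
#' Round-trips with [read_model_json()]: reloading yields identical
#' stoichiometry, bounds and gene sets.
#'
#' @param model A [flux_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "flux_model"))
  doc <- list(
    metabolites = purrr::pmap(model$metabolites, function(id, name, compartment, is_cofactor)
      list(id = id, name = name, compartment = compartment)),
    reactions = purrr::pmap(
      model$reactions,
      function(id, name, stoichiometry, lower_bound, upper_bound, genes, subsystem)
        list(id = id, name = name,
             metabolites = as.list(stoichiometry),
             lower_bound = lower_bound, upper_bound = upper_bound,
             gene_reaction_rule = paste(genes, collapse = " or "),
             subsystem = subsystem)),
    genes = lapply(model$genes, function(g) list(id = g, name = g)),
    id = "fluxpath_model"
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Minimal SBML Level 3 + FBC v2 reader (xml2 based). Covers the subset of
# SBML that BiGG-exported models use: species/reaction ids with M_/R_/G_
# prefixes, flux bounds referenced through global parameters, and
# geneProductAssociation trees flattened to gene sets.
#' @rdname load_model
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("failed to parse SBML '%s': %s",
                                            path, conditionMessage(e)))
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- tibble::tibble(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           strip(xml2::xml_attr(sp, "id"), "M_")),
    compartment = xml2::xml_attr(sp, "compartment")
  )

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  parse_side <- function(node, tag, sign) {
    refs <- xml2::xml_find_all(
      node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
    if (!length(refs)) return(numeric(0))
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    setNames(sign * st, strip(xml2::xml_attr(refs, "species"), "M_"))
  }
  rxns <- tibble::tibble(
    id = strip(xml2::xml_attr(rx, "id"), "R_"),
    name = dplyr::coalesce(xml2::xml_attr(rx, "name"),
                           strip(xml2::xml_attr(rx, "id"), "R_")),
    stoichiometry = lapply(rx, function(node) {
      st <- c(parse_side(node, "listOfReactants", -1),
              parse_side(node, "listOfProducts", 1))
      if (!length(st))
        stopf("reaction '%s' has no stoichiometry",
              strip(xml2::xml_attr(node, "id"), "R_"))
      # collapse duplicated species references
      agg <- tapply(st, names(st), sum)
      setNames(as.numeric(agg), names(agg))
    }),
    lower_bound = vapply(rx, function(node) {
      ref <- xml2::xml_attr(node, "lowerFluxBound")
      if (is.na(ref)) {
        rev <- xml2::xml_attr(node, "reversible")
        if (identical(rev, "false")) 0 else -BIG_BOUND
      } else unname(pval[ref])
    }, numeric(1)),
    upper_bound = vapply(rx, function(node) {
      ref <- xml2::xml_attr(node, "upperFluxBound")
      if (is.na(ref)) BIG_BOUND else unname(pval[ref])
    }, numeric(1)),
    genes = lapply(rx, function(node) {
      gp <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
      sort(unique(strip(xml2::xml_attr(gp, "geneProduct"), "G_")))
    }),
    subsystem = ""
  )
  flux_model(mets, rxns)
}

#' Load a differential expression table
#'
#' Reads a TSV/CSV file with columns `gene` and `fold_change` (ratio scale,
#' 1.0 = unchanged). Extra columns (e.g. per-sample raw expression) are
#' retained. Genes absent from any particular model are kept; filtering
#' happens at scoring time.
#'
#' @param path File path (delimiter sniffed from content).
#' @param log2 If `TRUE`, `fold_change` is interpreted as log2 fold change
#'   and exponentiated on load.
#' @return A tibble with columns `gene`, `fold_change`, plus any extras.
#' @export
load_expression <- function(path, log2 = FALSE) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "fold_change") %in% names(tab)))
    stopf("expression table must have columns 'gene' and 'fold_change'")
  tab$gene <- as.character(tab$gene)
  if (log2) tab$fold_change <- 2^tab$fold_change
  dup <- tab$gene[duplicated(tab$gene)]
  if (length(dup)) stopf("duplicated gene id in expression table: %s", dup[1])
  bad <- which(!is.finite(tab$fold_change) | tab$fold_change <= 0)
  if (length(bad))
    stopf("non-positive fold change for gene '%s' (fold changes are ratios; pass log2 = TRUE for log-scale input)",
          tab$gene[bad[1]])
  tibble::as_tibble(tab)
}

#' Write a set of pathways as TSV
#'
#' One row per (metabolite, direction, reaction): columns `metabolite_id`,
#' `direction`, `reaction_id`, `weight`, `condition`.
#'
#' @param pathways A list of `met_pathway` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathways_tsv <- function(pathways, path) {
  tab <- pathways_table(pathways)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Export pathways as GMT gene sets
#'
#' Each pathway becomes one GMT line named
#' `<metabolite>|<direction>[|<condition>]`, listing the union of genes of
#' its reactions, for use with generic gene-set tools.
#'
#' @param pathways List of `met_pathway` objects.
#' @param model The [flux_model()] supplying gene annotations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, model, path) {
  if (inherits(pathways, "met_pathway")) pathways <- list(pathways)
  gene_map <- setNames(model$reactions$genes, model$reactions$id)
  lines <- vapply(pathways, function(p) {
    genes <- sort(unique(unlist(gene_map[p$weights$reaction_id])))
    nm <- paste(c(p$metabolite_id, p$direction,
                  if (nzchar(p$condition %||% "")) p$condition), collapse = "|")
    paste(c(nm, "fluxpath", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
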