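#' Describe a growth condition
#'
#' A condition specifies the environment (exchange bounds), the linear
#' objective, an optional growth constraint, and the flux-length penalty
#' used when estimating the flux state.
#'
#' @param name Condition name.
#' @param exchange_bounds Named list of length-2 numeric vectors
#'   `c(lower, upper)` keyed by exchange reaction id, in mmol/gDW/h
#'   (negative lower bound = uptake allowed).
#' @param objective Reaction id whose flux is maximized.
#' @param growth Optional growth constraint: a list with elements
#'   `reaction` (id), `type` (`"fixed"`, `"minimum"`, or `"max_capacity"`),
#'   and `value` (ignored for `"max_capacity"`, where the biomass flux is
#'   first maximized and then imposed as a minimum before the stated
#'   objective is solved).
#' @param flux_length_penalty Positive scalar weight of the quadratic
#'   flux-length term (default `1e-6`).
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(name, exchange_bounds = list(), objective,
                           growth = NULL, flux_length_penalty = 1e-6) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(flux_length_penalty) || flux_length_penalty <= 0)
    stopf("flux_length_penalty must be > 0")
  if (length(exchange_bounds)) {
    ok <- vapply(exchange_bounds, function(b)
      is.numeric(b) && length(b) == 2 && b[1] <= b[2], logical(1))
    if (!all(ok))
      stopf("exchange_bounds entries must be c(lower, upper) with lower <= upper (offender: %s)",
            names(exchange_bounds)[!ok][1])
  }
  if (!is.null(growth)) {
    growth$type <- match.arg(growth$type, c("fixed", "minimum", "max_capacity"))
    if (growth$type != "max_capacity" && is.null(growth$value))
      stopf("growth constraint of type '%s' needs a value", growth$type)
  }
  structure(
    list(name = name, exchange_bounds = exchange_bounds, objective = objective,
         objective_sense = "maximize", growth = growth,
         flux_length_penalty = flux_length_penalty),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s: objective max %s, %d exchange bound(s)%s\n",
              x$name, x$objective, length(x$exchange_bounds),
              if (is.null(x$growth)) "" else
                sprintf(", growth %s (%s)", x$growth$reaction, x$growth$type)))
  invisible(x)
}

#' Apply a condition to a model
#'
#' Overwrites the listed exchange bounds, installs a fixed/minimum growth
#' bound when requested, and builds the linear objective vector (single
#' nonzero entry at the objective reaction).
#'
#' @param model A [flux_model()].
#' @param condition A [condition_spec()].
#' @return A `flux_problem` object ready for [solve_flux_state()].
#' @export
apply_condition <- function(model, condition) {
  stopifnot(inherits(model, "flux_model"), inherits(condition, "condition_spec"))
  rxn_ids <- model$reactions$id
  if (!condition$objective %in% rxn_ids)
    stopf("objective reaction '%s' not in model", condition$objective)

  unknown <- setdiff(names(condition$exchange_bounds), rxn_ids)
  if (length(unknown))
    stopf("unknown exchange reaction(s): %s\nvalid exchange ids: %s",
          paste(unknown, collapse = ", "),
          paste(exchange_ids(model), collapse = ", "))
  for (id in names(condition$exchange_bounds)) {
    j <- match(id, rxn_ids)
    b <- condition$exchange_bounds[[id]]
    model$reactions$lower_bound[j] <- b[1]
    model$reactions$upper_bound[j] <- b[2]
  }

  g <- condition$growth
  if (!is.null(g)) {
    if (!g$reaction %in% rxn_ids)
      stopf("growth reaction '%s' not in model", g$reaction)
    j <- match(g$reaction, rxn_ids)
    if (g$type == "fixed") {
      model$reactions$lower_bound[j] <- g$value
      model$reactions$upper_bound[j] <- g$value
    } else if (g$type == "minimum") {
      model$reactions$lower_bound[j] <- g$value
    } # max_capacity handled at solve time (two-stage)
  }

  cvec <- setNames(numeric(length(rxn_ids)), rxn_ids)
  cvec[condition$objective] <- 1
  structure(
    list(model = model, condition = condition, c = cvec,
         F_scale = condition$flux_length_penalty),
    class = "flux_problem"
  )
}

#' Read and write condition presets as JSON
#'
#' A preset file is a JSON array of objects with fields `name`,
#' `exchange_bounds` (map reaction id -> [lower, upper]), `objective`,
#' optional `growth` (`reaction`, `type`, `value`) and
#' `flux_length_penalty`.
#'
#' @param conditions A list of [condition_spec()] objects.
#' @param path File path.
#' @return `path` (write), or a list of [condition_spec()] (read).
#' @export
write_conditions_json <- function(conditions, path) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  doc <- purrr::map(conditions, function(cs)
    list(name = cs$name, objective = cs$objective,
         exchange_bounds = purrr::map(cs$exchange_bounds, as.list),
         growth = cs$growth,
         flux_length_penalty = cs$flux_length_penalty))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_conditions_json
#' @export
read_conditions_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  purrr::map(doc, function(cs)
    condition_spec(cs$name,
                   exchange_bounds = purrr::map(cs$exchange_bounds,
                                                ~ as.numeric(unlist(.x))),
                   objective = cs$objective,
                   growth = if (length(cs$growth)) cs$growth,
                   flux_length_penalty = cs$flux_length_penalty %||% 1e-6))
}

# ---------------------------------------------------------------------------
# Built-in condition presets

AMINO_ACID_EXCHANGES <- c(
  "EX_ala__L_e", "EX_arg__L_e", "EX_asn__L_e", "EX_asp__L_e", "EX_cys__L_e",
  "EX_gln__L_e", "EX_glu__L_e", "EX_gly_e", "EX_his__L_e", "EX_ile__L_e",
  "EX_leu__L_e", "EX_lys__L_e", "EX_met__L_e", "EX_phe__L_e", "EX_pro__L_e",
  "EX_ser__L_e", "EX_thr__L_e", "EX_trp__L_e", "EX_tyr__L_e", "EX_val__L_e"
)

CARBON_SOURCE_EXCHANGES <- c(
  glc__D = "EX_glc__D_e", lac__D = "EX_lac__D_e", gal = "EX_gal_e",
  man = "EX_man_e", ac = "EX_ac_e", fum = "EX_fum_e", succ = "EX_succ_e",
  glyclt = "EX_glyclt_e"
)

#' Built-in growth-condition presets
#'
#' Returns the preset list used to build the multi-condition pathway
#' database for the tagged model: the standard minimal glucose medium, 20
#' single amino-acid supplements (exchange lower bound -0.5) crossed with
#' aerobic/anaerobic, and 8 carbon sources crossed with normoxia, hypoxia
#' (O2 lower bound -2) and anoxia with nitrate as electron acceptor. The
#' glucose/normoxia cell coincides with the standard condition and is not
#' duplicated, giving 64 presets. Every preset maximizes ATP production
#' (`ATPM`) after first pushing biomass to the model's maximum capacity and
#' fixing it as a minimum.
#'
#' @param model_tag Model tag; currently `"iJO1366"`.
#' @return A list of [condition_spec()] objects.
#' @export
builtin_conditions <- function(model_tag) {
  known <- c("iJO1366")
  if (!model_tag %in% known)
    stopf("unknown model tag '%s'; available: %s", model_tag,
          paste(known, collapse = ", "))

  biomass <- "BIOMASS_Ec_iJO1366_core_53p95M"
  objective <- "ATPM"
  growth <- list(reaction = biomass, type = "max_capacity")
  o2 <- list(aerobic = c(-20, 1000), anaerobic = c(0, 1000), hypoxia = c(-2, 1000))
  base_glc <- list(EX_glc__D_e = c(-10, 1000))

  mk <- function(name, bounds) {
    condition_spec(name, exchange_bounds = bounds, objective = objective,
                   growth = growth)
  }

  out <- list(mk("standard", c(base_glc, list(EX_o2_e = o2$aerobic))))

  for (aa in AMINO_ACID_EXCHANGES) {
    tag <- sub("^EX_(.*)_e$", "\\1", aa)
    for (air in c("aerobic", "anaerobic")) {
      bounds <- c(base_glc, setNames(list(c(-0.5, 1000)), aa),
                  list(EX_o2_e = o2[[air]]))
      out <- c(out, list(mk(sprintf("aa_%s_%s", tag, air), bounds)))
    }
  }

  for (cs in names(CARBON_SOURCE_EXCHANGES)) {
    ex <- CARBON_SOURCE_EXCHANGES[[cs]]
    for (ox in c("normoxia", "hypoxia", "anoxia_no3")) {
      if (cs == "glc__D" && ox == "normoxia") next  # identical to "standard"
      bounds <- list(EX_glc__D_e = c(0, 1000))
      bounds[[ex]] <- c(-10, 1000)
      if (ox == "anoxia_no3") {
        bounds$EX_o2_e <- c(0, 1000)
        bounds$EX_no3_e <- c(-10, 1000)
      } else {
        bounds$EX_o2_e <- if (ox == "normoxia") o2$aerobic else o2$hypoxia
      }
      out <- c(out, list(mk(sprintf("c_%s_%s", cs, ox), bounds)))
    }
  }
  out
}
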