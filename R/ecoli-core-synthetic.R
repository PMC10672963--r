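#' Synthetic E. coli central-carbon metabolism model
#'
#' A self-contained reconstruction of Escherichia coli central carbon
#' metabolism -- glycolysis, pentose phosphate pathway, TCA cycle,
#' glyoxylate shunt, anaplerosis, overflow fermentation, oxidative
#' phosphorylation, ammonium assimilation and a simplified biomass
#' reaction -- written from textbook stoichiometry with BiGG-style
#' reaction/metabolite identifiers and representative gene names
#' (~60 reactions). It is a synthetic stand-in assembled in code, not a
#' published model file, and is sized so that flux states solve in
#' milliseconds while still exhibiting realistic pathway structure
#' (condition-dependent fermentation vs. respiration, isozyme choice,
#' glyoxylate bypass, proton-motive coupling).
#'
#' Default bounds encode an M9-like minimal glucose medium: glucose uptake
#' up to 10 mmol/gDW/h, unconstrained oxygen, free exchange of CO2, water,
#' protons, ammonium and phosphate, and a non-growth ATP maintenance flux
#' of at least 8.39 mmol/gDW/h.
#'
#' @param flag_cofactors If `TRUE` (default) the standard currency
#'   metabolites are flagged via [flag_cofactors()].
#' @return A [flux_model()].
#' @export
synthetic_ecoli_core <- function(flag_cofactors = TRUE) {
  rx <- function(id, st, lb, ub, genes, sub) {
    tibble::tibble(id = id, stoichiometry = list(st), lower_bound = lb,
                   upper_bound = ub, genes = list(genes), subsystem = sub)
  }
  rev_ <- function(id, st, genes, sub) rx(id, st, -1000, 1000, genes, sub)
  irr_ <- function(id, st, genes, sub) rx(id, st, 0, 1000, genes, sub)
  ex_ <- function(met, lb = 0) rx(paste0("EX_", met), setNames(-1, met),
                                  lb, 1000, character(), "Exchange")

  rxns <- dplyr::bind_rows(
    # --- exchanges (M9-like defaults) ---
    ex_("glc__D_e", -10), ex_("o2_e", -1000), ex_("co2_e", -1000),
    ex_("h2o_e", -1000), ex_("h_e", -1000), ex_("nh4_e", -1000),
    ex_("pi_e", -1000), ex_("ac_e"), ex_("etoh_e"), ex_("for_e"),
    ex_("lac__D_e"), ex_("succ_e"), ex_("fum_e"),

    # --- transport ---
    irr_("GLCpts", c(glc__D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
         c("ptsG", "ptsH", "ptsI", "crr"), "Transport"),
    rev_("O2t", c(o2_e = -1, o2_c = 1), character(), "Transport"),
    rev_("CO2t", c(co2_e = -1, co2_c = 1), character(), "Transport"),
    rev_("H2Ot", c(h2o_e = -1, h2o_c = 1), character(), "Transport"),
    rev_("NH4t", c(nh4_e = -1, nh4_c = 1), "amtB", "Transport"),
    rev_("PIt2r", c(pi_e = -1, h_e = -1, pi_c = 1, h_c = 1), "pitA", "Transport"),
    rev_("ACt2r", c(ac_e = -1, h_e = -1, ac_c = 1, h_c = 1), "actP", "Transport"),
    rev_("ETOHt2r", c(etoh_e = -1, h_e = -1, etoh_c = 1, h_c = 1),
         character(), "Transport"),
    irr_("FORti", c(for_c = -1, for_e = 1), "focA", "Transport"),
    rev_("D_LACt2", c(lac__D_e = -1, h_e = -1, lac__D_c = 1, h_c = 1),
         "lldP", "Transport"),
    irr_("SUCCt2_2", c(succ_e = -1, h_e = -2, succ_c = 1, h_c = 2),
         "dctA", "Transport"),
    irr_("SUCCt3", c(succ_c = -1, h_e = -1, succ_e = 1, h_c = 1),
         character(), "Transport"),
    irr_("FUMt2_2", c(fum_e = -1, h_e = -2, fum_c = 1, h_c = 2),
         "dctA", "Transport"),

    # --- glycolysis / gluconeogenesis ---
    rev_("PGI", c(g6p_c = -1, f6p_c = 1), "pgi", "Glycolysis/Gluconeogenesis"),
    irr_("PFK", c(atp_c = -1, f6p_c = -1, adp_c = 1, fdp_c = 1, h_c = 1),
         c("pfkA", "pfkB"), "Glycolysis/Gluconeogenesis"),
    irr_("FBP", c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1),
         "fbp", "Glycolysis/Gluconeogenesis"),
    rev_("FBA", c(fdp_c = -1, dhap_c = 1, g3p_c = 1),
         c("fbaA", "fbaB"), "Glycolysis/Gluconeogenesis"),
    rev_("TPI", c(dhap_c = -1, g3p_c = 1), "tpiA", "Glycolysis/Gluconeogenesis"),
    rev_("GAPD", c(g3p_c = -1, nad_c = -1, pi_c = -1,
                   dpg13_c = 1, h_c = 1, nadh_c = 1),
         "gapA", "Glycolysis/Gluconeogenesis"),
    rev_("PGK", c(dpg13_c = -1, adp_c = -1, pg3_c = 1, atp_c = 1),
         "pgk", "Glycolysis/Gluconeogenesis"),
    rev_("PGM", c(pg3_c = -1, pg2_c = 1),
         c("gpmA", "gpmM"), "Glycolysis/Gluconeogenesis"),
    rev_("ENO", c(pg2_c = -1, h2o_c = 1, pep_c = 1),
         "eno", "Glycolysis/Gluconeogenesis"),
    irr_("PYK", c(adp_c = -1, h_c = -1, pep_c = -1, atp_c = 1, pyr_c = 1),
         c("pykF", "pykA"), "Glycolysis/Gluconeogenesis"),
    irr_("PDH", c(coa_c = -1, nad_c = -1, pyr_c = -1,
                  accoa_c = 1, co2_c = 1, nadh_c = 1),
         c("aceE", "aceF", "lpd"), "Pyruvate Metabolism"),

    # --- pentose phosphate pathway ---
    rev_("G6PDH2r", c(g6p_c = -1, nadp_c = -1, pgl6_c = 1, h_c = 1, nadph_c = 1),
         "zwf", "Pentose Phosphate Pathway"),
    irr_("PGL", c(pgl6_c = -1, h2o_c = -1, pgc6_c = 1, h_c = 1),
         "pgl", "Pentose Phosphate Pathway"),
    irr_("GND", c(pgc6_c = -1, nadp_c = -1, co2_c = 1, nadph_c = 1, ru5p__D_c = 1),
         "gnd", "Pentose Phosphate Pathway"),
    rev_("RPI", c(r5p_c = -1, ru5p__D_c = 1),
         c("rpiA", "rpiB"), "Pentose Phosphate Pathway"),
    rev_("RPE", c(ru5p__D_c = -1, xu5p__D_c = 1),
         "rpe", "Pentose Phosphate Pathway"),
    rev_("TKT1", c(r5p_c = -1, xu5p__D_c = -1, g3p_c = 1, s7p_c = 1),
         c("tktA", "tktB"), "Pentose Phosphate Pathway"),
    rev_("TALA", c(g3p_c = -1, s7p_c = -1, e4p_c = 1, f6p_c = 1),
         c("talA", "talB"), "Pentose Phosphate Pathway"),
    rev_("TKT2", c(e4p_c = -1, xu5p__D_c = -1, f6p_c = 1, g3p_c = 1),
         c("tktA", "tktB"), "Pentose Phosphate Pathway"),

    # --- TCA cycle ---
    irr_("CS", c(accoa_c = -1, h2o_c = -1, oaa_c = -1,
                 cit_c = 1, coa_c = 1, h_c = 1), "gltA", "Citric Acid Cycle"),
    rev_("ACONTa", c(cit_c = -1, acon_C_c = 1, h2o_c = 1),
         c("acnA", "acnB"), "Citric Acid Cycle"),
    rev_("ACONTb", c(acon_C_c = -1, h2o_c = -1, icit_c = 1),
         c("acnA", "acnB"), "Citric Acid Cycle"),
    rev_("ICDHyr", c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
         "icd", "Citric Acid Cycle"),
    irr_("AKGDH", c(akg_c = -1, coa_c = -1, nad_c = -1,
                    co2_c = 1, nadh_c = 1, succoa_c = 1),
         c("sucA", "sucB", "lpd"), "Citric Acid Cycle"),
    rev_("SUCOAS", c(atp_c = -1, coa_c = -1, succ_c = -1,
                     adp_c = 1, pi_c = 1, succoa_c = 1),
         c("sucC", "sucD"), "Citric Acid Cycle"),
    irr_("SUCDi", c(q8_c = -1, succ_c = -1, fum_c = 1, q8h2_c = 1),
         c("sdhA", "sdhB", "sdhC", "sdhD"), "Citric Acid Cycle"),
    irr_("FRD7", c(fum_c = -1, q8h2_c = -1, q8_c = 1, succ_c = 1),
         c("frdA", "frdB", "frdC", "frdD"), "Citric Acid Cycle"),
    rev_("FUM", c(fum_c = -1, h2o_c = -1, mal__L_c = 1),
         c("fumA", "fumB", "fumC"), "Citric Acid Cycle"),
    rev_("MDH", c(mal__L_c = -1, nad_c = -1, h_c = 1, nadh_c = 1, oaa_c = 1),
         "mdh", "Citric Acid Cycle"),

    # --- anaplerosis and glyoxylate shunt ---
    irr_("PPC", c(co2_c = -1, h2o_c = -1, pep_c = -1,
                  h_c = 1, oaa_c = 1, pi_c = 1), "ppc", "Anaplerotic Reactions"),
    irr_("PPCK", c(atp_c = -1, oaa_c = -1, adp_c = 1, co2_c = 1, pep_c = 1),
         "pck", "Anaplerotic Reactions"),
    irr_("ICL", c(icit_c = -1, glx_c = 1, succ_c = 1),
         "aceA", "Anaplerotic Reactions"),
    irr_("MALS", c(accoa_c = -1, glx_c = -1, h2o_c = -1,
                   coa_c = 1, h_c = 1, mal__L_c = 1),
         "aceB", "Anaplerotic Reactions"),
    irr_("ME1", c(mal__L_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1, pyr_c = 1),
         "maeA", "Anaplerotic Reactions"),
    irr_("ME2", c(mal__L_c = -1, nadp_c = -1, co2_c = 1, nadph_c = 1, pyr_c = 1),
         "maeB", "Anaplerotic Reactions"),

    # --- oxidative phosphorylation / energy ---
    irr_("NADH16", c(h_c = -4, nadh_c = -1, q8_c = -1,
                     h_e = 3, nad_c = 1, q8h2_c = 1),
         c("nuoA", "nuoB", "nuoF"), "Oxidative Phosphorylation"),
    irr_("CYTBD", c(h_c = -2, o2_c = -0.5, q8h2_c = -1,
                    h2o_c = 1, h_e = 2, q8_c = 1),
         c("cydA", "cydB"), "Oxidative Phosphorylation"),
    rev_("ATPS4r", c(adp_c = -1, h_e = -4, pi_c = -1,
                     atp_c = 1, h2o_c = 1, h_c = 3),
         c("atpA", "atpD", "atpF"), "Oxidative Phosphorylation"),
    rx("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, h_c = 1, pi_c = 1),
       8.39, 1000, character(), "Energy Maintenance"),
    irr_("THD2", c(h_e = -2, nadh_c = -1, nadp_c = -1,
                   h_c = 2, nad_c = 1, nadph_c = 1),
         c("pntA", "pntB"), "Oxidative Phosphorylation"),
    irr_("NADTRHD", c(nad_c = -1, nadph_c = -1, nadh_c = 1, nadp_c = 1),
         "udhA", "Oxidative Phosphorylation"),

    # --- fermentation / pyruvate metabolism ---
    irr_("PFL", c(coa_c = -1, pyr_c = -1, accoa_c = 1, for_c = 1),
         "pflB", "Pyruvate Metabolism"),
    rev_("LDH_D", c(lac__D_c = -1, nad_c = -1, h_c = 1, nadh_c = 1, pyr_c = 1),
         "ldhA", "Pyruvate Metabolism"),
    rev_("ALCD2x", c(etoh_c = -1, nad_c = -1, acald_c = 1, h_c = 1, nadh_c = 1),
         "adhE", "Pyruvate Metabolism"),
    rev_("ACALD", c(acald_c = -1, coa_c = -1, nad_c = -1,
                    accoa_c = 1, h_c = 1, nadh_c = 1),
         c("adhE", "mhpF"), "Pyruvate Metabolism"),
    rev_("PTAr", c(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1),
         "pta", "Pyruvate Metabolism"),
    rev_("ACKr", c(ac_c = -1, atp_c = -1, actp_c = 1, adp_c = 1),
         "ackA", "Pyruvate Metabolism"),

    # --- nitrogen assimilation ---
    rev_("GLUDy", c(glu__L_c = -1, h2o_c = -1, nadp_c = -1,
                    akg_c = 1, h_c = 1, nadph_c = 1, nh4_c = 1),
         "gdhA", "Glutamate Metabolism"),
    irr_("GLNS", c(atp_c = -1, glu__L_c = -1, nh4_c = -1,
                   adp_c = 1, gln__L_c = 1, h_c = 1, pi_c = 1),
         "glnA", "Glutamate Metabolism"),

    # --- simplified biomass (synthetic precursor drain) ---
    irr_("BIOMASS_core_synth",
         c(pg3_c = -1.496, accoa_c = -3.7478, atp_c = -59.81, e4p_c = -0.361,
           f6p_c = -0.0709, g3p_c = -0.129, g6p_c = -0.205, gln__L_c = -0.2557,
           glu__L_c = -4.9414, h2o_c = -59.81, nad_c = -3.547,
           nadph_c = -13.0279, oaa_c = -1.7867, pep_c = -0.5191,
           pyr_c = -2.8328, r5p_c = -0.8977,
           adp_c = 59.81, akg_c = 4.1182, coa_c = 3.7478, h_c = 59.81,
           nadh_c = 3.547, nadp_c = 13.0279, pi_c = 59.81),
         character(), "Biomass")
  )

  met_ids <- sort(unique(unlist(lapply(rxns$stoichiometry, names))))
  model <- flux_model(tibble::tibble(id = met_ids), rxns)
  if (flag_cofactors) model <- suppressWarnings(flag_cofactors(model))
  model
}

#' Aerobic and anaerobic glucose conditions for the synthetic core model
#'
#' The aerobic condition fixes growth at 0.4 /h with unconstrained oxygen;
#' the anaerobic shift lowers growth to 0.26 and oxygen uptake to
#' -2 mmol/gDW/h. Both maximize non-growth ATP production (`ATPM`).
#'
#' @param which `"aerobic"` or `"anaerobic"`.
#' @return A [condition_spec()].
#' @export
core_condition <- function(which = c("aerobic", "anaerobic")) {
  which <- match.arg(which)
  if (which == "aerobic") {
    condition_spec("core_aerobic_glc",
                   exchange_bounds = list(EX_glc__D_e = c(-10, 1000),
                                          EX_o2_e = c(-1000, 1000)),
                   objective = "ATPM",
                   growth = list(reaction = "BIOMASS_core_synth",
                                 type = "fixed", value = 0.4))
  } else {
    condition_spec("core_anaerobic_glc",
                   exchange_bounds = list(EX_glc__D_e = c(-10, 1000),
                                          EX_o2_e = c(-2, 1000)),
                   objective = "ATPM",
                   growth = list(reaction = "BIOMASS_core_synth",
                                 type = "fixed", value = 0.26))
  }
}
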