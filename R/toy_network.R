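# Synthetic core metabolic network.
#
# A ~34-reaction lumped model of xylose/glucose catabolism in a
# respiro-fermentative yeast with the respiratory topology of
# *Scheffersomyces stipitis*: a proton-pumping NADH:quinone
# oxidoreductase (CINADH), a pumping terminal oxidase (COX) and a
# non-pumping alternative oxidase (AOX).  The lumping keeps every LP
# hand-checkable while preserving the redox features the analysis
# probes: the XR/XDH cofactor imbalance of xylose assimilation, the
# cytosolic/mitochondrial NAD(H) split, fermentative NADH reoxidation,
# a glycerol overflow sink, and branch-dependent P/O ratios.

#' Options for the synthetic core network
#'
#' @param carbon_source which carbon exchange is opened by default
#'   (`"xylose"` or `"glucose"`); both assimilation pathways are always
#'   present, so one network serves matched xylose/glucose scans.
#' @param include_cinadh,include_cox,include_aox include the respective
#'   respiratory-chain reaction.
#' @param xr_cofactor cofactor consumed by xylose reductase; `"NADPH"`
#'   (the default) reproduces the net cytosolic NADH surplus of xylose
#'   assimilation, `"NADH"` removes the imbalance.
#' @param p_o_ratio_cinadh ATP gained per NADH oxidized through the
#'   pumping branch CINADH -> COX.
#' @param p_o_ratio_alternative ATP per NADH through CINADH -> AOX (the
#'   alternative oxidase does not pump, so only the CINADH site remains).
#' @param shuttle_pmf_cost proton-motive charge dissipated per cytosolic
#'   NADH moved into the mitochondrion (the physiological redox shuttle
#'   is electrogenic, so respiring cytosolic NADH yields less ATP than
#'   respiring matrix NADH).
#' @param ngam non-growth-associated ATP maintenance flux forced through
#'   the ATPase (mmol gDW^-1 h^-1; default 0).
#' @param default_uptake,default_o2 initial bounds on the carbon and
#'   oxygen exchanges (mmol gDW^-1 h^-1); scans normally override them.
#' @return list of class `"toy_network_options"`.
#' @export
toy_network_options <- function(carbon_source = c("xylose", "glucose"),
                                include_cinadh = TRUE,
                                include_cox = TRUE,
                                include_aox = TRUE,
                                xr_cofactor = c("NADPH", "NADH"),
                                p_o_ratio_cinadh = 1.5,
                                p_o_ratio_alternative = 0.5,
                                shuttle_pmf_cost = 0.5,
                                ngam = 0,
                                default_uptake = 10,
                                default_o2 = 10) {
  carbon_source <- match.arg(carbon_source)
  xr_cofactor <- match.arg(xr_cofactor)
  stopifnot(p_o_ratio_cinadh > 0, p_o_ratio_alternative > 0,
            p_o_ratio_cinadh >= p_o_ratio_alternative,
            shuttle_pmf_cost >= 0, ngam >= 0)
  structure(list(carbon_source = carbon_source,
                 include_cinadh = include_cinadh,
                 include_cox = include_cox,
                 include_aox = include_aox,
                 xr_cofactor = xr_cofactor,
                 p_o_ratio_cinadh = p_o_ratio_cinadh,
                 p_o_ratio_alternative = p_o_ratio_alternative,
                 shuttle_pmf_cost = shuttle_pmf_cost,
                 ngam = ngam,
                 default_uptake = default_uptake,
                 default_o2 = default_o2),
            class = "toy_network_options")
}

#' Build the synthetic core network
#'
#' Constructs the lumped network described in [toy_network_options()].
#' Lumped stoichiometry (per mmol): xylose assimilation XR/XDH/XK feeds
#' xylulose-5-P into a glycolytic lump yielding 5/3 pyruvate, 8/3 ATP and
#' 5/3 NADH (so one xylose nets 5/3 ATP after the kinase step and 8/3
#' cytosolic NADH before cofactor regeneration); glucose yields 2
#' pyruvate, 2 ATP, 2 NADH.  NADPH comes from an ATP-coupled NADH kinase.
#' The biomass reaction consumes 40/3 pyruvate (40 mmol C), 60 ATP and
#' 8 NADPH per gram dry weight.  Every metabolite carries a declared
#' carbon count and every non-exchange reaction balances carbon exactly,
#' which [carbon_balance()] verifies.
#'
#' @param options a [toy_network_options()] list.
#' @return a [metabolic_network()] with objective `"BIOMASS"`.
#' @export
make_core_network <- function(options = toy_network_options()) {
  o <- options
  mets <- do.call(rbind, list(
    metabolite("xyl_e",  "xylose (ext)",        "e", 5),
    metabolite("glc_e",  "glucose (ext)",       "e", 6),
    metabolite("o2_e",   "oxygen (ext)",        "e", 0),
    metabolite("co2_e",  "CO2 (ext)",           "e", 1),
    metabolite("etoh_e", "ethanol (ext)",       "e", 2),
    metabolite("glyc_e", "glycerol (ext)",      "e", 3),
    metabolite("biomass_e", "biomass",          "e", 40),
    metabolite("xyl_c",  "xylose",              "c", 5),
    metabolite("xlt_c",  "xylitol",             "c", 5),
    metabolite("xlu_c",  "xylulose",            "c", 5),
    metabolite("x5p_c",  "xylulose-5-phosphate","c", 5),
    metabolite("glc_c",  "glucose",             "c", 6),
    metabolite("pyr_c",  "pyruvate",            "c", 3),
    metabolite("acald_c","acetaldehyde",        "c", 2),
    metabolite("etoh_c", "ethanol",             "c", 2),
    metabolite("glyc_c", "glycerol",            "c", 3),
    metabolite("co2_c",  "CO2",                 "c", 1),
    metabolite("nadh_c", "NADH (cytosol)",      "c", 0),
    metabolite("nad_c",  "NAD+ (cytosol)",      "c", 0),
    metabolite("nadph_c","NADPH (cytosol)",     "c", 0),
    metabolite("nadp_c", "NADP+ (cytosol)",     "c", 0),
    metabolite("atp_c",  "ATP",                 "c", 0),
    metabolite("adp_c",  "ADP",                 "c", 0),
    metabolite("pyr_m",  "pyruvate (mito)",     "m", 3),
    metabolite("co2_m",  "CO2 (mito)",          "m", 1),
    metabolite("nadh_m", "NADH (mito)",         "m", 0),
    metabolite("nad_m",  "NAD+ (mito)",         "m", 0),
    metabolite("q_m",    "ubiquinone",          "m", 0),
    metabolite("qh2_m",  "ubiquinol",           "m", 0),
    metabolite("o2_m",   "oxygen (mito)",       "m", 0),
    metabolite("pmf_m",  "proton-motive charge","m", 0)))

  xr_sub <- if (o$xr_cofactor == "NADPH") c(nadph = "nadph_c", nadp = "nadp_c")
            else                          c(nadph = "nadh_c",  nadp = "nad_c")
  pump_cinadh <- o$p_o_ratio_alternative
  pump_cox <- o$p_o_ratio_cinadh - o$p_o_ratio_alternative

  ub <- 1000
  rx <- list(
    # exchanges (uptake = negative flux)
    reaction("EX_xyl", c(xyl_e = -1),
             lower_bound = if (o$carbon_source == "xylose") -o$default_uptake else 0,
             upper_bound = ub, name = "xylose exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_glc", c(glc_e = -1),
             lower_bound = if (o$carbon_source == "glucose") -o$default_uptake else 0,
             upper_bound = ub, name = "glucose exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_o2", c(o2_e = -1), lower_bound = -o$default_o2,
             upper_bound = 0, name = "oxygen exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_co2", c(co2_e = -1), 0, ub, "CO2 exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_etoh", c(etoh_e = -1), 0, ub, "ethanol exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_glyc", c(glyc_e = -1), 0, ub, "glycerol exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    reaction("EX_biomass", c(biomass_e = -1), 0, ub, "biomass exchange",
             is_exchange = TRUE, subsystem = "Exchange"),
    # transport
    reaction("XYLt", c(xyl_e = -1, xyl_c = 1), 0, ub,
             "xylose transport", subsystem = "Transport"),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), 0, ub,
             "glucose transport", subsystem = "Transport"),
    reaction("O2t", c(o2_e = -1, o2_m = 1), 0, ub,
             "oxygen diffusion", subsystem = "Transport"),
    reaction("CO2tm", c(co2_m = -1, co2_c = 1), 0, ub,
             "CO2 export (mito)", subsystem = "Transport"),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), 0, ub,
             "CO2 export", subsystem = "Transport"),
    reaction("ETOHt", c(etoh_c = -1, etoh_e = 1), 0, ub,
             "ethanol export", subsystem = "Transport"),
    reaction("GLYCt", c(glyc_c = -1, glyc_e = 1), 0, ub,
             "glycerol export", subsystem = "Transport"),
    # xylose assimilation
    reaction("XR", stats::setNames(c(-1, -1, 1, 1),
                                   c("xyl_c", xr_sub[["nadph"]], "xlt_c", xr_sub[["nadp"]])),
             0, ub, "xylose reductase", subsystem = "Xylose assimilation"),
    reaction("XDH", c(xlt_c = -1, nad_c = -1, xlu_c = 1, nadh_c = 1),
             0, ub, "xylitol dehydrogenase", subsystem = "Xylose assimilation"),
    reaction("XK", c(xlu_c = -1, atp_c = -1, x5p_c = 1, adp_c = 1),
             0, ub, "xylulokinase", subsystem = "Xylose assimilation"),
    # glycolytic lumps
    reaction("GLYC_X", c(x5p_c = -1, adp_c = -8/3, nad_c = -5/3,
                         pyr_c = 5/3, atp_c = 8/3, nadh_c = 5/3),
             0, ub, "glycolysis (from xylulose-5-P)", subsystem = "Glycolysis"),
    reaction("GLYC_G", c(glc_c = -1, adp_c = -2, nad_c = -2,
                         pyr_c = 2, atp_c = 2, nadh_c = 2),
             0, ub, "glycolysis (from glucose)", subsystem = "Glycolysis"),
    # oxidative PPP lump: NADPH from glucose carbon; the pentose product
    # re-enters glycolysis at the xylulose-5-P node
    reaction("PPP_OX", c(glc_c = -1, atp_c = -1, nadp_c = -2,
                         x5p_c = 1, co2_c = 1, nadph_c = 2, adp_c = 1),
             0, ub, "oxidative pentose phosphate lump",
             subsystem = "Pentose phosphate pathway"),
    # glycerol overflow (NADH sink at carbon + ATP cost)
    reaction("GPD_X", c(x5p_c = -1, nadh_c = -5/3, atp_c = -2/3,
                        glyc_c = 5/3, nad_c = 5/3, adp_c = 2/3),
             0, ub, "glycerol shunt (from xylulose-5-P)",
             subsystem = "Glycerol metabolism"),
    reaction("GPD_G", c(glc_c = -1, nadh_c = -2, atp_c = -2,
                        glyc_c = 2, nad_c = 2, adp_c = 2),
             0, ub, "glycerol shunt (from glucose)",
             subsystem = "Glycerol metabolism"),
    # fermentation
    reaction("PDC", c(pyr_c = -1, acald_c = 1, co2_c = 1),
             0, ub, "pyruvate decarboxylase", subsystem = "Fermentation"),
    reaction("ADH", c(acald_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1),
             0, ub, "alcohol dehydrogenase", subsystem = "Fermentation"),
    # mitochondrion
    reaction("PYRtm", c(pyr_c = -1, pyr_m = 1), 0, ub,
             "pyruvate import (mito)", subsystem = "Transport"),
    reaction("TCA", c(pyr_m = -1, nad_m = -4, co2_m = 3, nadh_m = 4),
             0, ub, "pyruvate oxidation (TCA lump)", subsystem = "TCA cycle"),
    reaction("NADHSH", c(nadh_c = -1, nad_m = -1, pmf_m = -o$shuttle_pmf_cost,
                         nad_c = 1, nadh_m = 1),
             0, ub, "redox shuttle (cytosol to mito, electrogenic)",
             subsystem = "Transport"),
    # cofactor and energy
    reaction("NADHK", c(nadh_c = -1, atp_c = -1, nadp_c = -1,
                        nad_c = 1, adp_c = 1, nadph_c = 1),
             0, ub, "NADH kinase", subsystem = "Cofactor metabolism"),
    reaction("ATPS", c(pmf_m = -1, adp_c = -1, atp_c = 1),
             0, ub, "ATP synthase", subsystem = "Oxidative phosphorylation"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1), o$ngam, ub,
             "ATP maintenance", subsystem = "Energy maintenance"),
    # biomass
    reaction("BIOMASS", c(pyr_c = -40/3, atp_c = -60, nadph_c = -8,
                          biomass_e = 1, adp_c = 60, nadp_c = 8),
             0, ub, "biomass synthesis", subsystem = "Biomass"))

  if (o$include_cinadh)
    rx <- c(rx, list(reaction("CINADH",
      c(nadh_m = -1, q_m = -1, nad_m = 1, qh2_m = 1, pmf_m = pump_cinadh),
      0, ub, "NADH dehydrogenase with H+ transport (complex I)",
      subsystem = "Oxidative phosphorylation")))
  if (o$include_cox)
    rx <- c(rx, list(reaction("COX",
      c(qh2_m = -1, o2_m = -0.5, q_m = 1, pmf_m = pump_cox),
      0, ub, "cytochrome oxidase",
      subsystem = "Oxidative phosphorylation")))
  if (o$include_aox)
    rx <- c(rx, list(reaction("AOX",
      c(qh2_m = -1, o2_m = -0.5, q_m = 1),
      0, ub, "alternative oxidase",
      subsystem = "Oxidative phosphorylation")))

  net <- metabolic_network(mets, rx, objective_id = "BIOMASS",
                           compartments = c("c", "m", "e"))
  # structural guard: some NADH sink must exist (fermentative ADH always
  # qualifies; this protects against future option combinations)
  sinks <- vapply(net$reactions, function(r) {
    idx <- names(r$stoich) %in% c("nadh_c", "nadh_m")
    any(r$stoich[idx] < 0)
  }, logical(1))
  if (!any(sinks))
    stop("contradictory options: network has no NADH-oxidizing reaction")
  imbal <- carbon_balance(net)
  if (any(abs(imbal) > 1e-9))
    stop("internal error: carbon imbalance in ",
         paste(names(imbal)[abs(imbal) > 1e-9], collapse = ", "))
  net
}
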