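## Programmatic fixture models.
##
## miniMito is a hand-sized two-compartment model of core cardiomyocyte
## mitochondrial physiology: glycolysis-lite, pyruvate import, the full
## eight-step TCA cycle, lumped fatty-acid beta-oxidation (octanoate) and
## ketone-body degradation, an electron transport chain with explicit proton
## pumping and a fixed reactive-oxygen branch carrying 0.1 % of complex I
## electrons, an ATP synthase translocating 8/3 H+ per ATP plus 1 H+
## equivalent for phosphate transport, the malate-aspartate shuttle, the
## GABA shunt, and six objective pseudo-reactions. Free protons carry only
## proton-motive-force bookkeeping; scalar chemistry protons of the lumped
## reactions are folded away (see the methods vignette).

#' Fixture specification
#'
#' @param seed integer seed for the random-model generator.
#' @param n_reactions approximate number of chain reactions in a random
#'   model.
#' @param n_orphans number of planted single-use (orphan) metabolites.
#' @param n_loops number of planted internal 3-cycles.
#' @param ros,gaba,shuttle feature flags for [build_minimito()]: the
#'   complex I reactive-oxygen branch, the GABA shunt, and the
#'   malate-aspartate shuttle.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_reactions = 20L, n_orphans = 0L,
                         n_loops = 0L, ros = TRUE, gaba = TRUE,
                         shuttle = TRUE) {
  stopifnot(n_reactions >= 4L, n_orphans >= 0L, n_loops >= 0L)
  structure(list(seed = as.integer(seed), n_reactions = as.integer(n_reactions),
                 n_orphans = as.integer(n_orphans), n_loops = as.integer(n_loops),
                 ros = isTRUE(ros), gaba = isTRUE(gaba),
                 shuttle = isTRUE(shuttle)),
            class = "fixture_spec")
}

## Key physiological constants of the fixture, isolated for easy revision.
## Units umol/min/gDW for bounds; dimensionless stoichiometries otherwise.
minimito_constants <- function() {
  list(
    o2_uptake = 19.8,        # maximum oxygen uptake of resting heart
    glc_uptake = 0.9,        # maximum glucose uptake
    lac_uptake = 0.5,        # lactate uptake (heart is a net lactate consumer)
    bhb_uptake = 0.35,       # 3-hydroxybutyrate (ketone body) uptake
    minor_uptake = 0.01,     # default ceiling for unmeasured boundary uptakes
    ros_fraction = 0.001,    # fraction of complex I electron pairs to superoxide
    h_per_atp_rotor = 8 / 3, # rotor protons per ATP at the synthase
    pump_cI = 4, pump_cIII = 4, pump_cIV = 2,  # H+ pumped per electron pair
    lipid_ratio = c(pc = 0.40, pe = 0.34, ps = 0.03, cl = 0.18)
  )
}

#' Build the miniMito fixture model
#'
#' @param spec a [fixture_spec()]; only the feature flags are used.
#' @return an `fba_model` that passes structural validation, the
#'   zero-boundary loop audit and the flux-capability audit.
#' @export
build_minimito <- function(spec = fixture_spec()) {
  k <- minimito_constants()
  f <- if (spec$ros) k$ros_fraction else 0
  B <- FLUX_BOUND_SENTINEL

  met <- function(id, name) fba_metabolite(id, name)
  mets <- list()
  addm <- function(id, name) mets[[length(mets) + 1L]] <<- met(id, name)

  ## cytosol
  addm("C00031Cyto", "glucose");        addm("C00022Cyto", "pyruvate")
  addm("C00186Cyto", "lactate");        addm("C00002Cyto", "ATP")
  addm("C00008Cyto", "ADP");            addm("C00009Cyto", "phosphate")
  addm("C00003Cyto", "NAD+");           addm("C00004Cyto", "NADH")
  addm("C00080Cyto", "H+");             addm("C00001Cyto", "H2O")
  addm("C00007Cyto", "O2");             addm("C00011Cyto", "CO2")
  addm("C00036Cyto", "oxaloacetate");   addm("C00149Cyto", "malate")
  addm("C00026Cyto", "2-oxoglutarate"); addm("C00049Cyto", "aspartate")
  addm("C00025Cyto", "glutamate");      addm("C00041Cyto", "alanine")
  addm("C00064Cyto", "glutamine");      addm("C00014Cyto", "ammonia")
  addm("C00162Cyto", "fatty acid (octanoate)")
  addm("C01089Cyto", "3-hydroxybutyrate")
  addm("C00027Cyto", "H2O2");           addm("C00037Cyto", "glycine")
  addm("C00158Cyto", "citrate");        addm("C00042Cyto", "succinate")
  addm("C00157Cyto", "phosphatidylcholine")
  addm("C00350Cyto", "phosphatidylethanolamine")
  addm("C02737Cyto", "phosphatidylserine")
  addm("C05980Cyto", "cardiolipin")
  ## matrix
  addm("C00022MM", "pyruvate");         addm("C00024MM", "acetyl-CoA")
  addm("C00010MM", "CoA");              addm("C00036MM", "oxaloacetate")
  addm("C00158MM", "citrate");          addm("C00311MM", "isocitrate")
  addm("C00026MM", "2-oxoglutarate");   addm("C00091MM", "succinyl-CoA")
  addm("C00042MM", "succinate");        addm("C00122MM", "fumarate")
  addm("C00149MM", "malate");           addm("C00003MM", "NAD+")
  addm("C00004MM", "NADH");             addm("C00399MM", "ubiquinone")
  addm("C00390MM", "ubiquinol");        addm("C00125MM", "ferricytochrome c")
  addm("C00126MM", "ferrocytochrome c")
  addm("C00002MM", "ATP");              addm("C00008MM", "ADP")
  addm("C00009MM", "phosphate");        addm("C00080MM", "H+")
  addm("C00001MM", "H2O");              addm("C00007MM", "O2")
  addm("C00011MM", "CO2");              addm("C00025MM", "glutamate")
  addm("C00014MM", "ammonia");          addm("C00037MM", "glycine")
  addm("C00162MM", "fatty acid (octanoate)")
  addm("C01089MM", "3-hydroxybutyrate")
  addm("C00288Cyto", "bicarbonate"); addm("C00288MM", "bicarbonate")
  if (spec$ros) {
    addm("C00704MM", "superoxide");     addm("C00027MM", "H2O2")
  }
  if (spec$gaba) {
    addm("C00334MM", "4-aminobutanoate (GABA)")
    addm("C00232MM", "succinate semialdehyde")
  }
  if (spec$shuttle) addm("C00049MM", "aspartate")
  ## boundary
  for (b in c("C00031_b", "C00186_b", "C00007_b", "C00011_b", "C00001_b",
              "C00080_b", "C00162_b", "C01089_b", "C00049_b", "C00149_b",
              "C00036_b", "C00158_b", "C00014_b", "C00037_b", "C00041_b",
              "C00064_b", "C00026_b", "C00042_b", "C00288_b"))
    addm(b, strip_compartment(b))
  if (spec$ros) addm("C00027_b", "H2O2")

  rxns <- list()
  addr <- function(id, stoich, lb = 0, ub = B, note = "") {
    rxns[[length(rxns) + 1L]] <<-
      fba_reaction(id, stoich, lb = lb, ub = ub, note = note)
  }
  S <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }

  ## -- cytosolic chemistry ------------------------------------------------
  addr("GLYCCyto", S("C00031Cyto" = -1, "C00008Cyto" = -2, "C00009Cyto" = -2,
                     "C00003Cyto" = -2, "C00022Cyto" = 2, "C00002Cyto" = 2,
                     "C00004Cyto" = 2, "C00001Cyto" = 2, "C00080Cyto" = 2),
       note = "glycolysis-lite: glucose -> 2 pyruvate + 2 ATP + 2 NADH + 2 H+")
  addr("R00703Cyto", S("C00022Cyto" = -1, "C00004Cyto" = -1,
                       "C00080Cyto" = -1, "C00186Cyto" = 1, "C00003Cyto" = 1),
       lb = -B, note = "lactate dehydrogenase, reversible")
  addr("R00258Cyto", S("C00022Cyto" = -1, "C00025Cyto" = -1,
                       "C00041Cyto" = 1, "C00026Cyto" = 1),
       lb = -B, note = "alanine transaminase, reversible")
  addr("R00355Cyto", S("C00036Cyto" = -1, "C00025Cyto" = -1,
                       "C00049Cyto" = 1, "C00026Cyto" = 1),
       lb = -B, note = "aspartate transaminase, reversible")
  addr("R00342Cyto", S("C00149Cyto" = -1, "C00003Cyto" = -1,
                       "C00036Cyto" = 1, "C00004Cyto" = 1),
       lb = -B, note = "cytosolic malate dehydrogenase, reversible")
  addr("R00253Cyto", S("C00025Cyto" = -1, "C00014Cyto" = -1, "C00002Cyto" = -1,
                       "C00064Cyto" = 1, "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "glutamine synthetase")
  addr("PCSYNCyto", S("C00162Cyto" = -1, "C00002Cyto" = -1, "C00157Cyto" = 1,
                      "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "lumped phosphatidylcholine synthesis")
  addr("PESYNCyto", S("C00162Cyto" = -1, "C00002Cyto" = -1, "C00350Cyto" = 1,
                      "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "lumped phosphatidylethanolamine synthesis")
  addr("PSSYNCyto", S("C00162Cyto" = -1, "C00002Cyto" = -1, "C02737Cyto" = 1,
                      "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "lumped phosphatidylserine synthesis")
  addr("CLSYNCyto", S("C00162Cyto" = -2, "C00002Cyto" = -2, "C05980Cyto" = 1,
                      "C00008Cyto" = 2, "C00009Cyto" = 2),
       note = "lumped cardiolipin synthesis (two acyl units)")

  ## -- matrix chemistry ---------------------------------------------------
  addr("R00209MM", S("C00022MM" = -1, "C00010MM" = -1, "C00003MM" = -1,
                     "C00024MM" = 1, "C00011MM" = 1, "C00004MM" = 1),
       note = "pyruvate dehydrogenase")
  addr("R00351MM", S("C00024MM" = -1, "C00036MM" = -1, "C00001MM" = -1,
                     "C00158MM" = 1, "C00010MM" = 1),
       note = "citrate synthase")
  addr("R01324MM", S("C00158MM" = -1, "C00311MM" = 1), lb = -B,
       note = "aconitase, reversible")
  addr("R00709MM", S("C00311MM" = -1, "C00003MM" = -1, "C00026MM" = 1,
                     "C00011MM" = 1, "C00004MM" = 1),
       note = "isocitrate dehydrogenase (NAD+)")
  addr("R01700MM", S("C00026MM" = -1, "C00010MM" = -1, "C00003MM" = -1,
                     "C00091MM" = 1, "C00011MM" = 1, "C00004MM" = 1),
       note = "2-oxoglutarate dehydrogenase complex")
  addr("R00405MM", S("C00091MM" = -1, "C00008MM" = -1, "C00009MM" = -1,
                     "C00042MM" = 1, "C00002MM" = 1, "C00010MM" = 1),
       lb = -B, note = "succinyl-CoA synthetase, reversible")
  addr("R02164MM", S("C00042MM" = -1, "C00399MM" = -1,
                     "C00122MM" = 1, "C00390MM" = 1),
       note = "succinate dehydrogenase (complex II), towards fumarate")
  addr("R01082MM", S("C00122MM" = -1, "C00001MM" = -1, "C00149MM" = 1),
       lb = -B, note = "fumarase, reversible")
  addr("R00342MM", S("C00149MM" = -1, "C00003MM" = -1,
                     "C00036MM" = 1, "C00004MM" = 1),
       lb = -B, note = "matrix malate dehydrogenase, reversible")
  addr("R00243MM", S("C00025MM" = -1, "C00003MM" = -1, "C00001MM" = -1,
                     "C00026MM" = 1, "C00014MM" = 1, "C00004MM" = 1),
       lb = -B, note = "glutamate dehydrogenase, reversible")
  if (spec$shuttle)
    addr("R00355MM", S("C00036MM" = -1, "C00025MM" = -1,
                       "C00049MM" = 1, "C00026MM" = 1),
         lb = -B, note = "matrix aspartate transaminase, reversible")
  if (spec$gaba) {
    addr("R00261MM", S("C00025MM" = -1, "C00334MM" = 1, "C00011MM" = 1),
         note = "glutamate decarboxylase (GABA shunt)")
    addr("R01648MM", S("C00334MM" = -1, "C00026MM" = -1,
                       "C00232MM" = 1, "C00025MM" = 1),
         note = "GABA transaminase (GABA shunt)")
    addr("R00713MM", S("C00232MM" = -1, "C00003MM" = -1, "C00001MM" = -1,
                       "C00042MM" = 1, "C00004MM" = 1),
         note = "succinate-semialdehyde dehydrogenase (GABA shunt)")
  }
  addr("R00344MM", S("C00022MM" = -1, "C00288MM" = -1, "C00002MM" = -1,
                     "C00036MM" = 1, "C00008MM" = 1, "C00009MM" = 1),
       note = "pyruvate carboxylase (anaplerosis; bicarbonate-dependent)")
  addr("FAOXMM", S("C00162MM" = -1, "C00002MM" = -2, "C00010MM" = -4,
                   "C00399MM" = -3, "C00003MM" = -3, "C00001MM" = -3,
                   "C00024MM" = 4, "C00390MM" = 3, "C00004MM" = 3,
                   "C00008MM" = 2, "C00009MM" = 2),
       note = "lumped beta-oxidation of octanoate (activation costs 2 ATP)")
  addr("KBDMM", S("C01089MM" = -1, "C00003MM" = -1, "C00091MM" = -1,
                  "C00010MM" = -1, "C00024MM" = 2, "C00004MM" = 1,
                  "C00042MM" = 1),
       note = "lumped ketone-body degradation (BDH + SCOT + thiolase)")

  ## -- electron transport chain and ATP synthase --------------------------
  ## Per NADH, a fraction f of electron pairs is diverted at complex I to
  ## superoxide (no pumping on the diverted fraction).
  cI <- S("C00004MM" = -1, "C00399MM" = -(1 - f),
          "C00080MM" = -k$pump_cI * (1 - f), "C00003MM" = 1,
          "C00390MM" = (1 - f), "C00080Cyto" = k$pump_cI * (1 - f))
  if (f > 0) cI <- c(cI, S("C00007MM" = -2 * f, "C00704MM" = 2 * f))
  addr("CXIMM", cI,
       note = sprintf("complex I; %.1f %% of electrons to superoxide",
                      100 * f))
  addr("CXIIIMM", S("C00390MM" = -1, "C00125MM" = -2,
                    "C00080MM" = -k$pump_cIII, "C00399MM" = 1,
                    "C00126MM" = 2, "C00080Cyto" = k$pump_cIII),
       note = "complex III (proton-motive bookkeeping only)")
  addr("CXIVMM", S("C00126MM" = -2, "C00007MM" = -0.5,
                   "C00080MM" = -k$pump_cIV, "C00125MM" = 2,
                   "C00001MM" = 1, "C00080Cyto" = k$pump_cIV),
       note = "complex IV (proton-motive bookkeeping only)")
  if (spec$ros)
    addr("R00275MM", S("C00704MM" = -2, "C00007MM" = 1, "C00027MM" = 1),
         note = "superoxide dismutase")
  addr("ATPSMM", S("C00008MM" = -1, "C00009MM" = -1,
                   "C00080Cyto" = -k$h_per_atp_rotor, "C00002MM" = 1,
                   "C00001MM" = 1, "C00080MM" = k$h_per_atp_rotor),
       note = "ATP synthase, 8/3 H+ per ATP through the rotor")

  ## -- inner-membrane transport steps -------------------------------------
  addr("TX_PYR", S("C00022Cyto" = -1, "C00080Cyto" = -1,
                   "C00022MM" = 1, "C00080MM" = 1),
       note = "pyruvate/H+ symport")
  addr("TX_PI", S("C00009Cyto" = -1, "C00080Cyto" = -1,
                  "C00009MM" = 1, "C00080MM" = 1),
       note = "phosphate/H+ symport (the 1 H+ equivalent per exported ATP)")
  addr("TX_ANT", S("C00002MM" = -1, "C00008Cyto" = -1,
                   "C00002Cyto" = 1, "C00008MM" = 1),
       note = "adenine nucleotide translocase, ATP out only")
  if (spec$shuttle) {
    addr("TX_MALOG", S("C00149Cyto" = -1, "C00026MM" = -1,
                       "C00149MM" = 1, "C00026Cyto" = 1),
         note = "oxoglutarate carrier: malate in / oxoglutarate out")
    addr("TX_ASPGLU", S("C00049MM" = -1, "C00025Cyto" = -1, "C00080Cyto" = -1,
                        "C00049Cyto" = 1, "C00025MM" = 1, "C00080MM" = 1),
         note = "aspartate/glutamate carrier, electrogenic, aspartate out")
  }
  addr("TX_GLU", S("C00025Cyto" = -1, "C00080Cyto" = -1,
                   "C00025MM" = 1, "C00080MM" = 1),
       note = "glutamate/H+ symport (SLC25A22-like), into the matrix")
  addr("TX_O2", S("C00007Cyto" = -1, "C00007MM" = 1), note = "O2 diffusion")
  addr("TX_CO2", S("C00011MM" = -1, "C00011Cyto" = 1), note = "CO2 diffusion")
  addr("TX_H2O", S("C00001Cyto" = -1, "C00001MM" = 1), lb = -B,
       note = "water, freely permeable")
  addr("TX_LEAK", S("C00080Cyto" = -1, "C00080MM" = 1),
       note = "proton leak (uncoupling), into the matrix only")
  addr("TX_FA", S("C00162Cyto" = -1, "C00162MM" = 1),
       note = "lumped carnitine shuttle")
  addr("TX_BHB", S("C01089Cyto" = -1, "C01089MM" = 1),
       note = "ketone-body uptake into the matrix")
  addr("TX_NH3", S("C00014Cyto" = -1, "C00014MM" = 1), lb = -B,
       note = "ammonia diffusion, reversible")
  addr("TX_GLY", S("C00037Cyto" = -1, "C00037MM" = 1),
       note = "glycine import")
  addr("TX_HCO3", S("C00288Cyto" = -1, "C00288MM" = 1),
       note = "bicarbonate import")
  addr("TX_CIT", S("C00158Cyto" = -1, "C00149MM" = -1,
                   "C00158MM" = 1, "C00149Cyto" = 1),
       note = "citrate carrier: citrate in / malate out")
  addr("TX_SUC", S("C00042MM" = -1, "C00042Cyto" = 1),
       note = "dicarboxylate-carrier simplification, succinate out only")
  if (spec$ros)
    addr("TX_H2O2", S("C00027MM" = -1, "C00027Cyto" = 1),
         note = "hydrogen peroxide release")

  ## -- boundary conditions -------------------------------------------------
  ex_in <- function(chem, ub = B, note = "") {
    addr(paste0("EX_", chem, "_in"),
         S(stats::setNames(c(-1, 1), c(paste0(chem, "_b"),
                                       paste0(chem, "Cyto")))),
         ub = ub, note = note)
  }
  ex_out <- function(chem, ub = B, note = "") {
    addr(paste0("EX_", chem, "_out"),
         S(stats::setNames(c(-1, 1), c(paste0(chem, "Cyto"),
                                       paste0(chem, "_b")))),
         ub = ub, note = note)
  }
  ex_in("C00031", k$glc_uptake, "glucose uptake, measured maximum")
  ex_in("C00007", k$o2_uptake, "oxygen uptake, measured maximum")
  ex_in("C00186", k$lac_uptake, "lactate uptake")
  ex_out("C00186")
  ex_in("C00162", B, "fatty-acid uptake, oxygen-limited")
  ex_in("C01089", k$bhb_uptake, "ketone-body uptake")
  ex_in("C00049", k$minor_uptake, "aspartate, default small ceiling")
  ex_in("C00149", k$minor_uptake, "malate, default small ceiling")
  ex_in("C00036", k$minor_uptake, "oxaloacetate, default small ceiling")
  ex_in("C00158", k$minor_uptake, "citrate, default small ceiling")
  ex_in("C00014", 0.1, "ammonia, small ceiling")
  ex_in("C00288", 0.1, "bicarbonate, small ceiling")
  ex_in("C00037", 0.1, "glycine, small ceiling")
  ex_out("C00011"); ex_in("C00001"); ex_out("C00001")
  ex_out("C00080"); ex_out("C00041"); ex_out("C00064")
  ex_out("C00026"); ex_out("C00042")
  if (spec$ros) ex_out("C00027")

  ## -- objective pseudo-reactions ------------------------------------------
  lr <- k$lipid_ratio / sum(k$lipid_ratio)  # normalise the stated 95 % to 1
  addr("OBJ_ATP", S("C00002Cyto" = -1, "C00001Cyto" = -1,
                    "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "maximum ATP production (cytosolic ATP demand)")
  addr("OBJ_AA", S("C00041Cyto" = -0.25, "C00049Cyto" = -0.25,
                   "C00025Cyto" = -0.25, "C00064Cyto" = -0.25),
       note = "amino-acid availability (representative four)")
  addr("OBJ_RNA", S("C00002Cyto" = -1, "C00064Cyto" = -0.5,
                    "C00049Cyto" = -0.5, "C00008Cyto" = 1, "C00009Cyto" = 1),
       note = "RNA nucleotide synthesis demand")
  addr("OBJ_DNA", S("C00002Cyto" = -1, "C00064Cyto" = -0.5,
                    "C00049Cyto" = -0.5, "C00004Cyto" = -1,
                    "C00008Cyto" = 1, "C00009Cyto" = 1, "C00003Cyto" = 1),
       note = "DNA nucleotide synthesis demand (reduction step)")
  addr("OBJ_LIPID", S("C00157Cyto" = -lr[["pc"]], "C00350Cyto" = -lr[["pe"]],
                      "C02737Cyto" = -lr[["ps"]], "C05980Cyto" = -lr[["cl"]]),
       note = "inner-membrane lipid ratio demand (40/34/3/18, normalised)")
  addr("OBJ_HAEM", S("C00091MM" = -1, "C00037MM" = -1, "C00010MM" = 1),
       note = "haem synthesis demand (succinyl-CoA + glycine)")

  objectives <- list(
    objective_spec("OBJ_ATP", "ATP production"),
    objective_spec("OBJ_AA", "amino-acid availability"),
    objective_spec("OBJ_RNA", "nucleotide (RNA) synthesis"),
    objective_spec("OBJ_DNA", "nucleotide (DNA) synthesis"),
    objective_spec("OBJ_LIPID", "lipid synthesis"),
    objective_spec("OBJ_HAEM", "haem production"))

  fba_model(mets, rxns, objectives,
            metadata = "miniMito: miniature two-compartment mitochondrial fixture")
}

#' Build a seeded random model with planted defects
#'
#' Generates a reproducible single-compartment-per-chain toy network made of
#' boundary-fed linear pathways, then plants a requested number of orphan
#' (single-use) metabolites and internal 3-cycles. Ground truth is attached
#' for property tests.
#'
#' @param spec a [fixture_spec()]; `seed`, `n_reactions`, `n_orphans` and
#'   `n_loops` are used.
#' @return an `fba_model`; attributes `planted_orphans` and `planted_loops`
#'   hold the ground-truth metabolite and reaction ids.
#' @export
build_random_model <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n_chain <- spec$n_reactions
  mets <- list()
  rxns <- list()
  midx <- 0L
  new_met <- function(compartment) {
    midx <<- midx + 1L
    suffix <- c(matrix = "MM", cytosol = "Cyto", boundary = "_b")[[compartment]]
    id <- sprintf("X%03d%s", midx, suffix)
    mets[[length(mets) + 1L]] <<- fba_metabolite(id, id)
    id
  }
  ## boundary-fed chains: A_b -> A -> B -> ... -> Z -> Z_b
  n_chains <- max(1L, n_chain %/% 5L)
  per <- max(2L, n_chain %/% n_chains)
  ridx <- 0L
  new_rxn <- function(stoich, lb = 0, ub = FLUX_BOUND_SENTINEL) {
    ridx <<- ridx + 1L
    rxns[[length(rxns) + 1L]] <<-
      fba_reaction(sprintf("RX%03d", ridx), stoich, lb = lb, ub = ub)
  }
  for (ch in seq_len(n_chains)) {
    comp <- sample(c("matrix", "cytosol"), 1L)
    ids <- replicate(per, new_met(comp))
    b_in <- new_met("boundary")
    b_out <- new_met("boundary")
    new_rxn(stats::setNames(c(-1, 1), c(b_in, ids[1L])),
            ub = round(stats::runif(1, 1, 10), 1))
    for (i in seq_len(per - 1L))
      new_rxn(stats::setNames(c(-1, 1), c(ids[i], ids[i + 1L])),
              lb = if (stats::runif(1) < 0.3) -FLUX_BOUND_SENTINEL else 0)
    new_rxn(stats::setNames(c(-1, 1), c(ids[per], b_out)))
  }
  planted_orphans <- character()
  for (i in seq_len(spec$n_orphans)) {
    comp <- sample(c("matrix", "cytosol"), 1L)
    host <- sample(vapply(rxns, `[[`, "", "id"), 1L)
    orph <- new_met(comp)
    planted_orphans <- c(planted_orphans, orph)
    j <- match(host, vapply(rxns, `[[`, "", "id"))
    st <- rxns[[j]]$stoich
    st[orph] <- 1   # orphan produced by exactly one reaction
    rxns[[j]] <- fba_reaction(rxns[[j]]$id, st, lb = rxns[[j]]$lb,
                              ub = rxns[[j]]$ub)
  }
  planted_loops <- list()
  for (i in seq_len(spec$n_loops)) {
    comp <- sample(c("matrix", "cytosol"), 1L)
    tri <- replicate(3L, new_met(comp))
    loop_ids <- character(3L)
    for (e in 1:3) {
      ridx <- ridx + 1L
      loop_ids[e] <- sprintf("RX%03dLOOP", ridx)
      rxns[[length(rxns) + 1L]] <- fba_reaction(
        loop_ids[e],
        stats::setNames(c(-1, 1), c(tri[e], tri[e %% 3L + 1L])),
        lb = 0, ub = FLUX_BOUND_SENTINEL)
    }
    ## anchor the triangle so its members are not orphans beyond the cycle:
    ## the cycle itself uses each metabolite twice, which satisfies the
    ## orphan rule; no anchor needed.
    planted_loops[[i]] <- loop_ids
  }
  model <- fba_model(mets, rxns, objectives = list(), validate = FALSE)
  attr(model, "planted_orphans") <- planted_orphans
  attr(model, "planted_loops") <- planted_loops
  model
}
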