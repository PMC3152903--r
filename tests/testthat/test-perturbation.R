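# Disease simulation: presets, knockdown scans, threshold searches,
# uptake relief, efflux profiling and pathway activity.

test_that("presets carry the documented reactions and edits", {
  expect_equal(disease_preset("fumarase")$reactions, "R01082MM")
  expect_equal(disease_preset("fumarase")$efflux_metabolite, "C00122MM")
  expect_equal(disease_preset("sdh")$reactions, "R02164MM")
  expect_equal(disease_preset("ogdh")$reactions, "R01700MM")
  expect_setequal(disease_preset("ogdh_e3")$reactions,
                  c("R01700MM", "R07618MM"))
  expect_setequal(disease_preset("ogdh")$tracked,
                  c("R01648MM", "R00261MM", "R00713MM"))
  expect_error(disease_preset("nonsense"))
  # applying a preset whose reactions are missing from the model errors
  expect_error(apply_preset(build_minimito(), disease_preset("ogdh_e3")),
               "R07618MM")
})

test_that("knockdown curves are anchored at f = 1 and monotone", {
  m <- apply_preset(build_minimito(), disease_preset("fumarase"))
  base <- fba_optimize(m, "OBJ_ATP")$objective_value
  fr <- c(0, 0.2, 0.33, 0.5, 0.8, 0.97, 1)
  before <- m
  ks <- knockdown_scan(m, "R01082MM", fr, "OBJ_ATP")
  expect_model_identical(m, before)          # scan restores the model
  expect_equal(ks$status, rep("optimal", length(fr)))
  # f = 1 equals the unperturbed optimum
  expect_equal(ks$objective_value[fr == 1], base, tolerance = 1e-8)
  # non-decreasing in fraction (relaxation monotonicity)
  expect_true(all(diff(ks$objective_value) > -1e-6))
  # the deficiency phenotype: large ATP drop and fumarate + lactate efflux
  expect_lt(ks$objective_value[fr == 0] / base, 0.1)
  eff0 <- attr(ks, "effluxes")[[which(fr == 0)]]
  expect_true(all(c("C00122", "C00186") %in% names(eff0)))
  # fumarate is never effluxed at full enzyme capacity
  eff1 <- attr(ks, "effluxes")[[which(fr == 1)]]
  expect_false("C00122" %in% names(eff1))
})

test_that("succinate dehydrogenase deficiency effluxes succinate, not fumarate,
           and is at least as severe as fumarase deficiency", {
  m <- build_minimito()
  fum <- apply_preset(m, disease_preset("fumarase"))
  ks_f <- knockdown_scan(fum, "R01082MM", c(1, 0), "OBJ_ATP")
  ks_s <- knockdown_scan(m, "R02164MM", c(1, 0), "OBJ_ATP")
  eff_s <- attr(ks_s, "effluxes")[[2]]
  expect_true("C00042" %in% names(eff_s))    # succinate out
  expect_false("C00122" %in% names(eff_s))   # fumarate not
  # complex II no longer feeds the quinone pool: at least as severe
  expect_lte(ks_s$objective_value[2], ks_f$objective_value[2] + 1e-8)
})

test_that("the GABA shunt rescues oxoglutarate dehydrogenase deficiency", {
  m <- build_minimito()
  base <- fba_optimize(m, "OBJ_ATP")$objective_value
  ks <- knockdown_scan(m, "R01700MM", c(1, 0.33, 0), "OBJ_ATP")
  drop <- 1 - ks$objective_value[3] / base
  expect_lt(drop, 0.10)                      # minor effect
  expect_gt(drop, 0.005)                     # but a real one
  st0 <- attr(ks, "states")[[3]]
  expect_true(pathway_activity(st0, "gaba_shunt"))
  # without the shunt the same knockout is far more damaging
  m_ng <- build_minimito(fixture_spec(gaba = FALSE))
  ks_ng <- knockdown_scan(m_ng, "R01700MM", c(1, 0), "OBJ_ATP")
  base_ng <- fba_optimize(m_ng, "OBJ_ATP")$objective_value
  expect_gt(1 - ks_ng$objective_value[2] / base_ng, drop + 0.05)
})

test_that("threshold_search agrees with a brute-force grid and handles
           degenerate events", {
  m <- apply_preset(build_minimito(), disease_preset("fumarase"))
  # event that always holds: threshold is the top of the range
  always <- function(model, state) TRUE
  expect_equal(threshold_search(m, "R01082MM", always, "OBJ_ATP",
                                grid = seq(0, 1, 0.25)), 1)
  # event that never holds: sentinel
  never <- function(model, state) FALSE
  res <- threshold_search(m, "R01082MM", never, "OBJ_ATP",
                          grid = seq(0, 1, 0.25))
  expect_true(is.na(res))
  expect_equal(attr(res, "message"), "none in [0,1]")
  # fumarate efflux onset: compare against an independent dense scan
  ev <- event_efflux("C00122")
  thr <- threshold_search(m, "R01082MM", ev, "OBJ_ATP",
                          grid = seq(0, 1, 0.05), refine_to = 0.01)
  ref <- reference_fluxes(m, "OBJ_ATP")$flux[["R01082MM"]]
  dense <- seq(0, 1, 0.01)
  holds <- vapply(dense, function(f) {
    pm <- mitofba:::clamp_to_fraction(m, "R01082MM", f, ref)
    st <- fba_optimize(pm, "OBJ_ATP")
    isTRUE(ev(m, st))
  }, NA)
  brute <- max(dense[holds])
  expect_lte(abs(thr - brute), 0.011)
  # on this fixture any capacity below demand spills fumarate, so the
  # onset sits just under the full reference flux
  expect_gt(thr, 0.9)
})

test_that("lactate efflux onset is found and matches its dense scan", {
  m <- apply_preset(build_minimito(), disease_preset("fumarase"))
  ev <- event_efflux("C00186")
  thr <- threshold_search(m, "R01082MM", ev, "OBJ_ATP",
                          grid = seq(0, 1, 0.1), refine_to = 0.005)
  ref <- reference_fluxes(m, "OBJ_ATP")$flux[["R01082MM"]]
  dense <- seq(0, 1, 0.02)
  holds <- vapply(dense, function(f) {
    pm <- mitofba:::clamp_to_fraction(m, "R01082MM", f, ref)
    isTRUE(ev(m, fba_optimize(pm, "OBJ_ATP")))
  }, NA)
  expect_lte(abs(thr - max(dense[holds])), 0.021)
  # lactate spills only under deep knockdown, once the shuttle's NADH
  # disposal route has saturated
  expect_lt(thr, 0.9)
  expect_gt(thr, 0)
})

test_that("fatty-acid oxidation shuts down under deep fumarase knockdown", {
  m <- apply_preset(build_minimito(), disease_preset("fumarase"))
  ev <- event_pathway_inactive("fatty_acid_oxidation")
  thr <- threshold_search(m, "R01082MM", ev, "OBJ_ATP",
                          grid = seq(0, 1, 0.1), refine_to = 0.01)
  expect_false(is.na(thr))
  expect_lt(thr, 1)
  # cross-check at the reported threshold and just above it
  ref <- reference_fluxes(m, "OBJ_ATP")$flux[["R01082MM"]]
  at <- fba_optimize(mitofba:::clamp_to_fraction(m, "R01082MM", thr, ref),
                     "OBJ_ATP")
  expect_false(pathway_activity(at, "fatty_acid_oxidation"))
  above <- fba_optimize(
    mitofba:::clamp_to_fraction(m, "R01082MM", min(1, thr + 0.05), ref),
    "OBJ_ATP")
  expect_true(pathway_activity(above, "fatty_acid_oxidation"))
})

test_that("uptake relief raises ATP through the expected carriers", {
  m <- apply_preset(build_minimito(), disease_preset("fumarase"))
  rel <- uptake_relief_scan(
    m, "R01082MM", fraction = 0,
    boundaries = c("EX_C00049_in", "EX_C00149_in", "EX_C00036_in",
                   "EX_C00158_in", "EX_C00288_in", "EX_C00031_in"),
    objective = "OBJ_ATP")
  expect_equal(rel$status, rep("optimal", 6))
  # aspartate, malate, oxaloacetate and bicarbonate each help substantially
  helped <- rel$delta[match(c("EX_C00049_in", "EX_C00149_in",
                              "EX_C00036_in", "EX_C00288_in"),
                            rel$boundary_id)]
  expect_true(all(helped > 1))
  # citrate released to a stated trial value of 5 umol/min/gDW helps less
  rel5 <- uptake_relief_scan(m, "R01082MM", 0, "EX_C00158_in", "OBJ_ATP",
                             release_to = 5)
  expect_equal(rel5$release_to, 5)
  expect_gt(rel5$delta, 0)
  expect_lt(rel5$delta, helped[1])
  # oxoglutarate leaves by counter-exchange when C4 acids are imported
  eff <- attr(rel, "effluxes")[[match("EX_C00149_in", rel$boundary_id)]]
  expect_true("C00026" %in% names(eff))
  # releasing an already-unconstrained boundary changes nothing
  rel0 <- uptake_relief_scan(m, "R01082MM", 0, "EX_C00162_in", "OBJ_ATP")
  expect_equal(rel0$delta, 0, tolerance = 1e-7)
  # unknown boundary ids error
  expect_error(uptake_relief_scan(m, "R01082MM", 0, "EX_NOPE", "OBJ_ATP"),
               "EX_NOPE")
})

test_that("efflux profiles read direction from stoichiometry", {
  m <- build_minimito()
  rf <- reference_fluxes(m, "OBJ_ATP")
  prof <- efflux_profile(m, rf)
  expect_true(all(prof > FLUX_ZERO_TOL))
  expect_true(all(diff(prof) <= 0))          # sorted decreasing
  expect_true("C00011" %in% names(prof))     # CO2 always leaves
  expect_false("C00122" %in% names(prof))    # no fumarate exit exists here
  # uptakes never appear as effluxes
  expect_false("C00031" %in% names(prof))
  # an unsolved state is rejected
  bad <- structure(list(status = "infeasible"), class = "flux_state")
  expect_error(efflux_profile(m, bad), "optimal")
  # an all-zero state has an empty profile
  m0 <- m
  m0$rxns$lb[] <- 0
  m0$rxns$ub[] <- 0
  st0 <- fba_optimize(m0, "OBJ_ATP")
  expect_length(efflux_profile(m0, st0), 0)
})

test_that("pathway activity resolves names and flags zero-flux states", {
  m <- build_minimito()
  st <- reference_fluxes(m, "OBJ_ATP")
  expect_true(pathway_activity(st, "tca_cycle"))
  expect_true(pathway_activity(st, "fatty_acid_oxidation"))
  expect_true(pathway_activity(st, "electron_transport_chain"))
  # explicit reaction vectors work too
  expect_true(pathway_activity(st, c("R01082MM")))
  expect_error(pathway_activity(st, "no_such_pathway"), "unknown pathway")
  m0 <- m
  m0$rxns$lb[] <- 0
  m0$rxns$ub[] <- 0
  st0 <- fba_optimize(m0, "OBJ_ATP")
  for (p in names(minimito_pathways()))
    expect_false(pathway_activity(st0, p), label = p)
})

test_that("scan results serialise with one row per point", {
  m <- build_minimito()
  ks <- knockdown_scan(m, "R01700MM", c(1, 0.5, 0), "OBJ_ATP")
  path <- tempfile(fileext = ".tsv")
  write_scan_result(ks, path)
  d <- utils::read.delim(path)
  expect_equal(nrow(d), 3)
  expect_true(all(c("fraction", "objective_value", "effluxes") %in% names(d)))
})
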