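# Domain model: construction, validation, the stoichiometric matrix,
# orphan detection, constraint application, proton rebalancing and the
# disease-modelling efflux-path edit.

test_that("metabolite and reaction constructors enforce their invariants", {
  expect_error(fba_metabolite("glucose"), "compartment suffix")
  expect_error(fba_metabolite("C00031MM", compartment = "cytosol"),
               "contradicts")
  expect_equal(fba_metabolite("C00031Cyto")$compartment, "cytosol")
  expect_equal(compartment_of(c("XMM", "YCyto", "Z_b", "weird")),
               c("matrix", "cytosol", "boundary", NA))
  expect_error(fba_reaction("R1", c(ACyto = -1), lb = 1, ub = 0), "lb > ub")
  expect_error(fba_reaction("R1", c(ACyto = -1), lb = -Inf), "finite")
  # zero coefficients are dropped
  r <- fba_reaction("R1", c(ACyto = -1, BCyto = 0, CCyto = 1))
  expect_named(r$stoich, c("ACyto", "CCyto"))
})

test_that("category inference works from stoichiometry shape, not id", {
  # pure transport: same chemistry, different compartments
  expect_equal(infer_reaction_category("anything",
                                       c(C00022Cyto = -1, C00022MM = 1)),
               "transport")
  # coupled symport is still transport
  expect_equal(infer_reaction_category("x",
    c(C00022Cyto = -1, C00080Cyto = -1, C00022MM = 1, C00080MM = 1)),
    "transport")
  # membrane-spanning pump that changes chemistry is matrix
  expect_equal(infer_reaction_category("x",
    c(C00004MM = -1, C00003MM = 1, C00080MM = -4, C00080Cyto = 4)),
    "matrix")
  # boundary shape
  expect_equal(infer_reaction_category("x", c(C00031_b = -1, C00031Cyto = 1)),
               "boundary")
  expect_equal(infer_reaction_category("x", c(C00022Cyto = -1, C00186Cyto = 1)),
               "cytosolic")
})

test_that("build_matrix has the right shape and round-trips losslessly", {
  # empty model: 0 x 0
  empty <- fba_model(list(), list(), validate = FALSE)
  expect_equal(dim(build_matrix(empty)), c(0L, 0L))
  # 3-reaction chain A_b -> A -> B -> B_b: 2 internal rows x 3 columns,
  # coefficients as hand-written
  cm <- chain_model()
  S <- build_matrix(cm)
  expect_equal(dim(S), c(2L, 3L))
  expect_setequal(rownames(S), c("ACyto", "BCyto"))
  expect_equal(S["ACyto", "EX_A_in"], 1)
  expect_equal(S["ACyto", "RAB"], -1)
  expect_equal(S["BCyto", "RAB"], 1)
  expect_equal(S["BCyto", "OBJ_B"], -1)
  # column sums of a chain interior are zero, ends carry the boundary
  expect_equal(as.numeric(Matrix::colSums(S)),
               c(0, 1, -1)[match(colnames(S), c("RAB", "EX_A_in", "OBJ_B"))])
  # lossless: entries equal the stored stoichiometries
  mm <- build_minimito()
  Smm <- build_matrix(mm)
  for (r in sample(colnames(Smm), 10)) {
    st <- mm$stoich[[r]]
    st <- st[compartment_of(names(st)) != "boundary"]
    expect_equal(as.numeric(Smm[names(st), r]), as.numeric(st), info = r)
  }
  # deterministic: same model, identical matrix and index maps
  S2 <- build_matrix(build_minimito())
  expect_identical(dimnames(Smm), dimnames(S2))
  expect_equal(max(abs(Smm - S2)), 0)
  # unknown metabolite id names the offending reaction
  bad <- chain_model()
  bad$stoich$RAB <- c(ACyto = -1, GhostCyto = 1)
  expect_error(build_matrix(bad), "RAB")
})

test_that("orphan detection matches a brute-force usage count", {
  # species used only as product of one reaction
  mets <- list(fba_metabolite("ACyto"), fba_metabolite("XCyto"),
               fba_metabolite("A_b"))
  rxns <- list(fba_reaction("EX_A_in", c(A_b = -1, ACyto = 1)),
               fba_reaction("R1", c(ACyto = -1, XCyto = 1)))
  m <- fba_model(mets, rxns, validate = FALSE)
  expect_equal(find_orphan_metabolites(m), "XCyto")
  # randomly generated model with planted single-use species
  rnd <- build_random_model(fixture_spec(seed = 7, n_reactions = 20,
                                         n_orphans = 3))
  expect_setequal(find_orphan_metabolites(rnd), attr(rnd, "planted_orphans"))
  # brute force: count occurrences of each internal species over reactions
  counts <- table(unlist(lapply(rnd$stoich, names)))
  internal <- rnd$mets$id[rnd$mets$compartment != "boundary"]
  brute <- internal[!(internal %in% names(counts)) |
                    internal %in% names(counts)[counts <= 1]]
  expect_setequal(find_orphan_metabolites(rnd), brute)
  # the finished fixture has none
  expect_length(find_orphan_metabolites(build_minimito()), 0)
})

test_that("constraint sets apply idempotently and validate their targets", {
  m <- build_minimito()
  cs <- constraint_set(c("EX_C00031_in", "EX_C00007_in"),
                       lb = c(0, 0), ub = c(0.9, 19.8),
                       source = c("glucose uptake", "oxygen uptake"))
  m1 <- apply_constraint_set(m, cs)
  i <- match(c("EX_C00031_in", "EX_C00007_in"), m1$rxns$id)
  expect_equal(m1$rxns$ub[i], c(0.9, 19.8))
  # idempotent
  m2 <- apply_constraint_set(m1, cs)
  expect_model_identical(m1, m2)
  # empty set: unchanged
  expect_model_identical(m, apply_constraint_set(m, cs[0, ]))
  # unresolved ids are all reported
  bad <- constraint_set(c("NOPE1", "NOPE2"), 0, 1)
  expect_error(apply_constraint_set(m, bad), "NOPE1.*NOPE2")
  # TSV round trip with inf sentinels
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tlb\tub\tsource",
               "EX_C00031_in\t0\t0.9\tmeasured",
               "R01082MM\t-inf\tinf\tunconstrained"), path)
  cs2 <- read_constraint_set(path)
  expect_equal(cs2$lb, c(0, -FLUX_BOUND_SENTINEL))
  expect_equal(cs2$ub, c(0.9, FLUX_BOUND_SENTINEL))
  m3 <- apply_constraint_set(m, cs2)
  expect_equal(m3$rxns$ub[match("EX_C00031_in", m3$rxns$id)], 0.9)
})

test_that("proton rebalancing balances totals and reports what it cannot", {
  # ATP + H2O -> ADP + Pi at matrix pH: microspecies proton counts chosen
  # so the imbalance is exactly one released proton
  tab <- c(C00002MM = 12, C00001MM = 2, C00008MM = 12, C00009MM = 1)
  r <- fba_reaction("R00086MM", c(C00002MM = -1, C00001MM = -1,
                                  C00008MM = 1, C00009MM = 1))
  rb <- rebalance_protons(r, tab)
  expect_equal(rb$stoich[["C00080MM"]], 1)  # 12+2 in, 12+1 out: one H+ freed
  # non-proton coefficients unchanged
  expect_equal(rb$stoich[names(r$stoich)], r$stoich)
  # re-summation is zero including the free proton
  tot <- sum(rb$stoich * c(tab, C00080MM = 1)[names(rb$stoich)])
  expect_equal(tot, 0)
  # already balanced reaction comes back without a proton term
  tab2 <- c(C00022MM = 3, C00186MM = 3)
  r2 <- fba_reaction("RX", c(C00022MM = -1, C00186MM = 1))
  rb2 <- rebalance_protons(r2, tab2)
  expect_false("C00080MM" %in% names(rb2$stoich))
  # microspecies differing by one proton: coefficient +/- 1
  tab3 <- c(C00009MM = 2, C00013MM = 3)
  r3 <- fba_reaction("RY", c(C00009MM = -1, C00013MM = 1))
  expect_equal(rebalance_protons(r3, tab3)$stoich[["C00080MM"]], -1)
  # errors: missing species and cross-compartment reactions
  expect_error(rebalance_protons(r, tab[-1]), "C00002MM")
  rt <- fba_reaction("TXX", c(C00022Cyto = -1, C00022MM = 1))
  expect_error(rebalance_protons(rt, c(C00022Cyto = 3, C00022MM = 3)),
               "spans compartments")
  # property: rebalanced reactions always re-sum to zero
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    ids <- sprintf("M%02dMM", sample(50, n))
    st <- stats::setNames(sample(c(-2, -1, 1, 2), n, replace = TRUE), ids)
    tb <- stats::setNames(sample(0:15, n, replace = TRUE), ids)
    out <- rebalance_protons(fba_reaction("RR", st), tb)
    tot <- sum(out$stoich * c(tb, C00080MM = 1)[names(out$stoich)])
    expect_equal(tot, 0)
  }
})

test_that("add_efflux_path adds a zero-flux-by-default exit and is idempotent", {
  m <- build_minimito()
  m2 <- add_efflux_path(m, "C00122MM")
  expect_setequal(attr(m2, "added_reactions"),
                  c("TX_C00122_EFFLUX", "EX_C00122_out"))
  i <- match("TX_C00122_EFFLUX", m2$rxns$id)
  expect_equal(m2$rxns$lb[i], 0)                   # efflux-only
  expect_equal(m2$rxns$category[i], "transport")
  expect_equal(m2$rxns$category[match("EX_C00122_out", m2$rxns$id)],
               "boundary")
  expect_length(validate_model(m2)$errors, 0)
  # unperturbed, the addition does not affect the model: every objective
  # optimum is unchanged and the path is never forced to carry flux (its
  # FVA minimum is zero; minor objectives have alternate optima in which
  # C4 venting may tie between the succinate and fumarate exits)
  for (o in m2$objectives$id) {
    before <- fba_optimize(m, o)
    after <- fba_optimize(m2, o)
    expect_equal(after$objective_value, before$objective_value,
                 tolerance = 1e-9, info = o)
    rng <- flux_variability(m2, o, fraction = 1,
                            reactions = c("TX_C00122_EFFLUX", "EX_C00122_out"))
    expect_lt(max(abs(rng$min)), FLUX_ZERO_TOL)
  }
  # and the maximum-ATP reference distribution carries none
  st <- reference_fluxes(m2, "OBJ_ATP")
  expect_lt(abs(st$flux[["TX_C00122_EFFLUX"]]), FLUX_ZERO_TOL)
  expect_lt(abs(st$flux[["EX_C00122_out"]]), FLUX_ZERO_TOL)
  # second call warns and is a no-op
  expect_warning(m3 <- add_efflux_path(m2, "C00122MM"), "no-op")
  expect_model_identical(m2, m3)
  # non-matrix metabolite is rejected
  expect_error(add_efflux_path(m, "C00031Cyto"), "not a matrix metabolite")
  expect_error(add_efflux_path(m, "C99999MM"), "not a matrix metabolite")
})

test_that("a dead-ended matrix metabolite becomes flux-capable after the edit", {
  # toy: substrate_b -> S -> F(dead-ends in matrix)
  mets <- list(fba_metabolite("S_b"), fba_metabolite("SCyto"),
               fba_metabolite("SMM"), fba_metabolite("C00122MM", "fumarate"))
  rxns <- list(fba_reaction("EX_S_in", c(S_b = -1, SCyto = 1), lb = 0, ub = 2),
               fba_reaction("TX_S", c(SCyto = -1, SMM = 1), lb = 0),
               fba_reaction("RDEAD", c(SMM = -1, C00122MM = 1), lb = 0))
  m <- fba_model(mets, rxns, validate = FALSE)
  expect_true("RDEAD" %in% blocked_reactions(m)$blocked)
  m2 <- add_efflux_path(m, "C00122MM")
  expect_true("RDEAD" %in% blocked_reactions(m2)$capable)
})

test_that("transport steps conserve chemistry across compartments", {
  mm <- build_minimito()
  tr <- mm$rxns$id[mm$rxns$category == "transport"]
  expect_gt(length(tr), 10)
  for (r in tr) {
    st <- mm$stoich[[r]]
    cons <- sort(tapply(abs(st[st < 0]), strip_compartment(names(st[st < 0])), sum))
    prod <- sort(tapply(abs(st[st > 0]), strip_compartment(names(st[st > 0])), sum))
    expect_identical(names(cons), names(prod), info = r)
    expect_equal(as.numeric(cons), as.numeric(prod), info = r)
  }
  # a transport reaction failing conservation is a structural error
  bad <- mm
  bad$stoich$TX_PYR <- c(C00022Cyto = -1, C00026MM = 1)
  expect_gt(length(validate_model(bad)$errors), 0)
})
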