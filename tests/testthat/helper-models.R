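# Shared fixtures and independent oracles for the test suite.

# A three-reaction linear chain A_b -> A -> B -> B_b with configurable
# uptake bound; the terminal exchange is registered as the objective.
chain_model <- function(uptake_ub = 5) {
  mets <- list(fba_metabolite("A_b", "A"), fba_metabolite("ACyto", "A"),
               fba_metabolite("BCyto", "B"), fba_metabolite("B_b", "B"))
  rxns <- list(
    fba_reaction("EX_A_in", c(A_b = -1, ACyto = 1), lb = 0, ub = uptake_ub),
    fba_reaction("RAB", c(ACyto = -1, BCyto = 1), lb = 0),
    fba_reaction("OBJ_B", c(BCyto = -1, B_b = 1), lb = 0,
                 category = "objective_pseudo"))
  fba_model(mets, rxns, list(objective_spec("OBJ_B", "terminal exchange")))
}

# A two-route network where both parallel paths can carry the optimum:
# A_b -> A -> (P1 | P2) -> B -> B_b. Used for alternate-optima tests.
parallel_model <- function(uptake_ub = 4) {
  mets <- list(fba_metabolite("A_b", "A"), fba_metabolite("ACyto", "A"),
               fba_metabolite("MCyto", "M"), fba_metabolite("NCyto", "N"),
               fba_metabolite("BCyto", "B"), fba_metabolite("B_b", "B"))
  rxns <- list(
    fba_reaction("EX_A_in", c(A_b = -1, ACyto = 1), lb = 0, ub = uptake_ub),
    fba_reaction("P1A", c(ACyto = -1, MCyto = 1), lb = 0),
    fba_reaction("P1B", c(MCyto = -1, BCyto = 1), lb = 0),
    fba_reaction("P2A", c(ACyto = -1, NCyto = 1), lb = 0),
    fba_reaction("P2B", c(NCyto = -1, BCyto = 1), lb = 0),
    fba_reaction("OBJ_B", c(BCyto = -1, B_b = 1), lb = 0,
                 category = "objective_pseudo"))
  fba_model(mets, rxns, list(objective_spec("OBJ_B", "terminal exchange")))
}

# Closed-form maximum-ATP yield of the default miniMito fixture, derived by
# active-set bookkeeping before the solver existed (see the methods
# vignette for the derivation). The binding constraints are the oxygen
# uptake and the matrix proton row: every proton returned through the ATP
# synthase rotor (8/3 per ATP) and the phosphate carrier (1 per exported
# ATP) must be re-pumped by the respiratory chain, whose capacity is fixed
# by the oxygen bound.
minimito_atp_closed_form <- function() {
  kk <- list(f = 0.001, g = 0.9, l = 0.5, k = 0.35, c = 0.01, O2 = 19.8)
  with(kk, {
    pyr <- 2 * g + l            # pyruvate supply = shuttle turns s
    s <- pyr
    # T(F) = 4F + pyr + 2k ; N(F) = 3T + 3F + pyr + s + k + c
    aT <- 4; bT <- pyr + 2 * k
    aN <- 3 * aT + 3; bN <- 3 * bT + pyr + s + k + c
    # oxygen: ((1-f)/2 + f) N + (T + 3F)/2 = O2
    w <- (1 - f) / 2 + f
    Fu <- (O2 - w * bN - bT / 2) / (w * aN + (aT + 3) / 2)
    Tv <- aT * Fu + bT
    Nv <- aN * Fu + bN
    QIII <- (1 - f) * Nv + Tv + 3 * Fu
    H <- 4 * (1 - f) * Nv + 6 * QIII   # protons pumped out of the matrix
    # proton return: (8/3) P (rotor) + E (phosphate carrier) + pyruvate
    # import + shuttle, with ANT export E = P + (T - k) - 2F
    P <- (H - (Tv - k - 2 * Fu) - pyr - s) * 3 / 11
    Z <- P + Tv - k - 2 * Fu + 2 * g
    list(atp = Z, tca = Tv, fa_uptake = Fu,
         acetyl_split = c(fatty_acid = 4 * Fu / Tv, pyruvate = pyr / Tv,
                          ketone = 2 * k / Tv))
  })
}

# The same quantity as an exact rational frozen from the pre-registered
# derivation (numerators/denominators well inside 2^31).
MINIMITO_ATP_EXACT <- 609567852 / 6054125   # = 100.68636706377883
MINIMITO_TCA_EXACT <- 3913729 / 550375      # = 7.111022484669544

# Brute-force LP oracle by exhaustive vertex enumeration, for tiny
# problems only (chooses every basis and every nonbasic bound assignment).
# Independent of the simplex implementation under test.
brute_force_lp <- function(obj, A, lb, ub, sense = "max") {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(n <= 10, n - m <= 6)
  best <- NULL
  sgn <- if (sense == "max") 1 else -1
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), basis)
    for (mask in seq_len(2^length(nb)) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_along(nb) - 1L)))
      x <- numeric(n)
      x[nb] <- ifelse(at_ub, ub[nb], lb[nb])
      x[basis] <- solve(B, -A[, nb, drop = FALSE] %*% x[nb])
      if (all(x >= lb - 1e-9) && all(x <= ub + 1e-9)) {
        val <- sum(obj * x)
        if (is.null(best) || sgn * val > sgn * best) best <- val
      }
    }
  }
  best
}

# Independent LP oracle through scipy.optimize.linprog (pre-installed
# python in this environment). Solves max/min c'x s.t. Ax = 0, lb<=x<=ub.
scipy_lp <- function(obj, A, lb, ub, sense = "max") {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite needed for the scipy oracle")
  A <- as.matrix(A)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = as.vector(t(A)), m = nrow(A), n = ncol(A),
                            obj = obj, lb = lb, ub = ub, sense = sense),
                       infile, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(infile)),
    "A = np.array(d['A']).reshape(d['m'], d['n'])",
    "c = np.array(d['obj'], float)",
    "sgn = -1 if d['sense'] == 'max' else 1",
    "r = linprog(sgn*c, A_eq=A, b_eq=np.zeros(d['m']),",
    "            bounds=list(zip(d['lb'], d['ub'])), method='highs')",
    "out = {'status': int(r.status),",
    "       'objval': (sgn*r.fun if r.status == 0 else None)}",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile))),
    script)
  rc <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (rc != 0L) stop("scipy oracle failed to run")
  res <- jsonlite::read_json(outfile)
  list(status = if (res$status == 0) "optimal"
               else if (res$status == 2) "infeasible" else "other",
       objval = if (res$status == 0) as.numeric(res$objval) else NA_real_)
}

# Batched scipy oracle: per-column max and min flux over {Ax=0, lb<=x<=ub},
# all columns in a single python process.
scipy_column_ranges <- function(A, lb, ub) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite needed for the scipy oracle")
  A <- as.matrix(A)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = as.vector(t(A)), m = nrow(A), n = ncol(A),
                            lb = lb, ub = ub),
                       infile, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(infile)),
    "A = np.array(d['A']).reshape(d['m'], d['n'])",
    "bounds = list(zip(d['lb'], d['ub']))",
    "lo, hi = [], []",
    "for j in range(d['n']):",
    "    c = np.zeros(d['n']); c[j] = 1.0",
    "    r1 = linprog(c, A_eq=A, b_eq=np.zeros(d['m']), bounds=bounds, method='highs')",
    "    r2 = linprog(-c, A_eq=A, b_eq=np.zeros(d['m']), bounds=bounds, method='highs')",
    "    lo.append(r1.fun if r1.status == 0 else None)",
    "    hi.append(-r2.fun if r2.status == 0 else None)",
    sprintf("json.dump({'min': lo, 'max': hi}, open(%s, 'w'))",
            deparse(outfile))),
    script)
  rc <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (rc != 0L) stop("scipy oracle failed to run")
  res <- jsonlite::read_json(outfile)
  data.frame(reaction_id = colnames(A),
             min = vapply(res$min, function(x)
               if (is.null(x)) NA_real_ else as.numeric(x), 0),
             max = vapply(res$max, function(x)
               if (is.null(x)) NA_real_ else as.numeric(x), 0),
             stringsAsFactors = FALSE)
}

# structural equality of two models (used by the audit restore properties)
expect_model_identical <- function(a, b) {
  expect_identical(a$mets, b$mets)
  expect_identical(a$rxns, b$rxns)
  expect_identical(a$stoich, b$stoich)
  expect_identical(a$objectives, b$objectives)
}
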