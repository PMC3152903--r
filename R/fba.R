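## Flux balance analysis engine: steady-state LP solves, parsimonious
## reference flux distributions, flux variability and blocked-reaction
## analysis.

#' Global flux-zero threshold
#'
#' Any |flux| at or below this value (umol/min/gDW) is treated as "no flux"
#' wherever an efflux/loop/pathway-activity judgement is made. It sits far
#' below the two-decimal precision of reported physiological fluxes.
#' @export
FLUX_ZERO_TOL <- 1e-6

#' Steady-state feasibility/optimality tolerance
#' @export
FEASIBILITY_TOL <- 1e-9

## Resolve an objective argument (id string or objective_spec) against the
## model's registered objectives.
resolve_objective <- function(model, objective) {
  id <- if (inherits(objective, "objective_spec")) objective$id
        else as.character(objective)
  row <- match(id, model$objectives$id)
  if (is.na(row))
    stop("objective '", id, "' is not registered in the model")
  list(id = id, sense = model$objectives$sense[row])
}

#' Solve the flux balance LP for one objective
#'
#' Maximises (or minimises, per the objective's registered sense) the flux
#' through the objective pseudo-reaction subject to `S v = 0` and the
#' reaction bounds. Columns are fed to the solver in a deterministic order
#' (category, then id), so repeated solves of identical input return the
#' identical vertex.
#'
#' @param model an `fba_model`.
#' @param objective an objective id or [objective_spec()] registered in the
#'   model.
#' @return an object of class `flux_state`: `flux` (named by reaction id),
#'   `objective_id`, `objective_value` and `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`). Infeasibility is reported as a
#'   status, never as silent zeros.
#' @export
fba_optimize <- function(model, objective) {
  obj <- resolve_objective(model, objective)
  Smat <- build_matrix(model)
  ord <- colnames(Smat)
  bd <- model_bounds(model, ord)
  cvec <- as.numeric(ord == obj$id)
  sense <- if (obj$sense == "maximise") "max" else "min"
  sol <- lp_solve(cvec, Smat, NULL, bd$lb, bd$ub, sense = sense)
  if (sol$status != "optimal")
    return(structure(list(flux = NULL, objective_id = obj$id,
                          objective_value = NA_real_, status = sol$status),
                     class = "flux_state"))
  flux <- stats::setNames(sol$x, ord)
  resid <- max(abs(as.vector(Smat %*% sol$x)), 0)
  if (resid > FEASIBILITY_TOL)
    stop("solver returned a solution violating steady state (residual ",
         format(resid), ")")
  structure(list(flux = flux, objective_id = obj$id,
                 objective_value = sol$objval, status = "optimal"),
            class = "flux_state")
}

#' Parsimonious reference flux distribution
#'
#' Among all optima of the chosen objective, returns the flux distribution
#' minimising total absolute flux through non-boundary, non-objective
#' reactions (a two-stage LP, as in parsimonious FBA). This defines "flux
#' under normal conditions" reproducibly: single-stage LP vertices are
#' solver-dependent when alternate optima exist, so all knockdown fractions
#' in this package are expressed relative to this reference.
#'
#' @inheritParams fba_optimize
#' @return a `flux_state`; `objective_value` agrees with [fba_optimize()]
#'   to solver tolerance.
#' @export
reference_fluxes <- function(model, objective) {
  obj <- resolve_objective(model, objective)
  stage1 <- fba_optimize(model, objective)
  if (stage1$status != "optimal") return(stage1)
  zstar <- stage1$objective_value
  Smat <- build_matrix(model)
  ord <- colnames(Smat)
  bd <- model_bounds(model, ord)
  ## pin the objective flux at its optimum
  j <- match(obj$id, ord)
  bd$lb[j] <- zstar - FEASIBILITY_TOL
  bd$ub[j] <- zstar + FEASIBILITY_TOL
  ## split v = p - q, p,q >= 0; minimise sum of p+q over internal reactions
  idx <- match(ord, model$rxns$id)
  internal <- !(model$rxns$category[idx] %in% c("boundary", "objective_pseudo"))
  n <- length(ord)
  A2 <- cbind(as.matrix(Smat), -as.matrix(Smat))
  lb2 <- c(pmax(bd$lb, 0), pmax(-bd$ub, 0))
  ub2 <- c(pmax(bd$ub, 0), pmax(-bd$lb, 0))
  cost <- c(as.numeric(internal), as.numeric(internal))
  sol <- lp_solve(cost, A2, NULL, lb2, ub2, sense = "min")
  if (sol$status != "optimal")
    stop("parsimonious stage is ", sol$status,
         " although the first stage was optimal")
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  flux <- stats::setNames(v, ord)
  resid <- max(abs(as.vector(Smat %*% v)), 0)
  if (resid > FEASIBILITY_TOL)
    stop("parsimonious solution violates steady state (residual ",
         format(resid), ")")
  structure(list(flux = flux, objective_id = obj$id,
                 objective_value = flux[[obj$id]], status = "optimal"),
            class = "flux_state")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective retaining
#' at least `fraction` of its optimum. Quantifies alternate optima: a
#' reported flux is only meaningfully comparable to an external figure when
#' its variability range at `fraction = 1` is narrow.
#'
#' @inheritParams fba_optimize
#' @param fraction required fraction (0-1) of the optimal objective value.
#' @param reactions optional character vector restricting the analysis.
#' @return a data frame with `reaction_id`, `min`, `max`; both endpoints are
#'   certified by an optimal LP solve.
#' @export
flux_variability <- function(model, objective, fraction = 1,
                             reactions = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  obj <- resolve_objective(model, objective)
  stage1 <- fba_optimize(model, objective)
  if (stage1$status != "optimal")
    stop("model is ", stage1$status, " for objective ", obj$id)
  zstar <- stage1$objective_value
  Smat <- build_matrix(model)
  ord <- colnames(Smat)
  bd <- model_bounds(model, ord)
  j <- match(obj$id, ord)
  tol_z <- FEASIBILITY_TOL * (1 + abs(zstar))
  if (obj$sense == "maximise") {
    target <- if (zstar >= 0) fraction * zstar else zstar / max(fraction, 1e-12)
    bd$lb[j] <- max(bd$lb[j], target - tol_z)
  } else {
    target <- if (zstar >= 0) zstar / max(fraction, 1e-12) else fraction * zstar
    bd$ub[j] <- min(bd$ub[j], target + tol_z)
  }
  if (is.null(reactions)) reactions <- ord
  missing <- setdiff(reactions, ord)
  if (length(missing))
    stop("unknown reactions: ", paste(missing, collapse = ", "))
  A <- as.matrix(Smat)
  res <- lapply(reactions, function(r) {
    cvec <- as.numeric(ord == r)
    lo <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "min")
    hi <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", r)
    c(lo$objval, hi$objval)
  })
  out <- data.frame(reaction_id = reactions,
                    min = vapply(res, `[`, 0, 1L),
                    max = vapply(res, `[`, 0, 2L),
                    stringsAsFactors = FALSE)
  ## numerically a min can exceed a max by round-off only
  swap <- out$min > out$max
  if (any(swap)) {
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid
    out$max[swap] <- mid
  }
  out
}

#' Partition reactions into flux-capable and blocked
#'
#' A reaction is capable iff it can carry |flux| above the global flux-zero
#' threshold somewhere in the feasible region (at most two LPs per
#' reaction). The partition is exhaustive and invariant under reaction
#' reordering.
#'
#' @param model an `fba_model`.
#' @param reactions optional subset of reaction ids (default: all).
#' @return a list with character vectors `capable` and `blocked`.
#' @export
blocked_reactions <- function(model, reactions = NULL) {
  Smat <- build_matrix(model)
  ord <- colnames(Smat)
  bd <- model_bounds(model, ord)
  if (is.null(reactions)) reactions <- ord
  A <- as.matrix(Smat)
  capable <- logical(length(reactions))
  for (k in seq_along(reactions)) {
    r <- reactions[k]
    cvec <- as.numeric(ord == r)
    hi <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "max")
    if (hi$status == "optimal" && hi$objval > FLUX_ZERO_TOL) {
      capable[k] <- TRUE
      next
    }
    lo <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "min")
    capable[k] <- lo$status == "optimal" && lo$objval < -FLUX_ZERO_TOL
  }
  list(capable = sort(reactions[capable]),
       blocked = sort(reactions[!capable]))
}

#' @export
print.flux_state <- function(x, ...) {
  cat("Flux state (objective ", x$objective_id, "): ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  objective value: %.6g umol/min/gDW\n", x$objective_value))
    nz <- sum(abs(x$flux) > FLUX_ZERO_TOL)
    cat(sprintf("  %d of %d reactions carry flux above %g\n",
                nz, length(x$flux), FLUX_ZERO_TOL))
  }
  invisible(x)
}

#' @export
summary.flux_state <- function(object, ...) {
  if (object$status != "optimal") return(print(object))
  flux <- sort(abs(object$flux), decreasing = TRUE)
  cat("Objective", object$objective_id, "=",
      format(object$objective_value, digits = 8), "umol/min/gDW\n")
  cat("Largest fluxes:\n")
  print(utils::head(flux, 10))
  invisible(object)
}
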