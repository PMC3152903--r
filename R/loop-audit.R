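## Thermodynamically infeasible internal loop audits.
##
## An internal flux loop (a type II/III extreme pathway) is a circulation
## that carries flux with no net exchange across the system boundary. With
## every boundary condition constrained to zero, all fluxes should be zero;
## any feasible nonzero flux is a loop. Objective pseudo-reaction drains are
## zeroed as well, because an open drain would act as a boundary.

## Return a copy of the model with boundary and objective pseudo-reaction
## bounds constrained to zero.
zero_boundaries <- function(model) {
  sel <- model$rxns$category %in% c("boundary", "objective_pseudo")
  model$rxns$lb[sel] <- 0
  model$rxns$ub[sel] <- 0
  model
}

#' Objective-driven internal loop audit
#'
#' Emulates the classic audit: constrain all boundary conditions (and
#' objective drains) to zero, run a simulation under each objective and
#' report every internal reaction still carrying flux. Because a simplex
#' vertex chosen under a zero-valued objective is arbitrary, the audit is
#' made deterministic and adversarial: after fixing the (necessarily zero)
#' objective optimum, total internal flux is maximised, so any forward-
#' orientable circulation is surfaced rather than left to solver chance.
#' [probe_loop_capacity()] is the stronger, orientation-complete check.
#'
#' @param model an `fba_model` (never modified).
#' @param objectives character vector of objective ids (default: all
#'   registered).
#' @return an object of class `loop_report`: `per_objective` (named list of
#'   data frames with `reaction_id`, `flux`), `loop_free` (logical), and
#'   `structural_errors` (reactions whose bounds force nonzero flux).
#' @export
find_internal_loops <- function(model, objectives = model$objectives$id) {
  ## any reaction whose bounds exclude zero cannot be silent under closed
  ## boundaries: that is a structural error, not a loop
  forced <- model$rxns$id[model$rxns$lb > 0 | model$rxns$ub < 0]
  zm <- zero_boundaries(model)
  Smat <- build_matrix(zm)
  ord <- colnames(Smat)
  bd <- model_bounds(zm, ord)
  A <- as.matrix(Smat)
  idx <- match(ord, zm$rxns$id)
  internal <- !(zm$rxns$category[idx] %in% c("boundary", "objective_pseudo"))
  per <- list()
  for (o in objectives) {
    obj <- resolve_objective(model, o)
    cvec <- as.numeric(ord == obj$id)
    s1 <- lp_solve(cvec, A, NULL, bd$lb, bd$ub,
                   sense = if (obj$sense == "maximise") "max" else "min")
    if (s1$status != "optimal") {
      per[[o]] <- data.frame(reaction_id = NA_character_, flux = NA_real_)
      next
    }
    ## adversarial second stage: maximise total internal flux at the fixed
    ## (zero) objective value
    bd2 <- bd
    j <- match(obj$id, ord)
    bd2$lb[j] <- s1$objval - FEASIBILITY_TOL
    bd2$ub[j] <- s1$objval + FEASIBILITY_TOL
    s2 <- lp_solve(as.numeric(internal), A, NULL, bd2$lb, bd2$ub, sense = "max")
    v <- if (s2$status == "optimal") s2$x else s1$x
    hit <- internal & abs(v) > FLUX_ZERO_TOL
    per[[o]] <- data.frame(reaction_id = ord[hit], flux = v[hit],
                           stringsAsFactors = FALSE)
  }
  structure(list(per_objective = per,
                 loop_free = length(forced) == 0L &&
                   all(vapply(per, nrow, 0L) == 0L),
                 structural_errors = forced,
                 kind = "objective-driven audit"),
            class = "loop_report")
}

#' Per-reaction loop-capacity probe
#'
#' The orientation-complete audit: with all boundaries and objective drains
#' zeroed, each internal reaction's flux is maximised and minimised in
#' turn. Any reaction able to carry |flux| above the global threshold under
#' these conditions participates in an internal circulation. An empty probe
#' report implies the objective-driven audit is empty for every objective.
#'
#' @param model an `fba_model` (never modified).
#' @return a `loop_report`; `per_objective` holds a single `"probe"` entry
#'   listing every loop-capable reaction with its extremal flux.
#' @export
probe_loop_capacity <- function(model) {
  forced <- model$rxns$id[model$rxns$lb > 0 | model$rxns$ub < 0]
  zm <- zero_boundaries(model)
  internal_ids <- zm$rxns$id[!(zm$rxns$category %in%
                               c("boundary", "objective_pseudo"))]
  part <- blocked_reactions(zm, internal_ids)
  loopy <- part$capable
  flux <- numeric(length(loopy))
  if (length(loopy)) {
    Smat <- build_matrix(zm)
    ord <- colnames(Smat)
    bd <- model_bounds(zm, ord)
    A <- as.matrix(Smat)
    for (k in seq_along(loopy)) {
      cvec <- as.numeric(ord == loopy[k])
      hi <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "max")
      flux[k] <- hi$objval
      if (abs(flux[k]) <= FLUX_ZERO_TOL) {
        lo <- lp_solve(cvec, A, NULL, bd$lb, bd$ub, sense = "min")
        flux[k] <- lo$objval
      }
    }
  }
  per <- list(probe = data.frame(reaction_id = loopy, flux = flux,
                                 stringsAsFactors = FALSE))
  structure(list(per_objective = per,
                 loop_free = length(forced) == 0L && length(loopy) == 0L,
                 structural_errors = forced,
                 kind = "per-reaction capacity probe"),
            class = "loop_report")
}

#' Re-verify flux capability after directionality edits
#'
#' Companion audit to the loop checks: with the *normal* boundary
#' constraints in place, partitions reactions into flux-capable and
#' blocked, so that directionality constraints added to remove loops can be
#' shown not to have silenced parts of the network.
#'
#' @param model an `fba_model`.
#' @return the [blocked_reactions()] partition.
#' @export
verify_flux_capability <- function(model) {
  blocked_reactions(model)
}

#' @export
print.loop_report <- function(x, ...) {
  cat("Internal-loop audit (", x$kind, ")\n", sep = "")
  if (length(x$structural_errors))
    cat("  structural errors (bounds force nonzero flux):",
        paste(x$structural_errors, collapse = ", "), "\n")
  for (nm in names(x$per_objective)) {
    d <- x$per_objective[[nm]]
    if (nrow(d))
      cat(sprintf("  %s: %d loop-capable reactions (max |flux| %.3g)\n",
                  nm, nrow(d), max(abs(d$flux))))
  }
  cat("  verdict:", if (x$loop_free) "loop-free" else "LOOPS PRESENT", "\n")
  invisible(x)
}

#' Serialise a loop report as TSV
#'
#' @param report a `loop_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loop_report <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report$per_objective), function(nm) {
    d <- report$per_objective[[nm]]
    if (!nrow(d)) return(NULL)
    cbind(objective = nm, d)
  }))
  if (is.null(rows))
    rows <- data.frame(objective = character(), reaction_id = character(),
                       flux = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
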