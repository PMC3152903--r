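## Disease simulation: knockdown scans over residual-flux fractions,
## efflux-onset threshold searches, one-at-a-time boundary relief scans,
## efflux profiling and pathway activity flags.

#' Disease presets for the three TCA-cycle disorders
#'
#' Each preset names the constrained reaction(s), any model edit required
#' (fumarase deficiency needs an added fumarate efflux path, since the
#' unmodified network has no mechanism for fumarate to leave), the default
#' residual-flux fractions scanned, and the bypass reactions whose activity
#' is tracked.
#'
#' @param name one of `"fumarase"`, `"sdh"` (succinate dehydrogenase),
#'   `"ogdh"` (alpha-ketoglutarate dehydrogenase) or `"ogdh_e3"` (the E3 /
#'   dihydrolipoamide dehydrogenase subunit variant).
#' @return a list of class `disease_preset`.
#' @export
disease_preset <- function(name = c("fumarase", "sdh", "ogdh", "ogdh_e3")) {
  name <- match.arg(name)
  preset <- switch(name,
    fumarase = list(reactions = "R01082MM",
                    efflux_metabolite = "C00122MM",
                    tracked = character()),
    sdh = list(reactions = "R02164MM",
               efflux_metabolite = NULL,
               tracked = character()),
    ogdh = list(reactions = "R01700MM",
                efflux_metabolite = NULL,
                tracked = c("R01648MM", "R00261MM", "R00713MM")),
    ogdh_e3 = list(reactions = c("R01700MM", "R07618MM"),
                   efflux_metabolite = NULL,
                   tracked = c("R01648MM", "R00261MM", "R00713MM")))
  structure(c(list(name = name), preset,
              list(default_fractions = c(1, 0.33, 0))),
            class = "disease_preset")
}

#' Apply a disease preset's structural edits to a model
#'
#' Performs the model edits a preset requires (currently: the fumarate
#' efflux path for fumarase deficiency) without constraining any reaction.
#' Constraining is done by [knockdown_scan()] relative to the reference
#' flux of the *edited but unperturbed* model.
#'
#' @param model an `fba_model`.
#' @param preset a [disease_preset()].
#' @return the edited model.
#' @export
apply_preset <- function(model, preset) {
  stopifnot(inherits(preset, "disease_preset"))
  missing <- setdiff(preset$reactions, model$rxns$id)
  if (length(missing))
    stop("model lacks preset reaction(s): ", paste(missing, collapse = ", "))
  if (!is.null(preset$efflux_metabolite))
    model <- add_efflux_path(model, preset$efflux_metabolite)
  model
}

## clamp a reaction to a fraction of its reference flux, preserving the
## direction of the reference (residual enzyme activity cannot reverse a
## physiologically one-way step)
clamp_to_fraction <- function(model, reaction_id, fraction, reference_flux) {
  i <- match(reaction_id, model$rxns$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  target <- fraction * reference_flux
  model$rxns$lb[i] <- min(0, target)
  model$rxns$ub[i] <- max(0, target)
  model
}

#' Knockdown scan over residual-flux fractions
#'
#' At each fraction `f`, the reaction's bounds are clamped to
#' `[min(0, f * ref), max(0, f * ref)]` where `ref` is its flux in the
#' parsimonious reference distribution ([reference_fluxes()]) of the
#' unperturbed model, and the objective is re-optimised. Infeasible points
#' are recorded as such and the scan continues. The input model is never
#' modified.
#'
#' @param model an `fba_model` (with any preset edits already applied).
#' @param reaction_id the reaction to constrain.
#' @param fractions numeric vector in `[0, 1]`.
#' @param objective objective id or spec.
#' @return an object of class `scan_result`: a data frame (`fraction`,
#'   `objective_value`, `status`) with the per-point efflux profiles and
#'   flux states attached as attributes, plus `reference_flux`.
#' @export
knockdown_scan <- function(model, reaction_id, fractions, objective) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  ref <- reference_fluxes(model, objective)
  if (ref$status != "optimal")
    stop("cannot establish reference fluxes: model is ", ref$status)
  r0 <- ref$flux[[reaction_id]]
  states <- vector("list", length(fractions))
  vals <- rep(NA_real_, length(fractions))
  stat <- character(length(fractions))
  for (i in seq_along(fractions)) {
    pm <- clamp_to_fraction(model, reaction_id, fractions[i], r0)
    st <- fba_optimize(pm, objective)
    states[[i]] <- st
    stat[i] <- st$status
    if (st$status == "optimal") vals[i] <- st$objective_value
  }
  out <- data.frame(fraction = fractions, objective_value = vals,
                    status = stat, stringsAsFactors = FALSE)
  structure(out,
            class = c("scan_result", "data.frame"),
            swept = "fraction",
            reaction_id = reaction_id,
            objective_id = resolve_objective(model, objective)$id,
            reference_flux = r0,
            states = states,
            effluxes = lapply(states, function(s)
              if (s$status == "optimal") efflux_profile(model, s) else NULL))
}

#' Largest residual-flux fraction at which an event holds
#'
#' Scans a 1 % grid of knockdown fractions and refines the boundary by
#' bisection to 0.1 %, returning the largest fraction at which the event
#' predicate is true. The event is assumed monotone in the fraction (true
#' below the threshold); monotonicity over the grid is checked empirically
#' and violations raise a warning naming the offending points.
#'
#' @param model an `fba_model` (preset edits applied).
#' @param reaction_id reaction being knocked down.
#' @param event predicate `function(model, flux_state) -> logical`; see
#'   [event_efflux()] and [event_pathway_inactive()].
#' @param objective objective id or spec.
#' @param grid fraction grid (default 1 % steps from 0 to 1).
#' @param refine_to bisection resolution (default 0.001).
#' @return the largest fraction (to the requested resolution) at which the
#'   event holds, or `NA` with message `"none in [0,1]"` if it never does.
#' @export
threshold_search <- function(model, reaction_id, event, objective,
                             grid = seq(0, 1, by = 0.01),
                             refine_to = 0.001) {
  ref <- reference_fluxes(model, objective)
  if (ref$status != "optimal")
    stop("cannot establish reference fluxes: model is ", ref$status)
  r0 <- ref$flux[[reaction_id]]
  holds_at <- function(f) {
    st <- fba_optimize(clamp_to_fraction(model, reaction_id, f, r0), objective)
    if (st$status != "optimal") return(NA)
    isTRUE(event(model, st))
  }
  grid <- sort(grid)
  ok <- vapply(grid, holds_at, NA)
  if (!any(ok, na.rm = TRUE)) {
    out <- NA_real_
    attr(out, "message") <- "none in [0,1]"
    return(out)
  }
  ## monotone event: true on a lower interval of fractions
  known <- !is.na(ok)
  if (is.unsorted(rev(ok[known])))
    warning("event is not monotone over the scan grid at fractions: ",
            paste(grid[known][which(diff(ok[known]) == 1L)], collapse = ", "))
  hi_true <- max(grid[known & ok])
  above <- grid[known & grid > hi_true & !ok]
  if (!length(above)) return(hi_true)
  lo <- hi_true
  hi <- min(above)
  while (hi - lo > refine_to) {
    mid <- (lo + hi) / 2
    h <- holds_at(mid)
    if (isTRUE(h)) lo <- mid else hi <- mid
  }
  lo
}

#' Event: a metabolite is effluxed from the system
#'
#' @param chem compartment-free chemical id (e.g. `"C00122"` for fumarate)
#'   or full boundary-exchange reaction id.
#' @return a predicate for [threshold_search()].
#' @export
event_efflux <- function(chem) {
  function(model, state) {
    prof <- efflux_profile(model, state)
    chem %in% names(prof) && prof[[chem]] > FLUX_ZERO_TOL
  }
}

#' Event: a named pathway carries no flux
#'
#' @param pathway pathway name (see [minimito_pathways()]) or character
#'   vector of reaction ids.
#' @param pathways named list of pathway reaction sets.
#' @return a predicate for [threshold_search()].
#' @export
event_pathway_inactive <- function(pathway, pathways = minimito_pathways()) {
  function(model, state) !pathway_activity(state, pathway, pathways)
}

#' One-at-a-time boundary relief scan
#'
#' With a disease preset applied at a given residual fraction, each listed
#' boundary condition is released in turn (to the sentinel, or to an
#' explicit trial value such as 5 umol/min/gDW), the objective re-optimised
#' and the change in objective and the efflux profile recorded. All other
#' boundaries keep their normal constraints and the model is restored
#' between trials.
#'
#' @param model an `fba_model` (preset edits applied, unperturbed).
#' @param reaction_id the preset's constrained reaction.
#' @param fraction residual-flux fraction for the preset reaction.
#' @param boundaries character vector of boundary reaction ids to release.
#' @param objective objective id or spec.
#' @param release_to numeric release value(s) for the upper bound, recycled
#'   over `boundaries`; default the sentinel.
#' @return a `scan_result` data frame (`boundary_id`, `release_to`,
#'   `objective_value`, `delta`, `status`) with efflux profiles attached;
#'   `delta` is relative to the perturbed-but-unrelieved baseline.
#' @export
uptake_relief_scan <- function(model, reaction_id, fraction, boundaries,
                               objective,
                               release_to = FLUX_BOUND_SENTINEL) {
  missing <- setdiff(boundaries, model$rxns$id)
  if (length(missing))
    stop("unknown boundary reactions: ", paste(missing, collapse = ", "))
  release_to <- rep_len(release_to, length(boundaries))
  ref <- reference_fluxes(model, objective)
  if (ref$status != "optimal")
    stop("cannot establish reference fluxes: model is ", ref$status)
  r0 <- ref$flux[[reaction_id]]
  base_model <- clamp_to_fraction(model, reaction_id, fraction, r0)
  base <- fba_optimize(base_model, objective)
  base_val <- if (base$status == "optimal") base$objective_value else NA_real_
  vals <- rep(NA_real_, length(boundaries))
  stat <- character(length(boundaries))
  states <- vector("list", length(boundaries))
  for (i in seq_along(boundaries)) {
    pm <- base_model
    j <- match(boundaries[i], pm$rxns$id)
    pm$rxns$ub[j] <- max(pm$rxns$ub[j], release_to[i])
    st <- fba_optimize(pm, objective)
    states[[i]] <- st
    stat[i] <- st$status
    if (st$status == "optimal") vals[i] <- st$objective_value
  }
  out <- data.frame(boundary_id = boundaries, release_to = release_to,
                    objective_value = vals, delta = vals - base_val,
                    status = stat, stringsAsFactors = FALSE)
  structure(out,
            class = c("scan_result", "data.frame"),
            swept = "boundary",
            reaction_id = reaction_id,
            fraction = fraction,
            objective_id = resolve_objective(model, objective)$id,
            baseline = base_val,
            states = states,
            effluxes = lapply(states, function(s)
              if (s$status == "optimal") efflux_profile(model, s) else NULL))
}

#' Efflux profile of a solved state
#'
#' All boundary exchanges carrying flux in the efflux direction above the
#' global threshold, keyed by compartment-free chemical id and sorted in
#' decreasing order. The direction of each boundary exchange is read from
#' its stoichiometry: positive flux towards the boundary species is efflux;
#' flux of an uptake-written exchange never counts as efflux.
#'
#' @param model the `fba_model` the state was solved on.
#' @param state an optimal `flux_state`.
#' @return a named numeric vector (possibly empty).
#' @export
efflux_profile <- function(model, state) {
  if (!inherits(state, "flux_state") || state$status != "optimal")
    stop("efflux_profile requires an optimal flux_state")
  sel <- which(model$rxns$category == "boundary")
  out <- numeric(0)
  for (i in sel) {
    rid <- model$rxns$id[i]
    v <- state$flux[[rid]]
    if (is.null(v) || is.na(v)) next
    st <- model$stoich[[rid]]
    bcoef <- st[compartment_of(names(st)) == "boundary"]
    if (!length(bcoef)) next
    eff <- v * sign(bcoef[[1L]])   # flux towards the boundary species
    if (eff > FLUX_ZERO_TOL) {
      chem <- strip_compartment(names(bcoef)[1L])
      out[chem] <- if (chem %in% names(out)) out[[chem]] + eff else eff
    }
  }
  sort(out, decreasing = TRUE)
}

#' Named pathway reaction sets of the miniMito fixture
#'
#' @return a named list of character vectors of reaction ids.
#' @export
minimito_pathways <- function() {
  list(
    tca_cycle = c("R00351MM", "R01324MM", "R00709MM", "R01700MM",
                  "R00405MM", "R02164MM", "R01082MM", "R00342MM"),
    fatty_acid_oxidation = c("FAOXMM"),
    ketone_body_degradation = c("KBDMM"),
    gaba_shunt = c("R00261MM", "R01648MM", "R00713MM"),
    malate_aspartate_shuttle = c("TX_MALOG", "TX_ASPGLU"),
    electron_transport_chain = c("CXIMM", "CXIIIMM", "CXIVMM"))
}

#' Is a pathway active in a solved state?
#'
#' @param state an optimal `flux_state`.
#' @param pathway pathway name (resolved against `pathways`) or character
#'   vector of reaction ids.
#' @param pathways named list of pathway reaction sets (default
#'   [minimito_pathways()]).
#' @return `TRUE` iff any member reaction carries |flux| above the global
#'   threshold.
#' @export
pathway_activity <- function(state, pathway, pathways = minimito_pathways()) {
  if (!inherits(state, "flux_state") || state$status != "optimal")
    stop("pathway_activity requires an optimal flux_state")
  if (length(pathway) == 1L && pathway %in% names(pathways))
    pathway <- pathways[[pathway]]
  else if (length(pathway) == 1L && !pathway %in% names(state$flux))
    stop("unknown pathway name: ", pathway)
  missing <- setdiff(pathway, names(state$flux))
  if (length(missing))
    stop("pathway reactions absent from the model: ",
         paste(missing, collapse = ", "))
  any(abs(state$flux[pathway]) > FLUX_ZERO_TOL)
}

#' @export
print.scan_result <- function(x, ...) {
  sw <- attr(x, "swept")
  if (identical(sw, "fraction")) {
    cat(sprintf("Knockdown scan of %s (objective %s), reference flux %.4g\n",
                attr(x, "reaction_id"), attr(x, "objective_id"),
                attr(x, "reference_flux")))
  } else {
    cat(sprintf(
      "Relief scan at fraction %.3g of %s (objective %s), baseline %.4g\n",
      attr(x, "fraction"), attr(x, "reaction_id"),
      attr(x, "objective_id"), attr(x, "baseline")))
  }
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Serialise a scan result as TSV (one row per scan point)
#'
#' @param scan a `scan_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(scan, path) {
  d <- as.data.frame(scan)
  eff <- attr(scan, "effluxes")
  d$effluxes <- vapply(seq_len(nrow(d)), function(i) {
    e <- eff[[i]]
    if (is.null(e) || !length(e)) return("")
    paste(sprintf("%s:%.6g", names(e), e), collapse = ",")
  }, "")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
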