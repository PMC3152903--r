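## Core domain model: a two-compartment (mitochondrial matrix / cytosol)
## metabolic network with boundary species, flux bounds and objective
## pseudo-reactions.
##
## Identifier convention, following common usage for compartmentalised
## mitochondrial reconstructions: metabolite and reaction ids carry a
## compartment suffix -- "MM" for the mitochondrial matrix, "Cyto" for the
## cytosol and "_b" for system-boundary species.

#' Sentinel flux bound for practically unconstrained reactions
#'
#' Flux bounds are expressed in umol/min/gDW. Truly unconstrained bounds are
#' represented internally by +/- 1000 umol/min/gDW because the LP solver
#' requires finite bounds; no physiological flux in this problem domain
#' approaches this value.
#' @export
FLUX_BOUND_SENTINEL <- 1000

#' Infer the compartment of a metabolite id from its suffix
#'
#' @param id character vector of metabolite ids.
#' @return character vector: `"matrix"`, `"cytosol"`, `"boundary"` or `NA`
#'   when the suffix matches no convention.
#' @export
compartment_of <- function(id) {
  out <- rep(NA_character_, length(id))
  out[endsWith(id, "_b")] <- "boundary"
  out[is.na(out) & endsWith(id, "MM")] <- "matrix"
  out[is.na(out) & endsWith(id, "Cyto")] <- "cytosol"
  out
}

#' Strip the compartment suffix from a metabolite id
#' @param id character vector of metabolite ids.
#' @return the chemical (compartment-free) part of each id.
#' @export
strip_compartment <- function(id) {
  sub("(MM|Cyto|_b)$", "", id)
}

#' Construct a metabolite
#'
#' @param id metabolite id with compartment suffix (KEGG compound id where
#'   available, e.g. `"C00122MM"`).
#' @param name human-readable name.
#' @param compartment one of `"matrix"`, `"cytosol"`, `"boundary"`; inferred
#'   from the id suffix when omitted.
#' @param proton_count protons of the major microspecies at the compartment
#'   pH (optional, used by [rebalance_protons()]).
#' @param formula chemical formula (optional).
#' @return a list of class `fba_metabolite`.
#' @export
fba_metabolite <- function(id, name = id, compartment = compartment_of(id),
                           proton_count = NA_integer_, formula = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.na(compartment))
    stop("metabolite id '", id, "' has no recognisable compartment suffix")
  if (!is.na(compartment_of(id)) && compartment_of(id) != compartment)
    stop("metabolite id '", id, "' suffix contradicts compartment '",
         compartment, "'")
  structure(list(id = id, name = name, compartment = compartment,
                 proton_count = as.integer(proton_count),
                 formula = formula),
            class = "fba_metabolite")
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative for consumed species,
#' positive for produced species. Coefficients may be given exactly as
#' rationals (e.g. `8/3`); they are stored as doubles but originate from
#' exact expressions in the fixture generators.
#'
#' @param id reaction id (KEGG reaction id plus compartment suffix where
#'   applicable, e.g. `"R01082MM"`).
#' @param stoich named numeric vector, names are metabolite ids.
#' @param lb,ub flux bounds in umol/min/gDW.
#' @param category one of `"matrix"`, `"cytosolic"`, `"transport"`,
#'   `"boundary"`, `"objective_pseudo"`, `"unknown"`; inferred from the
#'   stoichiometry and id suffixes when omitted.
#' @param note free-text provenance for the directionality assignment.
#' @return a list of class `fba_reaction`.
#' @export
fba_reaction <- function(id, stoich, lb = -FLUX_BOUND_SENTINEL,
                         ub = FLUX_BOUND_SENTINEL, category = NULL,
                         note = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(stoich), !is.null(names(stoich)),
            all(nzchar(names(stoich))))
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  stoich <- stoich[stoich != 0]
  if (!is.finite(lb) || !is.finite(ub))
    stop("reaction '", id, "': bounds must be finite (use the sentinel)")
  if (lb > ub)
    stop("reaction '", id, "': lb > ub")
  if (is.null(category)) category <- infer_reaction_category(id, stoich)
  structure(list(id = id, stoich = stoich, lb = as.numeric(lb),
                 ub = as.numeric(ub), category = category, note = note),
            class = "fba_reaction")
}

#' Infer a reaction's category from its stoichiometry and id conventions
#'
#' Rules, applied in order: a reaction touching a boundary (`_b`) species or
#' with a single participant is a `boundary` exchange; a reaction whose
#' consumed and produced species are chemically identical and differ only in
#' compartment is a `transport` step; otherwise any reaction with matrix
#' species is `matrix` chemistry (this covers membrane-spanning pumps),
#' a purely cytosolic reaction is `cytosolic`, and anything else is
#' `unknown` (with a warning at validation time).
#'
#' @param id reaction id.
#' @param stoich named signed stoichiometry vector.
#' @param objective_ids ids registered as objective pseudo-reactions.
#' @return a category string.
#' @export
infer_reaction_category <- function(id, stoich, objective_ids = character()) {
  mets <- names(stoich)
  comp <- compartment_of(mets)
  if (id %in% objective_ids || grepl("^OBJ", id)) return("objective_pseudo")
  if (any(comp == "boundary", na.rm = TRUE) || length(mets) == 1L)
    return("boundary")
  if (is_transport_stoich(stoich)) return("transport")
  if (any(comp == "matrix", na.rm = TRUE)) return("matrix")
  if (all(comp == "cytosol", na.rm = TRUE) && !anyNA(comp)) return("cytosolic")
  "unknown"
}

## TRUE when consumed and produced species are the same chemical multiset,
## differing only in compartment.
is_transport_stoich <- function(stoich) {
  comp <- compartment_of(names(stoich))
  if (length(unique(comp[!is.na(comp) & comp != "boundary"])) < 2L) return(FALSE)
  cons <- stoich[stoich < 0]
  prod <- stoich[stoich > 0]
  key <- function(v) {
    k <- tapply(abs(v), strip_compartment(names(v)), sum)
    k <- k[order(names(k))]
    paste(names(k), signif(k, 12), collapse = ";")
  }
  length(cons) > 0 && length(prod) > 0 && key(cons) == key(prod)
}

#' Construct an objective specification
#'
#' Each objective is a registered pseudo-reaction whose flux is maximised
#' (or minimised) in a simulation; exactly one objective is active per LP
#' solve.
#'
#' @param id id of the objective pseudo-reaction.
#' @param description what the pseudo-reaction demands (e.g. "ATP
#'   production").
#' @param sense `"maximise"` or `"minimise"`.
#' @return a list of class `objective_spec`.
#' @export
objective_spec <- function(id, description = id, sense = "maximise") {
  sense <- match.arg(sense, c("maximise", "minimise"))
  structure(list(id = id, description = description, sense = sense),
            class = "objective_spec")
}

#' Assemble a constraint-based model
#'
#' @param metabolites list of [fba_metabolite()] objects.
#' @param reactions list of [fba_reaction()] objects.
#' @param objectives list of [objective_spec()] objects; every objective id
#'   must name a reaction of category `objective_pseudo`.
#' @param ph named numeric vector of compartment pH values (defaults to the
#'   physiological matrix pH 8.05 and cytosolic pH 7.3).
#' @param metadata free-text provenance.
#' @param validate run [validate_model()] and stop on structural errors.
#' @return an object of class `fba_model` with components `mets` (data
#'   frame), `rxns` (data frame), `stoich` (named list of named numeric
#'   vectors), `objectives` (data frame), `ph` and `metadata`.
#' @export
fba_model <- function(metabolites, reactions, objectives = list(),
                      ph = c(matrix = 8.05, cytosol = 7.3),
                      metadata = "", validate = TRUE) {
  mets <- data.frame(
    id = vapply(metabolites, `[[`, "", "id"),
    name = vapply(metabolites, `[[`, "", "name"),
    compartment = vapply(metabolites, `[[`, "", "compartment"),
    proton_count = vapply(metabolites, function(m)
      as.integer(m$proton_count), integer(1)),
    formula = vapply(metabolites, function(m)
      as.character(m$formula), character(1)),
    stringsAsFactors = FALSE)
  obj <- if (length(objectives)) data.frame(
    id = vapply(objectives, `[[`, "", "id"),
    description = vapply(objectives, `[[`, "", "description"),
    sense = vapply(objectives, `[[`, "", "sense"),
    stringsAsFactors = FALSE)
  else data.frame(id = character(), description = character(),
                  sense = character(), stringsAsFactors = FALSE)
  ## re-infer categories now that objective registration is known
  rxns <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    lb = vapply(reactions, `[[`, 0, "lb"),
    ub = vapply(reactions, `[[`, 0, "ub"),
    category = vapply(reactions, function(r)
      if (r$id %in% obj$id) "objective_pseudo" else r$category, ""),
    note = vapply(reactions, function(r) as.character(r$note), ""),
    stringsAsFactors = FALSE)
  stoich <- lapply(reactions, `[[`, "stoich")
  names(stoich) <- rxns$id
  model <- structure(list(mets = mets, rxns = rxns, stoich = stoich,
                          objectives = obj, ph = ph, metadata = metadata),
                     class = "fba_model")
  if (validate) {
    v <- validate_model(model)
    if (length(v$errors))
      stop("model fails structural validation:\n  ",
           paste(v$errors, collapse = "\n  "))
  }
  model
}

#' Structurally validate a model
#'
#' Checks id uniqueness, compartment-suffix agreement, bound sanity,
#' transport-step chemical conservation, boundary-exchange shape, objective
#' registration and reports orphan metabolites and per-category reaction
#' counts. Orphans are reported as warnings (a model under construction may
#' legitimately contain them); structural inconsistencies are errors.
#'
#' @param model an `fba_model`.
#' @return a list with `errors`, `warnings`, `counts` (reactions per
#'   category), `n_metabolites`, `n_reactions` and `orphans`.
#' @export
validate_model <- function(model) {
  errors <- character()
  warns <- character()
  mets <- model$mets
  rxns <- model$rxns
  if (anyDuplicated(mets$id))
    errors <- c(errors, paste("duplicated metabolite ids:",
                              paste(unique(mets$id[duplicated(mets$id)]),
                                    collapse = ", ")))
  if (anyDuplicated(rxns$id))
    errors <- c(errors, paste("duplicated reaction ids:",
                              paste(unique(rxns$id[duplicated(rxns$id)]),
                                    collapse = ", ")))
  suff <- compartment_of(mets$id)
  bad <- which(!is.na(suff) & suff != mets$compartment)
  if (length(bad))
    errors <- c(errors, paste0("metabolite id/compartment mismatch: ",
                               paste(mets$id[bad], collapse = ", ")))
  if (anyNA(suff))
    warns <- c(warns, paste0("metabolite ids without compartment suffix: ",
                             paste(mets$id[is.na(suff)], collapse = ", ")))
  if (any(rxns$lb > rxns$ub))
    errors <- c(errors, paste("lb > ub for:",
                              paste(rxns$id[rxns$lb > rxns$ub], collapse = ", ")))
  known <- mets$id
  for (i in seq_len(nrow(rxns))) {
    st <- model$stoich[[rxns$id[i]]]
    missing <- setdiff(names(st), known)
    if (length(missing))
      errors <- c(errors, paste0("reaction ", rxns$id[i],
                                 " references unknown metabolites: ",
                                 paste(missing, collapse = ", ")))
  }
  ## category-specific shape checks
  for (i in which(rxns$category == "transport")) {
    if (!is_transport_stoich(model$stoich[[rxns$id[i]]]))
      errors <- c(errors, paste0("transport step ", rxns$id[i],
                                 " does not conserve chemical species ",
                                 "across compartments"))
  }
  for (i in which(rxns$category == "boundary")) {
    st <- model$stoich[[rxns$id[i]]]
    nb <- sum(compartment_of(names(st)) != "boundary", na.rm = TRUE)
    if (nb != 1L)
      errors <- c(errors, paste0("boundary exchange ", rxns$id[i],
                                 " must involve exactly one non-boundary ",
                                 "species (has ", nb, ")"))
  }
  if (any(rxns$category == "unknown"))
    warns <- c(warns, paste("reactions of unknown category:",
                            paste(rxns$id[rxns$category == "unknown"],
                                  collapse = ", ")))
  missing_obj <- setdiff(model$objectives$id, rxns$id)
  if (length(missing_obj))
    errors <- c(errors, paste("objective ids missing from reactions:",
                              paste(missing_obj, collapse = ", ")))
  unreg <- setdiff(rxns$id[rxns$category == "objective_pseudo"],
                   model$objectives$id)
  if (length(unreg))
    warns <- c(warns, paste("objective_pseudo reactions not registered:",
                            paste(unreg, collapse = ", ")))
  orph <- find_orphan_metabolites(model)
  if (length(orph))
    warns <- c(warns, paste("orphan metabolites:", paste(orph, collapse = ", ")))
  counts <- table(factor(rxns$category,
                         levels = c("matrix", "cytosolic", "transport",
                                    "boundary", "objective_pseudo", "unknown")))
  list(errors = errors, warnings = warns, counts = counts,
       n_metabolites = nrow(mets), n_reactions = nrow(rxns), orphans = orph)
}

#' Build the stoichiometric matrix S
#'
#' Rows are non-boundary metabolites (boundary `_b` species are outside the
#' steady-state assumption and contribute no row), columns are all reactions
#' in a deterministic order (by category, then lexicographic id). Entry
#' `(m, r)` is reaction `r`'s signed coefficient for metabolite `m`.
#'
#' @param model an `fba_model` passing structural validation.
#' @return a sparse `dgCMatrix` with metabolite ids as row names and
#'   reaction ids as column names.
#' @export
build_matrix <- function(model) {
  mets <- model$mets
  internal <- mets$id[mets$compartment != "boundary"]
  rid <- reaction_order(model)
  i <- integer(); j <- integer(); x <- numeric()
  row_of <- stats::setNames(seq_along(internal), internal)
  for (k in seq_along(rid)) {
    st <- model$stoich[[rid[k]]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction ", rid[k], " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    keep <- names(st) %in% internal
    st <- st[keep]
    if (!length(st)) next
    i <- c(i, row_of[names(st)])
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, as.numeric(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(internal), length(rid)),
                       dimnames = list(internal, rid))
}

## Deterministic solver-facing column order: category then id. This fixes
## the vertex the simplex reports among alternate optima.
reaction_order <- function(model) {
  rxns <- model$rxns
  lev <- c("matrix", "cytosolic", "transport", "boundary",
           "objective_pseudo", "unknown")
  ord <- order(match(rxns$category, lev), rxns$id)
  rxns$id[ord]
}

#' Find orphan metabolites
#'
#' An orphan is a non-boundary metabolite participating in at most one
#' reaction; it forces that reaction's flux to zero at steady state. A
#' finished model should contain none.
#'
#' @param model an `fba_model`.
#' @return character vector of orphan metabolite ids (possibly empty).
#' @export
find_orphan_metabolites <- function(model) {
  internal <- model$mets$id[model$mets$compartment != "boundary"]
  use <- table(unlist(lapply(model$stoich, names)))
  cnt <- stats::setNames(rep(0L, length(internal)), internal)
  present <- intersect(names(use), internal)
  cnt[present] <- as.integer(use[present])
  names(cnt)[cnt <= 1L]
}

#' Read a constraint table from TSV
#'
#' Format: header `reaction_id<TAB>lb<TAB>ub<TAB>source`; the strings
#' `"inf"` and `"-inf"` are accepted and mapped to the finite sentinel.
#'
#' @param path file path.
#' @return a data frame of class `constraint_set`.
#' @export
read_constraint_set <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub", "source")
  if (!all(need %in% names(d)))
    stop("constraint table must have columns: ", paste(need, collapse = ", "))
  num <- function(v) {
    v <- as.character(v)
    out <- suppressWarnings(as.numeric(v))
    out[tolower(v) %in% c("inf", "+inf")] <- FLUX_BOUND_SENTINEL
    out[tolower(v) == "-inf"] <- -FLUX_BOUND_SENTINEL
    if (anyNA(out)) stop("unparseable bound in constraint table: ",
                         paste(v[is.na(out)], collapse = ", "))
    out
  }
  constraint_set(d$reaction_id, num(d$lb), num(d$ub), d$source)
}

#' Construct a constraint set in code
#'
#' @param reaction_id character vector of reaction ids.
#' @param lb,ub numeric bounds (umol/min/gDW); infinities are clamped to the
#'   sentinel.
#' @param source citation strings.
#' @return a data frame of class `constraint_set`.
#' @export
constraint_set <- function(reaction_id, lb, ub, source = "") {
  lb <- pmax(as.numeric(lb), -FLUX_BOUND_SENTINEL)
  ub <- pmin(as.numeric(ub), FLUX_BOUND_SENTINEL)
  structure(data.frame(reaction_id = reaction_id, lb = lb, ub = ub,
                       source = source, stringsAsFactors = FALSE),
            class = c("constraint_set", "data.frame"))
}

#' Write a constraint set to TSV
#' @param cs a `constraint_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_constraint_set <- function(cs, path) {
  utils::write.table(cs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a constraint set to a model
#'
#' Replaces the bounds of every referenced reaction; all other reactions are
#' untouched. The operation is idempotent. Rows referencing reactions absent
#' from the model raise an error listing every unresolved id.
#'
#' @param model an `fba_model`.
#' @param cs a `constraint_set` (or data frame with the same columns).
#' @return the modified model.
#' @export
apply_constraint_set <- function(model, cs) {
  if (!nrow(cs)) return(model)
  missing <- setdiff(cs$reaction_id, model$rxns$id)
  if (length(missing))
    stop("constraint set references unknown reactions: ",
         paste(missing, collapse = ", "))
  idx <- match(cs$reaction_id, model$rxns$id)
  model$rxns$lb[idx] <- pmax(cs$lb, -FLUX_BOUND_SENTINEL)
  model$rxns$ub[idx] <- pmin(cs$ub, FLUX_BOUND_SENTINEL)
  if (any(model$rxns$lb[idx] > model$rxns$ub[idx]))
    stop("constraint set sets lb > ub for: ",
         paste(cs$reaction_id[model$rxns$lb[idx] > model$rxns$ub[idx]],
               collapse = ", "))
  model
}

#' Rebalance the free-proton coefficient of a reaction
#'
#' Compartment pH differences change the protonation state of metabolites
#' (the major microspecies at matrix pH 8.05 differs from the one at
#' cytosolic pH 7.3, notably for phosphate-containing compounds). Given a
#' table of proton counts for each species' major microspecies, this adjusts
#' the stoichiometric coefficient of the free proton so that total protons
#' balance across the reaction. All non-proton coefficients are unchanged.
#'
#' @param reaction an `fba_reaction` whose non-proton species live in a
#'   single compartment.
#' @param proton_table named integer vector: metabolite id -> proton count
#'   of the major microspecies at the compartment pH.
#' @param proton_prefix chemical id of the free proton (default KEGG
#'   `"C00080"`).
#' @return the reaction with its free-proton coefficient replaced.
#' @export
rebalance_protons <- function(reaction, proton_table, proton_prefix = "C00080") {
  st <- reaction$stoich
  is_h <- strip_compartment(names(st)) == proton_prefix
  others <- names(st)[!is_h]
  comp <- unique(compartment_of(others))
  comp <- comp[!is.na(comp) & comp != "boundary"]
  if (length(comp) > 1L)
    stop("reaction '", reaction$id, "' spans compartments; rebalance each ",
         "half-reaction with its own per-compartment proton species")
  if (length(comp) == 0L)
    stop("reaction '", reaction$id, "' has no compartmentalised species")
  miss <- setdiff(others, names(proton_table))
  if (length(miss))
    stop("no proton count for species: ", paste(miss, collapse = ", "))
  h_id <- paste0(proton_prefix, c(matrix = "MM", cytosol = "Cyto")[[comp]])
  imbalance <- sum(st[others] * as.numeric(proton_table[others]))
  st <- st[!is_h]
  if (abs(imbalance) > 1e-12) st[h_id] <- -imbalance
  out <- reaction
  out$stoich <- st
  out
}

#' Add an efflux path for a matrix metabolite
#'
#' Adds a one-way matrix-to-cytosol transport step and a cytosol-to-boundary
#' exchange for the given matrix metabolite, creating the cytosolic and
#' boundary species if absent. This mirrors the standard disease-modelling
#' edit of permitting a metabolite that accumulates behind an enzyme block
#' (e.g. fumarate) to leave the system. Under unperturbed conditions the
#' addition does not affect the model: every objective optimum is
#' unchanged, the path is never forced to carry flux, and the maximum-ATP
#' parsimonious reference distribution ([reference_fluxes()]) routes
#' nothing through it. Calling it twice is an idempotent no-op with a
#' warning.
#'
#' @param model an `fba_model`.
#' @param matrix_metabolite_id id of a metabolite in the matrix compartment.
#' @return the extended model; the added reaction ids are in
#'   `attr(, "added_reactions")`.
#' @export
add_efflux_path <- function(model, matrix_metabolite_id) {
  mid <- matrix_metabolite_id
  row <- match(mid, model$mets$id)
  if (is.na(row) || model$mets$compartment[row] != "matrix")
    stop("'", mid, "' is not a matrix metabolite of this model")
  chem <- strip_compartment(mid)
  cid <- paste0(chem, "Cyto")
  bid <- paste0(chem, "_b")
  t_id <- paste0("TX_", chem, "_EFFLUX")
  e_id <- paste0("EX_", chem, "_out")
  if (t_id %in% model$rxns$id && e_id %in% model$rxns$id) {
    warning("efflux path for '", mid, "' already present; no-op")
    attr(model, "added_reactions") <- character()
    return(model)
  }
  base_name <- model$mets$name[row]
  add_met <- function(model, id, compartment) {
    if (!id %in% model$mets$id)
      model$mets <- rbind(model$mets, data.frame(
        id = id, name = base_name, compartment = compartment,
        proton_count = NA_integer_, formula = NA_character_,
        stringsAsFactors = FALSE))
    model
  }
  model <- add_met(model, cid, "cytosol")
  model <- add_met(model, bid, "boundary")
  add_rxn <- function(model, id, stoich, category, note) {
    if (id %in% model$rxns$id) return(model)
    model$rxns <- rbind(model$rxns, data.frame(
      id = id, lb = 0, ub = FLUX_BOUND_SENTINEL, category = category,
      note = note, stringsAsFactors = FALSE))
    model$stoich[[id]] <- stoich
    model
  }
  model <- add_rxn(model, t_id, stats::setNames(c(-1, 1), c(mid, cid)),
                   "transport", "disease-modelling efflux step (one-way out)")
  model <- add_rxn(model, e_id, stats::setNames(c(-1, 1), c(cid, bid)),
                   "boundary", "disease-modelling efflux boundary")
  attr(model, "added_reactions") <- c(t_id, e_id)
  model
}

#' @export
print.fba_model <- function(x, ...) {
  v <- validate_model(x)
  cat("Constraint-based metabolic model\n")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  cat(sprintf("  %d metabolites (%d matrix, %d cytosol, %d boundary)\n",
              nrow(x$mets), sum(x$mets$compartment == "matrix"),
              sum(x$mets$compartment == "cytosol"),
              sum(x$mets$compartment == "boundary")))
  cat(sprintf("  %d reactions:", nrow(x$rxns)))
  cnt <- v$counts[v$counts > 0]
  cat(" ", paste(sprintf("%d %s", cnt, names(cnt)), collapse = ", "), "\n")
  cat(sprintf("  %d objective pseudo-reactions registered\n",
              nrow(x$objectives)))
  if (length(v$orphans))
    cat("  orphan metabolites:", paste(v$orphans, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fba_model <- function(object, ...) {
  v <- validate_model(object)
  structure(list(counts = v$counts, n_metabolites = v$n_metabolites,
                 n_reactions = v$n_reactions, orphans = v$orphans,
                 warnings = v$warnings, errors = v$errors,
                 objectives = object$objectives),
            class = "summary.fba_model")
}

#' @export
print.summary.fba_model <- function(x, ...) {
  cat("Reactions per category:\n")
  print(x$counts)
  cat("Metabolites:", x$n_metabolites, "\n")
  cat("Orphans:", if (length(x$orphans)) paste(x$orphans, collapse = ", ")
      else "none", "\n")
  if (length(x$errors)) cat("Errors:\n ", paste(x$errors, collapse = "\n  "), "\n")
  if (length(x$warnings)) cat("Warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

## internal helper: bounds vector aligned with reaction_order
model_bounds <- function(model, order = reaction_order(model)) {
  idx <- match(order, model$rxns$id)
  list(lb = model$rxns$lb[idx], ub = model$rxns$ub[idx])
}
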