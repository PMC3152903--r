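## SBML input/output.
##
## The 2011-era convention for constraint-based models is SBML Level 2 with
## flux bounds carried as kinetic-law parameters (LOWER_BOUND, UPPER_BOUND,
## OBJECTIVE_COEFFICIENT); newer files use Level 3 with the fbc package
## (fbc:lowerFluxBound / fbc:upperFluxBound referencing global parameters,
## fbc:listOfObjectives). The reader accepts both and normalises to the
## in-memory lb/ub representation; the writer emits the Level 2 dialect.
## No libsbml binding is available in this environment, so the subset of
## SBML needed here is handled directly over xml2. Parsing is namespace-
## agnostic (XPath on local names) to tolerate dialect differences.

sbml_num <- function(x) sprintf("%.15g", x)

compartment_sbml_id <- c(matrix = "matrix", cytosol = "cytosol",
                         boundary = "boundary")

#' Write a model to SBML
#'
#' Emits SBML Level 2 Version 4 with flux bounds and objective coefficients
#' as kinetic-law parameters, category and provenance notes per reaction,
#' and objective registration plus compartment pH in the model notes. Ids
#' and bounds are serialised with 15 significant digits so that a
#' write/read round trip reproduces the model within 1e-12.
#'
#' @param model an `fba_model` passing structural validation.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  v <- validate_model(model)
  if (length(v$errors))
    stop("refusing to write a structurally invalid model:\n  ",
         paste(v$errors, collapse = "\n  "))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
           sprintf('<model id="model" name="%s">', esc(model$metadata)))
  notes <- c("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
             sprintf("<p>PH: matrix=%s cytosol=%s</p>",
                     sbml_num(model$ph[["matrix"]]),
                     sbml_num(model$ph[["cytosol"]])),
             vapply(seq_len(nrow(model$objectives)), function(i)
               sprintf("<p>OBJECTIVE: %s | %s | %s</p>",
                       model$objectives$id[i],
                       esc(model$objectives$description[i]),
                       model$objectives$sense[i]), ""),
             "</body></notes>")
  con <- c(con, notes, "<listOfCompartments>",
           sprintf('<compartment id="%s"/>', unique(compartment_sbml_id)),
           "</listOfCompartments>", "<listOfSpecies>")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    extra <- character()
    if (!is.na(m$proton_count))
      extra <- c(extra, sprintf("<p>PROTONS: %d</p>", m$proton_count))
    if (!is.na(m$formula))
      extra <- c(extra, sprintf("<p>FORMULA: %s</p>", esc(m$formula)))
    note <- if (length(extra))
      paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
             paste(extra, collapse = ""), "</body></notes>") else ""
    con <- c(con, sprintf(
      '<species id="%s" name="%s" compartment="%s" boundaryCondition="%s">%s</species>',
      m$id, esc(m$name), compartment_sbml_id[[m$compartment]],
      if (m$compartment == "boundary") "true" else "false", note))
  }
  con <- c(con, "</listOfSpecies>", "<listOfReactions>")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    st <- model$stoich[[r$id]]
    refs <- function(v) paste(sprintf(
      '<speciesReference species="%s" stoichiometry="%s"/>',
      names(v), sbml_num(abs(v))), collapse = "")
    obj_coef <- as.integer(r$id %in% model$objectives$id)
    con <- c(con,
      sprintf('<reaction id="%s" reversible="%s">',
              r$id, if (r$lb < 0) "true" else "false"),
      paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
             sprintf("<p>CATEGORY: %s</p>", r$category),
             if (nzchar(r$note)) sprintf("<p>NOTE: %s</p>", esc(r$note)) else "",
             "</body></notes>"),
      if (any(st < 0)) c("<listOfReactants>", refs(st[st < 0]),
                         "</listOfReactants>") else NULL,
      if (any(st > 0)) c("<listOfProducts>", refs(st[st > 0]),
                         "</listOfProducts>") else NULL,
      "<kineticLaw>",
      '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>',
      "<listOfParameters>",
      sprintf('<parameter id="LOWER_BOUND" value="%s" units="umol_per_min_per_gDW"/>',
              sbml_num(r$lb)),
      sprintf('<parameter id="UPPER_BOUND" value="%s" units="umol_per_min_per_gDW"/>',
              sbml_num(r$ub)),
      sprintf('<parameter id="OBJECTIVE_COEFFICIENT" value="%d"/>', obj_coef),
      "</listOfParameters>", "</kineticLaw>", "</reaction>")
  }
  con <- c(con, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(con, path)
  invisible(path)
}

## extract "KEY: value" lines from an SBML notes block
notes_fields <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  hits <- grep(paste0("^", key, ":"), txt, value = TRUE)
  trimws(sub(paste0("^", key, ":"), "", hits))
}

#' Read a model from SBML
#'
#' Accepts SBML Level 2 (bounds as kinetic-law parameters) and Level 3
#' FBC-style bounds (fbc attributes referencing global parameters).
#' Compartments are taken from the species' compartment attribute or the
#' `boundaryCondition` flag, falling back to the id-suffix convention
#' ("MM" matrix / "Cyto" cytosol / "_b" boundary). Reactions with no bound
#' information get `[-sentinel, sentinel]` if `reversible` (the SBML
#' default) else `[0, sentinel]`. Categories are restored from CATEGORY
#' notes when present, otherwise inferred from stoichiometry shape — a
#' transport step is recognised by conserved chemistry across compartments,
#' not by its id. Objectives come from model notes, fbc objectives, or
#' nonzero OBJECTIVE_COEFFICIENT parameters, in that priority order.
#'
#' @param path SBML file path.
#' @param validate stop on structural errors (default `TRUE`).
#' @return an `fba_model`.
#' @export
read_sbml <- function(path, validate = TRUE) {
  doc <- xml2::read_xml(path)   # malformed XML fails here with line context
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing"))
    stop("no <model> element found in ", path)

  ## global parameters (Level 3 fbc bound style)
  gpars <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  gpar_val <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(gpars, "value"))),
    xml2::xml_attr(gpars, "id"))

  ## compartments: map declared ids to our enum when recognisable
  comp_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp_map <- stats::setNames(
    vapply(tolower(xml2::xml_attr(comp_nodes, "id")), function(x) {
      if (grepl("matrix|mito|mm", x)) "matrix"
      else if (grepl("cyto", x)) "cytosol"
      else if (grepl("bound|ext", x)) "boundary"
      else NA_character_
    }, ""), xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- vector("list", length(sp_nodes))
  for (i in seq_along(sp_nodes)) {
    sp <- sp_nodes[[i]]
    id <- xml2::xml_attr(sp, "id")
    comp <- NA_character_
    if (identical(xml2::xml_attr(sp, "boundaryCondition"), "true"))
      comp <- "boundary"
    if (is.na(comp)) {
      declared <- xml2::xml_attr(sp, "compartment")
      if (!is.na(declared) && declared %in% names(comp_map))
        comp <- comp_map[[declared]]
    }
    if (is.na(comp)) comp <- compartment_of(id)
    if (is.na(comp)) {
      warning("species '", id, "' violates the compartment-suffix ",
              "convention and declares no known compartment; treating as cytosol")
      comp <- "cytosol"
    }
    pc <- notes_fields(sp, "PROTONS")
    fo <- notes_fields(sp, "FORMULA")
    mets[[i]] <- fba_metabolite(
      id,
      name = if (!is.na(xml2::xml_attr(sp, "name")))
        xml2::xml_attr(sp, "name") else id,
      compartment = comp,
      proton_count = if (length(pc)) as.integer(pc[1]) else NA_integer_,
      formula = if (length(fo)) fo[1] else NA_character_)
  }

  rx_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  fbc_obj_ids <- character()
  fbc_sense <- "maximise"
  fo_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  if (length(fo_nodes)) {
    fbc_obj_ids <- xml2::xml_attr(fo_nodes, "reaction")
    lst <- xml2::xml_find_first(model_node, ".//*[local-name()='objective']")
    if (!inherits(lst, "xml_missing") &&
        identical(xml2::xml_attr(lst, "type"), "minimize"))
      fbc_sense <- "minimise"
  }

  rxns <- vector("list", length(rx_nodes))
  obj_coef_ids <- character()
  for (i in seq_along(rx_nodes)) {
    rx <- rx_nodes[[i]]
    id <- xml2::xml_attr(rx, "id")
    rev <- !identical(xml2::xml_attr(rx, "reversible"), "false")
    side <- function(tag, sign) {
      sr <- xml2::xml_find_all(rx, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(sr)) return(numeric(0))
      stoi <- xml2::xml_attr(sr, "stoichiometry")
      stoi[is.na(stoi)] <- "1"
      stats::setNames(sign * as.numeric(stoi), xml2::xml_attr(sr, "species"))
    }
    st <- c(side("listOfReactants", -1), side("listOfProducts", 1))
    ## merge duplicated species across sides
    if (anyDuplicated(names(st)))
      st <- tapply(st, names(st), sum)[unique(names(st))]
    ## bounds: kinetic-law parameters, then fbc attributes, then defaults
    kpar <- xml2::xml_find_all(rx, paste0(
      ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))
    kv <- stats::setNames(
      suppressWarnings(as.numeric(xml2::xml_attr(kpar, "value"))),
      xml2::xml_attr(kpar, "id"))
    lb <- ub <- NA_real_
    if ("LOWER_BOUND" %in% names(kv)) lb <- kv[["LOWER_BOUND"]]
    if ("UPPER_BOUND" %in% names(kv)) ub <- kv[["UPPER_BOUND"]]
    for (attr_name in c("lowerFluxBound", "upperFluxBound")) {
      ref <- xml2::xml_attr(rx, attr_name)
      if (!is.na(ref) && ref %in% names(gpar_val)) {
        if (attr_name == "lowerFluxBound") lb <- gpar_val[[ref]]
        else ub <- gpar_val[[ref]]
      }
    }
    if (is.na(lb)) lb <- if (rev) -FLUX_BOUND_SENTINEL else 0
    if (is.na(ub)) ub <- FLUX_BOUND_SENTINEL
    lb <- max(lb, -FLUX_BOUND_SENTINEL)
    ub <- min(ub, FLUX_BOUND_SENTINEL)
    if ("OBJECTIVE_COEFFICIENT" %in% names(kv) &&
        isTRUE(kv[["OBJECTIVE_COEFFICIENT"]] != 0))
      obj_coef_ids <- c(obj_coef_ids, id)
    cat_note <- notes_fields(rx, "CATEGORY")
    note <- notes_fields(rx, "NOTE")
    rxns[[i]] <- fba_reaction(
      id, st, lb = lb, ub = ub,
      category = if (length(cat_note)) cat_note[1] else NULL,
      note = if (length(note)) note[1] else "")
  }

  ## objectives: model notes take precedence, then fbc, then coefficients
  obj_lines <- notes_fields(model_node, "OBJECTIVE")
  objectives <- list()
  if (length(obj_lines)) {
    for (ln in obj_lines) {
      parts <- trimws(strsplit(ln, "|", fixed = TRUE)[[1]])
      objectives[[length(objectives) + 1L]] <-
        objective_spec(parts[1],
                       if (length(parts) > 1) parts[2] else parts[1],
                       if (length(parts) > 2) parts[3] else "maximise")
    }
  } else if (length(fbc_obj_ids)) {
    objectives <- lapply(fbc_obj_ids, function(x)
      objective_spec(x, x, fbc_sense))
  } else if (length(obj_coef_ids)) {
    objectives <- lapply(unique(obj_coef_ids), function(x)
      objective_spec(x, x, "maximise"))
  }

  ph <- c(matrix = 8.05, cytosol = 7.3)
  ph_line <- notes_fields(model_node, "PH")
  if (length(ph_line)) {
    mm <- regmatches(ph_line[1],
                     regexec("matrix=([0-9.]+) cytosol=([0-9.]+)", ph_line[1]))[[1]]
    if (length(mm) == 3) ph <- c(matrix = as.numeric(mm[2]),
                                 cytosol = as.numeric(mm[3]))
  }
  name <- xml2::xml_attr(model_node, "name")
  fba_model(mets, rxns, objectives, ph = ph,
            metadata = if (is.na(name)) "" else name,
            validate = validate)
}

#' Convenience loader for a deposited full-scale model
#'
#' Thin wrapper around [read_sbml()] for a user-supplied copy of a
#' deposited mitochondrial model (e.g. the iAS253 SBML from the BioModels
#' repository, which cannot be redistributed inside this package). An
#' optional constraint table is applied after reading.
#'
#' @param path path to the SBML file.
#' @param constraints optional path to a TSV constraint table.
#' @return an `fba_model`.
#' @export
load_deposited_model <- function(path, constraints = NULL) {
  if (!file.exists(path))
    stop("deposited model file not found: ", path,
         "\nDownload it from its public repository and pass its local path.")
  model <- read_sbml(path)
  if (!is.null(constraints))
    model <- apply_constraint_set(model, read_constraint_set(constraints))
  model
}

#' Write a flux report as TSV
#'
#' One row per reaction: `reaction_id`, `flux` (umol/min/gDW), `category`,
#' ordered by category then id (the deterministic solver ordering).
#'
#' @param state an optimal `flux_state`.
#' @param model the model it was solved on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_report <- function(state, model, path) {
  if (!inherits(state, "flux_state") || state$status != "optimal")
    stop("write_flux_report requires an optimal flux_state")
  ord <- reaction_order(model)
  idx <- match(ord, model$rxns$id)
  d <- data.frame(reaction_id = ord,
                  flux = as.numeric(state$flux[ord]),
                  category = model$rxns$category[idx],
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
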