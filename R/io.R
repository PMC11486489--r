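#' Read a GSMM from SBML or COBRA-style JSON
#'
#' Supports SBML Level 3 (with the fbc package for flux bounds and the
#' biomass objective) and the COBRA JSON dialect. Exchange reactions are
#' auto-detected: a reaction is an exchange when it has the structural
#' boundary form (exactly one metabolite, coefficient -1, extracellular) or
#' an `EX_` id prefix; when the prefix and the structure disagree the
#' structural rule wins and a warning names the reaction.
#'
#' @param path model file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return a validated [gsmm()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  model <- switch(format, json = read_model_json(path),
                  sbml = read_model_sbml(path))
  model$provenance <- path
  model <- detect_exchanges(model)
  validate_gsmm(model)
  model
}

#' Write a GSMM to SBML or COBRA-style JSON
#'
#' Round-trips with [load_model()]: writing and re-reading reproduces the
#' same model (ids, formulas, stoichiometry, bounds, objective).
#'
#' @param model a [gsmm()].
#' @param path output file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

detect_exchanges <- function(model) {
  compartment <- stats::setNames(model$metabolites$compartment,
                                 model$metabolites$id)
  for (i in seq_along(model$reactions)) {
    rxn <- model$reactions[[i]]
    structural <- length(rxn$stoichiometry) == 1L &&
      rxn$stoichiometry[[1L]] == -1 &&
      compartment[[names(rxn$stoichiometry)[1L]]] == "e"
    prefixed <- startsWith(rxn$id, "EX_")
    if (prefixed && !structural)
      warning("reaction ", rxn$id, " has an EX_ prefix but not the ",
              "boundary structure; treated as non-exchange", call. = FALSE)
    model$reactions[[i]]$is_exchange <- structural
  }
  model
}

# JSON dialect ---------------------------------------------------------------

read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               formula = if (is.null(m$formula)) "" else m$formula,
               compartment = if (is.null(m$compartment))
                 sub("^.*_", "", m$id) else m$compartment,
               stringsAsFactors = FALSE)))
  objective_id <- NULL
  rxns <- lapply(x$reactions, function(r) {
    stoich <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient) &&
        r$objective_coefficient != 0)
      objective_id <<- r$id
    reaction(r$id, stoich,
             lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
             upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound)
  })
  if (is.null(objective_id))
    stop("model file ", path, " declares no objective reaction")
  gsmm(id = if (is.null(x$id)) basename(path) else x$id,
       metabolites = mets, reactions = rxns, objective_id = objective_id,
       check = FALSE)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i], name = model$metabolites$name[i],
         formula = model$metabolites$formula[i],
         compartment = model$metabolites$compartment[i]))
  rxns <- lapply(model$reactions, function(r)
    list(id = r$id, metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         objective_coefficient = if (r$id == model$objective_id) 1 else 0))
  jsonlite::write_json(
    list(id = model$id, metabolites = mets, reactions = unname(rxns),
         compartments = list(c = "cytosol", e = "extracellular space")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# SBML L3 + fbc --------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing")) stop("not an SBML L3 file: ", path)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp, function(nd)
    data.frame(id = strip_sbml_prefix(xml2::xml_attr(nd, "id"), "M_"),
               name = attr_or(nd, "name",
                              strip_sbml_prefix(xml2::xml_attr(nd, "id"), "M_")),
               formula = attr_or(nd, "chemicalFormula", ""),
               compartment = xml2::xml_attr(nd, "compartment"),
               stringsAsFactors = FALSE)))
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(nd) {
    rid <- strip_sbml_prefix(xml2::xml_attr(nd, "id"), "R_")
    reac <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    stoich <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_sbml_prefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_sbml_prefix(xml2::xml_attr(prod, "species"), "M_")))
    lbp <- attr_or(nd, "lowerFluxBound", NA_character_)
    ubp <- attr_or(nd, "upperFluxBound", NA_character_)
    reaction(rid, stoich,
             lower_bound = if (!is.na(lbp) && lbp %in% names(pval))
               pval[[lbp]] else -1000,
             upper_bound = if (!is.na(ubp) && ubp %in% names(pval))
               pval[[ubp]] else 1000)
  })
  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(fo, "xml_missing"))
    stop("model file ", path, " declares no fbc objective")
  objective_id <- strip_sbml_prefix(attr_or(fo, "reaction", NA_character_), "R_")
  gsmm(id = attr_or(mnode, "id", basename(path)),
       metabolites = mets, reactions = rxns, objective_id = objective_id,
       check = FALSE)
}

# fbc attributes may appear with or without their namespace prefix
attr_or <- function(nd, attr, default) {
  val <- xml2::xml_attr(nd, attr)
  if (is.na(val)) val <- xml2::xml_attr(nd, paste0("fbc:", attr))
  if (is.na(val)) default else val
}

strip_sbml_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      '      <species id="M_%s" name="%s" compartment="%s"%s hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(m$compartment),
      if (nzchar(m$formula))
        sprintf(' fbc:chemicalFormula="%s"', esc(m$formula)) else ""))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions)
    lines <- c(lines, sprintf(
      '      <parameter id="R_%s_lb" value="%.10g" constant="true"/>\n      <parameter id="R_%s_ub" value="%.10g" constant="true"/>',
      esc(r$id), r$lower_bound, esc(r$id), r$upper_bound))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="R_%s_lb" fbc:upperFluxBound="R_%s_ub">',
      esc(r$id), if (r$lower_bound < 0) "true" else "false",
      esc(r$id), esc(r$id)))
    if (length(reac) > 0L) {
      lines <- c(lines, '        <listOfReactants>')
      for (mid in names(reac))
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%.10g" constant="true"/>',
          esc(mid), -reac[[mid]]))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod) > 0L) {
      lines <- c(lines, '        <listOfProducts>')
      for (mid in names(prod))
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%.10g" constant="true"/>',
          esc(mid), prod[[mid]]))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            esc(model$objective_id)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
}
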