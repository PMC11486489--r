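#' Construct a growth medium
#'
#' A medium maps extracellular compound ids to maximal uptake fluxes
#' (mmol/gDW/h, strictly positive). It is the shared, growing environment of
#' a community simulation.
#'
#' @param bounds named numeric vector, compound id -> uptake bound (> 0).
#' @param name optional label.
#' @return named numeric vector of class `medium`.
#' @export
medium <- function(bounds = numeric(), name = NULL) {
  bounds <- unlist(bounds)
  if (length(bounds) > 0L) {
    if (is.null(names(bounds)) || any(names(bounds) == ""))
      stop("medium bounds must be named by compound id")
    if (anyDuplicated(names(bounds)))
      stop("duplicate compound id(s) in medium: ",
           paste(unique(names(bounds)[duplicated(names(bounds))]), collapse = ", "))
    if (any(!is.finite(bounds)) || any(bounds <= 0))
      stop("medium bounds must be strictly positive and finite; offending: ",
           paste(names(bounds)[!is.finite(bounds) | bounds <= 0], collapse = ", "))
  }
  structure(as.numeric(bounds), names = names(bounds), class = "medium",
            medium_name = name)
}

as_medium <- function(x) {
  if (inherits(x, "medium")) return(x)
  medium(x)
}

#' @export
print.medium <- function(x, ...) {
  nm <- attr(x, "medium_name")
  cat("<medium>", if (!is.null(nm)) nm else "", " ", length(x), " compounds\n",
      sep = "")
  invisible(x)
}

#' Read a medium table
#'
#' Accepts a TSV with columns `compound_id` and `bound_mmol_gDW_h` (a plain
#' `bound` column is also accepted; extra columns such as `formula` or `name`
#' are carried along as the `"compound_info"` attribute) or a JSON object
#' mapping compound id to bound.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @param name optional medium label; defaults to the file name.
#' @return a [medium()].
#' @export
load_medium <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- basename(path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(medium(unlist(x), name = name))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  bcol <- intersect(c("bound_mmol_gDW_h", "bound"), names(tab))
  if (!("compound_id" %in% names(tab)) || length(bcol) == 0L)
    stop("medium table needs columns compound_id and bound_mmol_gDW_h: ", path)
  med <- medium(stats::setNames(tab[[bcol[1L]]], tab$compound_id), name = name)
  attr(med, "compound_info") <- tab
  med
}

#' Read a model label table
#'
#' Maps model id to one of the three association classes: `"H"` (healthy
#' soil), `"S"` (sick soil) or `"NA"` (not associated). The classes come
#' from an upstream differential-abundance analysis and are consumed here as
#' plain input.
#'
#' @param path TSV with columns `model_id` and `class`, or JSON object.
#' @return named character vector of class `label_table`.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(label_table(stats::setNames(unlist(x), names(x))))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "")
  if (!all(c("model_id", "class") %in% names(tab)))
    stop("label table needs columns model_id and class: ", path)
  label_table(stats::setNames(tab$class, tab$model_id))
}

#' @rdname load_labels
#' @param labels named character vector of classes.
#' @export
label_table <- function(labels) {
  bad <- setdiff(unique(labels), c("H", "S", "NA"))
  if (length(bad) > 0L)
    stop("label class(es) outside {H, S, NA}: ", paste(bad, collapse = ", "))
  structure(labels, class = "label_table")
}

#' Parse an elemental formula
#'
#' @param formula Hill-style composition string, e.g. `"C6H12O6"`. The empty
#'   string is allowed and yields an empty count vector (unknown
#'   composition).
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula)) formula <- ""
  if (formula == "") return(stats::setNames(integer(0), character(0)))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("unparseable formula: '", formula, "'")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  parts <- regmatches(formula, list(m))[[1L]]
  el <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(parts, "")))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, el, sum)[unique(el)]
}

#' Default inorganic-carbon exclusion list
#'
#' Compounds that contain carbon but are conventionally inorganic: carbon
#' dioxide, carbon monoxide, bicarbonate, carbonate and the cyanide family.
#' Matched against the compound's base id (compartment suffix stripped).
#'
#' @return character vector of base ids.
#' @export
inorganic_carbon_ids <- function() {
  c("co2", "co", "hco3", "co3", "cyan", "hcn", "cynt", "tcynt")
}

strip_compartment <- function(id) sub("_[a-z][0-9]*$", "", id)

#' Classify a compound as organic, organic-P or inorganic
#'
#' A compound is organic when its formula contains at least one carbon atom
#' and its id is not on the inorganic-carbon exclusion list; organic_p when
#' additionally at least one phosphorus atom is present. Compounds with an
#' empty (unknown) formula are classified inorganic with a warning, which
#' keeps any organic-only network claim conservative.
#'
#' @param id compound id (compartment suffix tolerated, e.g. `"glc__D_e"`).
#' @param formula elemental formula string.
#' @param exclude base ids treated as inorganic despite containing carbon.
#' @return one of `"organic"`, `"organic_p"`, `"inorganic"`.
#' @export
classify_compound <- function(id, formula,
                              exclude = inorganic_carbon_ids()) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) {
    warning("compound '", id, "' has no formula; classified inorganic",
            call. = FALSE)
    return("inorganic")
  }
  if (strip_compartment(id) %in% exclude) return("inorganic")
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (nC < 1L) return("inorganic")
  nP <- if ("P" %in% names(counts)) counts[["P"]] else 0L
  if (nP >= 1L) "organic_p" else "organic"
}

#' @rdname classify_compound
#' @param met single-row metabolite entry (a list or data.frame row with
#'   `id` and `formula`).
#' @export
classify_metabolite <- function(met, exclude = inorganic_carbon_ids()) {
  classify_compound(met$id, met$formula, exclude = exclude)
}

#' Bundled apple-root exudate medium
#'
#' The 33 root-exudate compounds used as the sole carbon sources of the
#' rhizosphere environment (amino acids, mono-saccharides, sugar alcohols,
#' phenolics and other carbohydrates, organic acids, urea and octadecanoate),
#' with BIGG-style ids, formulas and uptake bounds of 1000 mmol/gDW/h.
#'
#' @return a [medium()] of 33 compounds, with the full table in the
#'   `"compound_info"` attribute.
#' @export
apple_root_exudates <- function() {
  load_medium(system.file("extdata", "apple_root_exudates.tsv",
                          package = "troponet"),
              name = "apple_root_exudates")
}

#' Bundled inorganic backbone medium
#'
#' A representative list of 60 inorganic compounds (water, gases, nitrogen,
#' phosphorus and sulfur sources, trace metals and halides) used together
#' with the root exudates to assemble the rhizosphere environment. The list
#' is synthetic: it stands in for a study-specific inorganic compound file
#' and carries no organic carbon.
#'
#' @return a [medium()] of 60 compounds.
#' @export
inorganic_backbone <- function() {
  load_medium(system.file("extdata", "synthetic_inorganic_medium.tsv",
                          package = "troponet"),
              name = "synthetic_inorganic_backbone")
}
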