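#' Construct a genome-scale metabolic model (GSMM)
#'
#' A `gsmm` is the package's in-memory representation of a stoichiometric
#' model: a metabolite table, a list of bounded reactions and a biomass
#' objective. Flux units are mmol/gDW/h throughout; the biomass flux is the
#' growth rate in 1/h.
#'
#' @param id model identifier (single string).
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `compartment`. Compartments are `"e"` (extracellular) or `"c"`
#'   (intracellular). Formulas are Hill-style element strings (`"C6H12O6"`);
#'   an empty string marks an unknown composition.
#' @param reactions list of reactions built with [reaction()].
#' @param objective_id reaction id of the biomass objective.
#' @param taxonomy,provenance optional free-text annotations.
#' @param check run full invariant validation (default `TRUE`).
#'
#' @return an object of class `gsmm`.
#' @seealso [reaction()], [load_model()], [solve_fba()]
#' @export
gsmm <- function(id, metabolites, reactions, objective_id,
                 taxonomy = NA_character_, provenance = NA_character_,
                 check = TRUE) {
  stopifnot(is.character(id), length(id) == 1L)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  required <- c("id", "name", "formula", "compartment")
  missing_cols <- setdiff(required, names(metabolites))
  if (length(missing_cols) > 0L)
    stop("metabolite table lacks column(s): ", paste(missing_cols, collapse = ", "))
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  obj <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective_id = objective_id, taxonomy = taxonomy,
         provenance = provenance),
    class = "gsmm")
  if (check) validate_gsmm(obj)
  obj
}

#' Construct a model reaction
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector mapping metabolite id to a
#'   non-zero coefficient; negative coefficients are consumed.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h. Non-finite
#'   bounds are capped at +/-1000, the global exchange bound.
#' @param is_exchange is this a boundary (exchange) reaction?
#'
#' @return a list of class `gsmm_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     is_exchange = FALSE) {
  stoichiometry <- stoichiometry[stoichiometry != 0]
  lower_bound <- max(lower_bound, -1000)
  upper_bound <- min(upper_bound, 1000)
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower_bound > upper_bound")
  structure(
    list(id = id, stoichiometry = stoichiometry,
         lower_bound = lower_bound, upper_bound = upper_bound,
         is_exchange = isTRUE(is_exchange)),
    class = "gsmm_reaction")
}

#' Validate model invariants
#'
#' Checks referential integrity (objective present, every referenced
#' metabolite declared), bound ordering, and the structural exchange rule:
#' an exchange reaction carries exactly one metabolite, with coefficient -1,
#' in the extracellular compartment. Optionally runs the
#' stoichiometric-consistency smoke test: with every exchange lower bound
#' closed the maximal biomass flux must be zero (no free mass; models are
#' expected to be drafted without gap filling).
#'
#' @param model a [gsmm()].
#' @param check_closed_growth also assert zero growth on the fully closed
#'   system (runs one LP; default `FALSE`).
#' @return the model, invisibly; errors name the offending entity.
#' @export
validate_gsmm <- function(model, check_closed_growth = FALSE) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  if (!model$objective_id %in% rxn_ids)
    stop("objective reaction '", model$objective_id, "' not found in model '",
         model$id, "'")
  compartment <- stats::setNames(model$metabolites$compartment, met_ids)
  for (rxn in model$reactions) {
    refs <- names(rxn$stoichiometry)
    unknown <- setdiff(refs, met_ids)
    if (length(unknown) > 0L)
      stop("reaction ", rxn$id, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (rxn$lower_bound > rxn$upper_bound)
      stop("reaction ", rxn$id, ": lower_bound > upper_bound")
    if (rxn$is_exchange) {
      if (length(rxn$stoichiometry) != 1L)
        stop("exchange reaction ", rxn$id, " references ",
             length(rxn$stoichiometry), " metabolites (expected exactly 1)")
      if (rxn$stoichiometry[[1L]] != -1)
        stop("exchange reaction ", rxn$id, " must have coefficient -1")
      if (compartment[[refs]] != "e")
        stop("exchange reaction ", rxn$id,
             " references a non-extracellular metabolite: ", refs)
    }
  }
  for (f in model$metabolites$formula)
    parse_formula(f)  # errors on an unparseable composition
  if (check_closed_growth) {
    closed <- close_exchanges(model)
    sol <- solve_fba(closed)
    if (sol$objective_value > 1e-6)
      stop("model '", model$id, "' grows with all exchanges closed (",
           signif(sol$objective_value, 4), "/h): stoichiometrically inconsistent")
  }
  invisible(model)
}

#' @export
print.gsmm <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, `[[`, TRUE, "is_exchange"))
  cat("<gsmm> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions),
      " (", n_ex, " exchanges)\n",
      "  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Exchange reactions of a model
#'
#' @param model a [gsmm()].
#' @return data.frame with columns `reaction` and `metabolite` (the single
#'   extracellular metabolite each exchange carries).
#' @export
exchanges <- function(model) {
  ex <- Filter(function(r) r$is_exchange, model$reactions)
  data.frame(
    reaction = vapply(ex, `[[`, "", "id"),
    metabolite = vapply(ex, function(r) names(r$stoichiometry), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [gsmm()].
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (rxn in model$reactions)
    S[names(rxn$stoichiometry), rxn$id] <- rxn$stoichiometry
  S
}

# All exchange lower bounds set to 0 (fully closed system).
close_exchanges <- function(model) {
  for (i in seq_along(model$reactions))
    if (model$reactions[[i]]$is_exchange)
      model$reactions[[i]]$lower_bound <- 0
  model
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

#' Apply a growth medium to a model
#'
#' Opens uptake for medium compounds and closes everything else: each
#' exchange reaction's lower bound becomes `-bound` when its metabolite is in
#' the medium, 0 otherwise. Secretion (upper) bounds are untouched. Medium
#' compounds with no matching exchange in this model are skipped; their ids
#' are recorded in the `"skipped_compounds"` attribute of the result.
#'
#' @param model a [gsmm()].
#' @param medium a [medium()] (named uptake bounds, mmol/gDW/h).
#' @return a modified copy of `model`.
#' @export
apply_medium <- function(model, medium) {
  bounds <- as_medium(medium)
  ex <- exchanges(model)
  for (i in seq_along(model$reactions)) {
    rxn <- model$reactions[[i]]
    if (!rxn$is_exchange) next
    met <- names(rxn$stoichiometry)
    model$reactions[[i]]$lower_bound <-
      if (met %in% names(bounds)) -min(bounds[[met]], 1000) else 0
  }
  attr(model, "skipped_compounds") <- setdiff(names(bounds), ex$metabolite)
  model
}
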