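#' Assemble the rhizosphere simulation environment
#'
#' Unions the root-exudate medium (the sole organic carbon sources) with the
#' inorganic backbone. The exudates must all classify as organic and the
#' inorganic list must contain no organic compound; formulas are looked up
#' in the media's `"compound_info"` attributes or in `formulas`.
#'
#' @param exudates [medium()] of root exudates.
#' @param inorganics [medium()] of inorganic compounds.
#' @param formulas optional named character vector, compound id -> formula,
#'   overriding/extending formulas carried by the media tables.
#' @return a [medium()] containing both compound sets.
#' @export
build_rhizosphere_environment <- function(exudates = apple_root_exudates(),
                                          inorganics = inorganic_backbone(),
                                          formulas = NULL) {
  exudates <- as_medium(exudates)
  inorganics <- as_medium(inorganics)
  shared <- intersect(names(exudates), names(inorganics))
  if (length(shared) > 0L)
    stop("exudate and inorganic lists overlap: ", paste(shared, collapse = ", "))
  lookup <- c(formulas,
              medium_formulas(exudates), medium_formulas(inorganics))
  lookup <- lookup[!duplicated(names(lookup))]
  cls <- function(id) {
    f <- if (id %in% names(lookup)) lookup[[id]] else ""
    suppressWarnings(classify_compound(id, f))
  }
  ex_cls <- vapply(names(exudates), cls, "")
  if (any(ex_cls == "inorganic"))
    stop("non-organic compound(s) in the exudate list: ",
         paste(names(exudates)[ex_cls == "inorganic"], collapse = ", "))
  in_cls <- vapply(names(inorganics), cls, "")
  if (any(in_cls != "inorganic"))
    stop("organic compound(s) in the inorganic list: ",
         paste(names(inorganics)[in_cls != "inorganic"], collapse = ", "))
  env <- medium(c(unclass(exudates), unclass(inorganics)),
                name = "rhizosphere_environment")
  attr(env, "exudate_ids") <- names(exudates)
  env
}

medium_formulas <- function(med) {
  info <- attr(med, "compound_info")
  if (is.null(info) || !("formula" %in% names(info))) return(character(0))
  stats::setNames(as.character(info$formula), info$compound_id)
}

#' Uptake/secretion profile of one model in a medium
#'
#' Applies the medium, checks growth by FBA and, for growing models, scans
#' all exchange reactions by FVA at `fraction` of the optimum. A compound is
#' potentially taken up when its exchange FVA minimum is below -1e-6 and
#' potentially secreted when the FVA maximum exceeds +1e-6; running at 90%
#' optimality deliberately admits the less restricted secretion profile.
#'
#' @param model a [gsmm()].
#' @param medium a [medium()].
#' @param fraction FVA fraction of optimum (default 0.9).
#' @return list of class `exchange_profile`: `model`, `grew`, `growth_rate`,
#'   `uptaken`, `secreted` (compound id sets; empty when not growing).
#' @export
exchange_profile <- function(model, medium, fraction = 0.9) {
  conditioned <- apply_medium(model, medium)
  sol <- solve_fba(conditioned)
  if (sol$status != "optimal" || sol$objective_value <= 1e-6)
    return(structure(list(model = model$id, grew = FALSE, growth_rate = 0,
                          uptaken = character(0), secreted = character(0)),
                     class = "exchange_profile"))
  fva <- run_fva(conditioned, fraction_of_optimum = fraction)
  ex <- exchanges(model)
  met_of <- stats::setNames(ex$metabolite, ex$reaction)
  structure(list(
    model = model$id,
    grew = TRUE,
    growth_rate = sol$objective_value,
    uptaken = unname(met_of[fva$reaction[fva$min < -1e-6]]),
    secreted = unname(met_of[fva$reaction[fva$max > 1e-6]])),
    class = "exchange_profile")
}

#' Microbial community succession simulation
#'
#' Iteratively grows every model in a shared environment. Each iteration:
#' (1) any injection scheduled for this iteration is added to the medium;
#' (2) an [exchange_profile()] is computed for every model on the cumulative
#' medium (all models are re-simulated, so an enriched medium can extend the
#' secretions of early growers); (3) every compound secreted by a growing
#' model and not yet present enters the medium at `secretion_bound` --
#' presence, not predicted quantity, is what carries the trophic effect;
#' (4) the iteration is recorded. The run stops at the trophic fixed point:
#' an iteration with no new grower, no new compound and no pending
#' injection.
#'
#' @param models list of [gsmm()] objects.
#' @param environment initial [medium()] (non-empty).
#' @param injections list of `list(iteration =, medium =)` entries: exogenous
#'   compound additions (e.g. an organic-phosphorus amendment) applied at the
#'   start of the stated iteration.
#' @param fraction FVA fraction of optimum (default 0.9).
#' @param secretion_bound uptake bound given to newly secreted compounds
#'   (default 1000 mmol/gDW/h).
#' @param max_iterations hard safety cap; defaults to
#'   `#models + #distinct exchange metabolites + #injections + 1`, which
#'   bounds the run because growers and compounds only accumulate.
#' @return object of class `succession_result`: `iterations` (list of
#'   per-iteration records with `profiles`, `new_growers`, `new_compounds`,
#'   `injected`), `cumulative_medium`, `first_growth`, `config`,
#'   `initial_compounds`, `injected_compounds` and a pooled metabolite info
#'   table (`met_info`).
#' @export
run_mcsm <- function(models, environment, injections = list(),
                     fraction = 0.9, secretion_bound = 1000,
                     max_iterations = NULL) {
  if (length(models) == 0L) stop("run_mcsm needs at least one model")
  environment <- as_medium(environment)
  if (length(environment) == 0L) stop("run_mcsm needs a non-empty environment")
  names(models) <- vapply(models, `[[`, "", "id")
  met_info <- pooled_met_info(models)
  all_ex_mets <- unique(unlist(lapply(models,
                                      function(m) exchanges(m)$metabolite)))
  if (is.null(max_iterations))
    max_iterations <- length(models) + length(all_ex_mets) +
      length(injections) + 1L
  med <- environment
  grown <- character(0)
  first_growth <- stats::setNames(integer(0), character(0))
  injected_all <- character(0)
  iterations <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    injected_now <- character(0)
    for (inj in injections) {
      if (inj$iteration != it) next
      add <- as_medium(inj$medium)
      new_ids <- setdiff(names(add), names(med))
      if (length(new_ids) > 0L)
        med <- medium(c(unclass(med), unclass(add)[new_ids]),
                      name = attr(environment, "medium_name"))
      injected_now <- c(injected_now, new_ids)
    }
    injected_all <- c(injected_all, injected_now)
    profiles <- lapply(models, exchange_profile, medium = med,
                       fraction = fraction)
    grew_now <- names(profiles)[vapply(profiles, `[[`, TRUE, "grew")]
    new_growers <- setdiff(grew_now, grown)
    grown <- union(grown, new_growers)
    first_growth[new_growers] <- it
    secreted <- unique(unlist(lapply(profiles[grew_now], `[[`, "secreted")))
    new_compounds <- setdiff(secreted, names(med))
    if (length(new_compounds) > 0L)
      med <- medium(c(unclass(med),
                      stats::setNames(rep(secretion_bound,
                                          length(new_compounds)),
                                      new_compounds)),
                    name = attr(environment, "medium_name"))
    iterations[[it]] <- list(index = it, profiles = profiles,
                             new_growers = new_growers,
                             new_compounds = new_compounds,
                             injected = injected_now)
    pending <- any(vapply(injections, function(x) x$iteration > it, TRUE))
    if (length(new_growers) == 0L && length(new_compounds) == 0L && !pending)
      break
    if (it >= max_iterations) {
      warning("run_mcsm: iteration cap reached before fixed point")
      break
    }
  }
  structure(list(iterations = iterations,
                 cumulative_medium = med,
                 first_growth = first_growth,
                 config = list(fraction = fraction,
                               secretion_bound = secretion_bound,
                               growth_eps = 1e-6, flux_eps = 1e-6,
                               injections = injections,
                               solver = "boot::simplex"),
                 initial_compounds = names(environment),
                 injected_compounds = injected_all,
                 met_info = met_info,
                 model_ids = names(models)),
            class = "succession_result")
}

pooled_met_info <- function(models) {
  info <- do.call(rbind, lapply(models, function(m)
    m$metabolites[m$metabolites$compartment == "e",
                  c("id", "name", "formula")]))
  info[!duplicated(info$id), , drop = FALSE]
}

#' @export
print.succession_result <- function(x, ...) {
  cat("<succession_result> ", length(x$iterations), " iterations, ",
      length(x$first_growth), "/", length(x$model_ids), " models grew, ",
      length(x$cumulative_medium), " compounds in the final medium\n",
      sep = "")
  invisible(x)
}

#' Three-media growth screen
#'
#' Growth rates of one model on its rich medium, its minimum-cardinality
#' poor medium (growth target 0.1/h, bounds rescaled to 1000 for the
#' screen) and the poor medium supplemented with the exudate list. The
#' expected ordering is rich >= poor+exudates >= poor: exudates can only
#' relax constraints relative to the poor medium, never beyond rich.
#'
#' @param model a [gsmm()].
#' @param exudates exudate [medium()].
#' @param growth_target target for the minimal-medium computation.
#' @return list with elements `rich`, `poor`, `poor_exudates` (growth rates,
#'   1/h) and `poor_medium` (the [medium()] found). Models infeasible on
#'   their rich medium yield an error of class `troponet_no_growth`.
#' @export
media_growth_screen <- function(model, exudates, growth_target = 0.1) {
  rich <- build_rich_medium(model)
  sol_rich <- solve_fba(apply_medium(model, rich))
  if (sol_rich$status != "optimal" || sol_rich$objective_value <= 1e-6)
    stop(structure(class = c("troponet_no_growth", "error", "condition"),
                   list(message = paste0("model '", model$id,
                                         "' does not grow on its rich medium"),
                        call = sys.call())))
  poor <- compute_minimal_medium(model, growth_target = growth_target,
                                 candidates = rich)
  poor_screen <- if (length(poor) > 0L)
    medium(stats::setNames(rep(1000, length(poor)), names(poor)),
           name = attr(poor, "medium_name"))
  else poor
  exudates <- as_medium(exudates)
  extra <- setdiff(names(exudates), names(poor_screen))
  poor_ex <- medium(c(unclass(poor_screen),
                      stats::setNames(rep(1000, length(extra)), extra)),
                    name = paste0(model$id, "_poor_exudates"))
  list(rich = sol_rich$objective_value,
       poor = solve_fba(apply_medium(model, poor_screen))$objective_value,
       poor_exudates = solve_fba(apply_medium(model, poor_ex))$objective_value,
       poor_medium = poor)
}

#' Screen models for organic-phosphorus requirements
#'
#' Unions the minimum-cardinality media of the given models and keeps the
#' compounds classifying as organic_p (carbon and phosphorus together) --
#' the amendment list used to relieve phosphorus limitation midway through a
#' succession run.
#'
#' @param models list of [gsmm()] objects.
#' @param bound uptake bound assigned to the returned compounds.
#' @param growth_target minimal-medium growth target.
#' @return a [medium()] of organic-P compounds (possibly empty).
#' @export
organic_p_screen <- function(models, bound = 1000, growth_target = 0.1) {
  met_info <- pooled_met_info(models)
  formulas <- stats::setNames(met_info$formula, met_info$id)
  found <- character(0)
  for (m in models) {
    poor <- tryCatch(compute_minimal_medium(m, growth_target = growth_target),
                     error = function(e) medium(numeric()))
    for (id in names(poor)) {
      f <- if (id %in% names(formulas)) formulas[[id]] else ""
      if (suppressWarnings(classify_compound(id, f)) == "organic_p")
        found <- union(found, id)
    }
  }
  medium(stats::setNames(rep(bound, length(found)), sort(found)),
         name = "organic_p_amendment")
}
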