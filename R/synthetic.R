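# Toy-model scaffolding ------------------------------------------------------
#
# Every generated organism follows the same minimal template: import of one
# (or more) carbon sources, a single biomass reaction converting the
# intracellular substrate(s) to product(s) plus water, and export of the
# products. Water is the shared inorganic by-product, mimicking the
# inorganic backbone of real secretion profiles without adding nutritional
# requirements.

toy_metabolite <- function(id, formula, name = id) {
  base <- strip_compartment(id)
  rbind(
    data.frame(id = paste0(base, "_e"), name = name, formula = formula,
               compartment = "e", stringsAsFactors = FALSE),
    data.frame(id = paste0(base, "_c"), name = name, formula = formula,
               compartment = "c", stringsAsFactors = FALSE))
}

# One organism: biomass consumes `inputs` (id -> coefficient, intracellular)
# and produces `outputs`, plus 1 h2o. Transport and exchange reactions are
# added for every input (import) and output (export).
toy_model <- function(id, inputs, outputs, formulas, names = NULL) {
  compounds <- unique(c(names(inputs), names(outputs), "h2o"))
  f_all <- c(formulas, h2o = "H2O")
  mets <- do.call(rbind, lapply(compounds, function(cid)
    toy_metabolite(cid, f_all[[cid]],
                   name = if (!is.null(names) && cid %in% names(names))
                     names[[cid]] else cid)))
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  rxns <- list()
  for (cid in names(inputs)) {
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("EX_", cid, "_e"),
      stats::setNames(-1, paste0(cid, "_e")), 0, 1000, is_exchange = TRUE)
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("T_", cid, "_in"),
      stats::setNames(c(-1, 1), paste0(cid, c("_e", "_c"))), 0, 1000)
  }
  biomass_stoich <- c(
    stats::setNames(-unname(inputs), paste0(names(inputs), "_c")),
    stats::setNames(unname(outputs), paste0(names(outputs), "_c")),
    stats::setNames(1, "h2o_c"))
  rxns[[length(rxns) + 1L]] <- reaction(paste0("BIOMASS_", id),
                                        biomass_stoich, 0, 1000)
  for (cid in c(names(outputs), "h2o")) {
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("T_", cid, "_out"),
      stats::setNames(c(-1, 1), paste0(cid, c("_c", "_e"))), 0, 1000)
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("EX_", cid, "_e"),
      stats::setNames(-1, paste0(cid, "_e")), 0, 1000, is_exchange = TRUE)
  }
  rxns <- rxns[!duplicated(vapply(rxns, `[[`, "", "id"))]
  gsmm(id = id, metabolites = mets, reactions = rxns,
       objective_id = paste0("BIOMASS_", id))
}

write_community <- function(models, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in models) {
    write_model(m, file.path(out_dir, paste0(m$id, ".json")), "json")
    write_model(m, file.path(out_dir, paste0(m$id, ".xml")), "sbml")
  }
  invisible(out_dir)
}

#' Generate a linear cross-feeding chain community
#'
#' Model `M_i` converts compound `S<i-1>` into `S<i>` with biomass
#' stoichiometry 2:1 (two substrate molecules per unit biomass) through
#' exchange, transport and biomass reactions. The medium carries only `S0`,
#' so the planted ground truth is a strict succession: `M_i` can first grow
#' at iteration `i`, and a community run reaches its fixed point after
#' `depth + 1` iterations.
#'
#' @param depth chain length (>= 1).
#' @param uptake_bound uptake bound for `S0` (default 10 mmol/gDW/h).
#' @param seed recorded in the community spec; the chain itself is fully
#'   deterministic.
#' @param out_dir optional directory; when given, every model is written as
#'   both JSON and SBML.
#' @return list with `models`, `environment` (a [medium()]) and `spec`
#'   (kind, parameters and planted ground truth: `first_growth`,
#'   `dependencies`).
#' @export
generate_chain_community <- function(depth, uptake_bound = 10, seed = 1L,
                                     out_dir = NULL) {
  stopifnot(depth >= 1)
  formulas <- stats::setNames(rep("C6H12O6", depth + 1L),
                              paste0("S", 0:depth))
  models <- lapply(seq_len(depth), function(i)
    toy_model(paste0("M", i),
              inputs = stats::setNames(2, paste0("S", i - 1L)),
              outputs = stats::setNames(1, paste0("S", i)),
              formulas = formulas))
  env <- medium(stats::setNames(uptake_bound, "S0_e"), name = "chain_S0")
  deps <- data.frame(
    producer = c(NA_character_, paste0("M", seq_len(depth - 1L))),
    compound = paste0("S", 0:(depth - 1L), "_e"),
    consumer = paste0("M", seq_len(depth)),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) write_community(models, out_dir)
  list(models = models, environment = env,
       spec = list(kind = "chain", depth = depth,
                   uptake_bound = uptake_bound, seed = seed,
                   ground_truth = list(
                     first_growth = stats::setNames(seq_len(depth),
                                                    paste0("M", seq_len(depth))),
                     dependencies = deps,
                     total_iterations = depth + 1L)))
}

#' Generate the cellulose-degradation fixture
#'
#' Three trophic guilds reproduce the canonical multi-step degradation of
#' cellulose oligosaccharides: a hydrolyzer cleaves the 4- and 6-unit
#' oligosaccharides to glucose (secreting the surplus), a fermenter converts
#' glucose to ethanol and acetate, and an oxidizer burns ethanol plus
#' acetate to CO2. The medium supplies only the two oligosaccharides, so
#' succession is hydrolysis, then fermentation, then oxidation; CO2 is
#' inorganic and never enters an organic-only network.
#'
#' @param uptake_bound oligosaccharide uptake bound (default 10).
#' @param out_dir optional directory for model files.
#' @return same shape as [generate_chain_community()].
#' @export
generate_cellulose_fixture <- function(uptake_bound = 10, out_dir = NULL) {
  formulas <- c(cell4 = "C24H42O21", cell6 = "C36H62O31",
                glc__D = "C6H12O6", etoh = "C2H6O", ac = "C2H3O2",
                co2 = "CO2")
  hyd <- toy_model("HYD", inputs = c(cell4 = 1, cell6 = 1),
                   outputs = c(glc__D = 8), formulas = formulas)
  # the hydrolyzer also respires part of the liberated glucose
  hyd$reactions[[length(hyd$reactions) + 1L]] <-
    reaction("GLCSINK", c(glc__D_c = -2, h2o_c = 1), 0, 1000)
  hyd <- gsmm(hyd$id, hyd$metabolites, hyd$reactions, hyd$objective_id)
  ferm <- toy_model("FERM", inputs = c(glc__D = 3),
                    outputs = c(etoh = 2, ac = 2), formulas = formulas)
  oxi <- toy_model("OXI", inputs = c(etoh = 1, ac = 1),
                   outputs = c(co2 = 4), formulas = formulas)
  models <- list(hyd, ferm, oxi)
  env <- medium(stats::setNames(c(uptake_bound, uptake_bound),
                                c("cell4_e", "cell6_e")),
                name = "cellulose_oligosaccharides")
  if (!is.null(out_dir)) write_community(models, out_dir)
  list(models = models, environment = env,
       spec = list(kind = "cellulose", uptake_bound = uptake_bound,
                   ground_truth = list(
                     first_growth = c(HYD = 1L, FERM = 2L, OXI = 3L),
                     stages = c("hydrolysis", "fermentation", "oxidation"),
                     total_iterations = 4L)))
}

#' Generate a random cross-feeding community
#'
#' Builds a random dependency DAG: a designated exudate layer of compounds
#' feeds level-one organisms, and each further organism draws its sole
#' carbon source either from the exudate layer or (with probability
#' `dependency_prob`) from the secretion of a previously generated organism.
#' Every organism secretes one fresh compound, so all planted dependencies
#' are realizable and the expected first-growth iteration of each organism
#' is its trophic level. Fully reproducible for a fixed seed.
#'
#' @param n_models number of organisms (>= 2).
#' @param n_compounds number of exudate-layer compounds.
#' @param dependency_prob probability that an organism feeds on a microbial
#'   secretion rather than an exudate.
#' @param seed RNG seed.
#' @param uptake_bound exudate uptake bound (default 10).
#' @param out_dir optional directory for model files.
#' @return same shape as [generate_chain_community()]; ground-truth
#'   `dependencies` has one row per organism (`producer` is `NA` for
#'   exudate feeders).
#' @export
generate_random_community <- function(n_models, n_compounds = 3L,
                                      dependency_prob = 0.5, seed = 1L,
                                      uptake_bound = 10, out_dir = NULL) {
  stopifnot(n_models >= 2, n_compounds >= 1,
            dependency_prob >= 0, dependency_prob <= 1)
  set.seed(seed)
  exudates <- paste0("X", seq_len(n_compounds))
  formulas <- stats::setNames(rep("C6H12O6", n_compounds), exudates)
  secretions <- character(0)   # compound -> produced by which model/level
  producer <- character(0)
  level <- stats::setNames(rep(0L, n_compounds), exudates)
  models <- vector("list", n_models)
  deps <- data.frame(producer = character(0), compound = character(0),
                     consumer = character(0), stringsAsFactors = FALSE)
  first_growth <- stats::setNames(integer(n_models),
                                  paste0("R", seq_len(n_models)))
  for (i in seq_len(n_models)) {
    mid <- paste0("R", i)
    use_secretion <- length(secretions) > 0L &&
      stats::runif(1) < dependency_prob
    source <- if (use_secretion) sample(secretions, 1L)
              else sample(exudates, 1L)
    product <- paste0("P", i)
    formulas[product] <- "C6H12O6"
    models[[i]] <- toy_model(mid, inputs = stats::setNames(2, source),
                             outputs = stats::setNames(1, product),
                             formulas = formulas)
    deps <- rbind(deps, data.frame(
      producer = if (use_secretion) producer[[source]] else NA_character_,
      compound = paste0(source, "_e"), consumer = mid,
      stringsAsFactors = FALSE))
    level[product] <- level[[source]] + 1L
    first_growth[mid] <- level[[product]]
    secretions <- c(secretions, product)
    producer[product] <- mid
  }
  env <- medium(stats::setNames(rep(uptake_bound, n_compounds),
                                paste0(exudates, "_e")),
                name = "random_exudate_layer")
  if (!is.null(out_dir)) write_community(models, out_dir)
  list(models = models, environment = env,
       spec = list(kind = "random", n_models = n_models,
                   n_compounds = n_compounds,
                   dependency_prob = dependency_prob, seed = seed,
                   uptake_bound = uptake_bound,
                   ground_truth = list(first_growth = first_growth,
                                       dependencies = deps,
                                       total_iterations = max(first_growth) + 1L)))
}
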