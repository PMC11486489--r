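# Internal LP layer ---------------------------------------------------------
#
# Flux programs -- optimize c'v subject to S v = 0, lb <= v <= ub and
# optional extra rows a'v >= rhs -- are shifted to x = v - lb >= 0, given
# upper-bound slack rows x + s = ub - lb and surplus variables for the extra
# rows, and handed to the internal two-phase simplex (see R/simplex.R).
# Deterministic for fixed inputs; reproducible to well below 1e-6.

solve_lp <- function(obj, S, lb, ub, extra = list(), maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n, all(lb <= ub))
  m <- nrow(S)
  k <- length(extra)
  nz <- 2L * n + k
  A <- matrix(0, m + n + k, nz)
  b <- numeric(m + n + k)
  A[seq_len(m), seq_len(n)] <- S
  b[seq_len(m)] <- as.vector(-S %*% lb)
  A[m + seq_len(n), seq_len(n)] <- diag(n)
  A[m + seq_len(n), n + seq_len(n)] <- diag(n)
  b[m + seq_len(n)] <- ub - lb
  for (i in seq_len(k)) {
    A[m + n + i, seq_len(n)] <- extra[[i]]$a
    A[m + n + i, 2L * n + i] <- -1
    b[m + n + i] <- extra[[i]]$rhs - sum(extra[[i]]$a * lb)
  }
  cc <- c(if (maximize) -obj else obj, rep(0, n + k))
  res <- lp_solve_standard(cc, A, b)
  if (res$status != "optimal")
    return(list(feasible = FALSE, objective = NA_real_,
                solution = rep(NA_real_, n)))
  v <- res$z[seq_len(n)] + lb
  list(feasible = TRUE, objective = sum(obj * v), solution = v)
}

# FBA ------------------------------------------------------------------------

#' Flux balance analysis
#'
#' Maximizes the biomass objective subject to steady-state mass balance
#' (S v = 0) and flux bounds. The objective value is deterministic; the flux
#' vector is one optimal vertex.
#'
#' @param model a [gsmm()].
#' @return list of class `flux_solution` with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value` (growth rate, 1/h; 0 by convention
#'   when infeasible) and `fluxes` (named vector, mmol/gDW/h).
#' @export
solve_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  rxn_ids <- colnames(S)
  obj <- as.numeric(rxn_ids == model$objective_id)
  res <- solve_lp(obj, S, bounds$lb, bounds$ub, maximize = TRUE)
  if (!res$feasible)
    return(structure(list(status = "infeasible", objective_value = 0,
                          fluxes = stats::setNames(rep(NA_real_, length(rxn_ids)),
                                                   rxn_ids)),
                     class = "flux_solution"))
  structure(list(status = "optimal",
                 objective_value = res$objective,
                 fluxes = stats::setNames(res$solution, rxn_ids)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$status,
      "  objective = ", signif(x$objective_value, 6), " /h\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' the biomass objective staying at or above `fraction_of_optimum` times the
#' FBA optimum. The full min/max range of exchange fluxes at 90% optimality
#' is what the community simulator uses to enumerate a model's uptake and
#' secretion potential.
#'
#' @param model a [gsmm()].
#' @param reactions reaction ids to scan; defaults to all exchanges.
#' @param fraction_of_optimum number in (0, 1]; default 0.9.
#' @return data.frame of class `flux_range` with columns `reaction`, `min`,
#'   `max`; the fraction used is kept in the `"fraction"` attribute.
#' @export
run_fva <- function(model, reactions = NULL, fraction_of_optimum = 0.9) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  if (is.null(reactions)) reactions <- exchanges(model)$reaction
  fba <- solve_fba(model)
  if (fba$status != "optimal" || fba$objective_value <= 1e-6)
    stop("run_fva: model '", model$id,
         "' does not grow (objective <= 1e-6); check growth before FVA")
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  rxn_ids <- colnames(S)
  missing <- setdiff(reactions, rxn_ids)
  if (length(missing) > 0L)
    stop("run_fva: unknown reaction(s): ", paste(missing, collapse = ", "))
  obj_row <- as.numeric(rxn_ids == model$objective_id)
  keep <- list(list(a = obj_row,
                    rhs = fraction_of_optimum * fba$objective_value))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    unit <- as.numeric(rxn_ids == reactions[i])
    lo <- solve_lp(unit, S, bounds$lb, bounds$ub, extra = keep,
                   maximize = FALSE)
    hi <- solve_lp(unit, S, bounds$lb, bounds$ub, extra = keep,
                   maximize = TRUE)
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  attr(out, "fraction") <- fraction_of_optimum
  class(out) <- c("flux_range", "data.frame")
  out
}

#' Model-specific rich medium
#'
#' The rich (optimal) environment of a model: every compound the model can
#' exchange, offered at the global 1000 mmol/gDW/h bound.
#'
#' @param model a [gsmm()].
#' @return a [medium()].
#' @export
build_rich_medium <- function(model) {
  mets <- exchanges(model)$metabolite
  medium(stats::setNames(rep(1000, length(mets)), mets),
         name = paste0(model$id, "_rich"))
}

#' Minimum-cardinality growth medium
#'
#' Finds the smallest subset of candidate compounds whose uptake sustains
#' growth at or above `growth_target`. The search enumerates candidate
#' subsets by increasing cardinality in lexicographic compound order, so the
#' result is the exact minimum and ties resolve to the lexicographically
#' first subset. When the candidate set is large (`> exact_limit`) an
#' approximate greedy pass is used instead (iterative removal in
#' lexicographic order) and flagged via the `"approximate"` attribute.
#'
#' @param model a [gsmm()].
#' @param growth_target minimal acceptable growth rate (1/h); default 0.1.
#' @param candidates candidate [medium()]; defaults to the model's rich
#'   medium.
#' @param exact_limit maximal candidate-set size for the exact search.
#' @return a [medium()] (bounds inherited from `candidates`).
#' @export
compute_minimal_medium <- function(model, growth_target = 0.1,
                                   candidates = build_rich_medium(model),
                                   exact_limit = 16L) {
  candidates <- as_medium(candidates)
  grows_on <- function(ids) {
    med <- medium(candidates[ids])
    sol <- solve_fba(apply_medium(model, med))
    sol$status == "optimal" && sol$objective_value >= growth_target - 1e-9
  }
  ids <- sort(intersect(names(candidates), exchanges(model)$metabolite))
  if (!grows_on(ids))
    stop("model '", model$id, "' cannot reach growth ", growth_target,
         " /h even on the full candidate set")
  if (length(ids) <= exact_limit) {
    for (k in 0:length(ids)) {
      if (k == 0L) {
        if (grows_on(character(0)))
          return(structure(medium(numeric(), name = paste0(model$id, "_poor")),
                           approximate = FALSE))
        next
      }
      combos <- utils::combn(ids, k, simplify = FALSE)
      for (sub in combos)
        if (grows_on(sub))
          return(structure(medium(candidates[sub],
                                  name = paste0(model$id, "_poor")),
                           approximate = FALSE))
    }
    stop("unreachable: full candidate set grows but no subset found")
  }
  keep <- ids
  for (id in ids) {
    trial <- setdiff(keep, id)
    if (grows_on(trial)) keep <- trial
  }
  structure(medium(candidates[keep], name = paste0(model$id, "_poor")),
            approximate = TRUE)
}
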