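#' Untangle a trophic network into PM and PMM path motifs
#'
#' Screens directed paths that start at an exudate node and end at a
#' terminal metabolite (a secreted compound no model consumes). In the
#' default `"shortest"` mode all shortest paths are enumerated per
#' (exudate, terminal) pair: a 2-edge path is a plant-microbe (PM) motif
#' (exudate -> microbe -> metabolite) and a 4-edge path is a
#' plant-microbe-microbe (PMM) motif (exudate -> microbe -> intermediate
#' metabolite -> microbe -> metabolite); a pair therefore contributes PMM
#' motifs only when no 2-edge path connects it. The `"exhaustive"` mode
#' enumerates every simple 2- and 4-edge path regardless of shortestness,
#' for sensitivity analysis. Paths are unique node sequences in both modes.
#'
#' @param net network from [build_network()].
#' @param mode `"shortest"` (default) or `"exhaustive"`.
#' @return list with data.frames `pm` (`exudate`, `model`, `metabolite`) and
#'   `pmm` (`exudate`, `model1`, `metabolite1`, `model2`, `metabolite2`).
#' @export
enumerate_motifs <- function(net, mode = c("shortest", "exhaustive")) {
  mode <- match.arg(mode)
  v <- igraph::V(net)
  exudates <- v$name[v$type == "metabolite" & v$subtype == "exudate"]
  terminals <- v$name[v$type == "metabolite" &
                        igraph::degree(net, mode = "out") == 0L]
  pm <- list()
  pmm <- list()
  for (ex in exudates) {
    if (igraph::degree(net, ex, mode = "out") == 0L) next
    targets <- setdiff(terminals, ex)
    if (length(targets) == 0L) next
    paths <- if (mode == "shortest") {
      igraph::all_shortest_paths(net, from = ex, to = targets,
                                 mode = "out")$vpaths
    } else {
      unlist(lapply(targets, function(t)
        igraph::all_simple_paths(net, from = ex, to = t, mode = "out",
                                 cutoff = 4L)), recursive = FALSE)
    }
    for (p in paths) {
      ids <- igraph::as_ids(p)
      if (length(ids) == 3L) pm[[length(pm) + 1L]] <- ids
      else if (length(ids) == 5L) pmm[[length(pmm) + 1L]] <- ids
    }
  }
  pm_df <- if (length(pm) > 0L) {
    m <- unique(do.call(rbind, pm))
    data.frame(exudate = m[, 1L], model = m[, 2L], metabolite = m[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(exudate = character(0), model = character(0),
               metabolite = character(0))
  }
  pmm_df <- if (length(pmm) > 0L) {
    m <- unique(do.call(rbind, pmm))
    data.frame(exudate = m[, 1L], model1 = m[, 2L], metabolite1 = m[, 3L],
               model2 = m[, 4L], metabolite2 = m[, 5L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(exudate = character(0), model1 = character(0),
               metabolite1 = character(0), model2 = character(0),
               metabolite2 = character(0))
  }
  list(pm = pm_df, pmm = pmm_df)
}

#' Model position usage in PMM motifs
#'
#' Counts, per model, how often it occupies the first (primary exudate
#' consumer) and second (secondary consumer) microbe position of PMM
#' motifs, and correlates the two counts across models (Pearson; p from the
#' t distribution with n-2 degrees of freedom). A negative correlation
#' indicates position/trophic-level specialisation.
#'
#' @param pmm PMM data.frame from [enumerate_motifs()].
#' @return list with `counts` (data.frame `model`, `pos1`, `pos2`),
#'   `r` and `p`.
#' @export
position_statistics <- function(pmm) {
  models <- sort(unique(c(pmm$model1, pmm$model2)))
  if (length(models) < 3L)
    stop("position_statistics needs >= 3 models with PMM participation")
  counts <- data.frame(
    model = models,
    pos1 = as.integer(table(factor(pmm$model1, levels = models))),
    pos2 = as.integer(table(factor(pmm$model2, levels = models))),
    stringsAsFactors = FALSE)
  if (stats::sd(counts$pos1) == 0 || stats::sd(counts$pos2) == 0)
    stop("position counts have zero variance; correlation undefined")
  ct <- stats::cor.test(counts$pos1, counts$pos2, method = "pearson")
  list(counts = counts, r = unname(ct$estimate), p = ct$p.value)
}

#' Compare PMM position counts between model classes
#'
#' Counts motifs per model at the requested microbe position (optionally
#' restricted to motifs whose first-position model carries
#' `condition_class`), groups the counts by the models' H/S/NA labels and
#' tests for group separation with one-way ANOVA followed by Tukey's HSD.
#' The count universe is every model appearing at either position of the
#' full motif set, zero-filled, so non-participating classes are not
#' silently dropped.
#'
#' @param pmm PMM data.frame from [enumerate_motifs()].
#' @param labels a [label_table()] covering the models.
#' @param position microbe position, 1 or 2.
#' @param condition_class optional class filter applied to the
#'   first-position model before counting.
#' @return list with `counts` (`model`, `class`, `count`), `anova`
#'   (`F`, `p`, `df`) and `tukey` (pairwise data.frame: `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
classify_and_count <- function(pmm, labels, position = 1,
                               condition_class = NULL) {
  stopifnot(position %in% c(1, 2))
  universe <- sort(unique(c(pmm$model1, pmm$model2)))
  unknown <- setdiff(universe, names(labels))
  if (length(unknown) > 0L)
    stop("unlabeled model(s): ", paste(unknown, collapse = ", "))
  if (!is.null(condition_class))
    pmm <- pmm[unclass(labels)[pmm$model1] == condition_class, , drop = FALSE]
  col <- if (position == 1) "model1" else "model2"
  counts <- data.frame(
    model = universe,
    class = unname(unclass(labels)[universe]),
    count = as.integer(table(factor(pmm[[col]], levels = universe))),
    stringsAsFactors = FALSE)
  tab <- table(counts$class)
  if (sum(tab >= 2L) < 2L)
    stop("ANOVA needs >= 2 classes with >= 2 models each")
  counts$class <- factor(counts$class)
  fit <- stats::aov(count ~ class, data = counts)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$class
  list(counts = counts,
       anova = list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                    df = unname(an[["Df"]])),
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Compound enrichment in class-labeled PM motifs
#'
#' For each class X in {H, S} and each compound occupying the `role`
#' position of PM motifs, tests whether the compound is over-represented in
#' X-labeled motifs relative to the reference population (X together with
#' NA motifs by default, all motifs when `reference = "all"`), using the
#' one-sided (upper tail) hypergeometric test. p-values are
#' Benjamini-Hochberg adjusted within each (class, role) family;
#' significance is called at q <= 0.05.
#'
#' @param pm PM data.frame from [enumerate_motifs()].
#' @param labels a [label_table()] covering the PM models.
#' @param role `"consumed"` (the exudate position) or `"secreted"` (the
#'   end-metabolite position).
#' @param reference `"na"` (class vs class+NA, default) or `"all"`.
#' @param alpha FDR threshold for the `significant` flag.
#' @param classes which classes to test; defaults to the members of
#'   `{H, S}` actually present among the labeled motifs. Requesting a class
#'   whose family is empty is an error.
#' @return data.frame with one row per (class, compound): `compound`,
#'   `role`, `class`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`.
#' @export
metabolite_enrichment <- function(pm, labels, role = c("consumed", "secreted"),
                                  reference = c("na", "all"), alpha = 0.05,
                                  classes = NULL) {
  role <- match.arg(role)
  reference <- match.arg(reference)
  col <- if (role == "consumed") "exudate" else "metabolite"
  unknown <- setdiff(unique(pm$model), names(labels))
  if (length(unknown) > 0L)
    stop("unlabeled model(s): ", paste(unknown, collapse = ", "))
  path_class <- unname(unclass(labels)[pm$model])
  if (is.null(classes)) classes <- intersect(c("H", "S"), path_class)
  if (length(classes) == 0L)
    stop("empty enrichment family: no H- or S-labeled motifs present")
  out <- list()
  for (cls in classes) {
    in_pop <- if (reference == "na") path_class %in% c(cls, "NA")
              else rep(TRUE, length(path_class))
    pop <- pm[in_pop, , drop = FALSE]
    pop_class <- path_class[in_pop]
    N <- nrow(pop)
    n <- sum(pop_class == cls)
    if (N == 0L || n == 0L || sum(pop_class == "NA") == 0L && reference == "na")
      stop("empty enrichment family for class ", cls,
           ": need both ", cls, " and reference motifs")
    compounds <- sort(unique(pop[[col]]))
    k <- as.integer(table(factor(pop[[col]][pop_class == cls],
                                 levels = compounds)))
    K <- as.integer(table(factor(pop[[col]], levels = compounds)))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    out[[cls]] <- data.frame(compound = compounds, role = role, class = cls,
                             k = k, n = n, K = K, N = N, p = p, q = q,
                             significant = q <= alpha,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
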