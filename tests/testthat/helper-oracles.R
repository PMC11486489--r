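# Independent oracles used across the suite. Every routine here is written
# from first principles (vertex enumeration, exhaustive subset search,
# recursive DFS, textbook closed forms) and never calls the package code it
# is checking.

# --- LP oracle: brute-force vertex enumeration ------------------------------
# Feasible region: S v = 0, optional extra row a'v >= rhs, lb <= v <= ub
# (all bounds finite). Every vertex has n linearly independent active
# constraints; equalities are always active, so enumerate which variables
# sit at which bound (and whether the extra row is active) and solve the
# square system.
oracle_vertices <- function(S, lb, ub, extra = NULL) {
  n <- ncol(S)
  verts <- list()
  active_sets <- if (is.null(extra)) list(NULL) else list(NULL, extra)
  for (act in active_sets) {
    Aact <- if (is.null(act)) S else rbind(S, act$a)
    rhs <- if (is.null(act)) rep(0, nrow(S)) else c(rep(0, nrow(S)), act$rhs)
    ra <- qr(Aact)$rank
    nfree <- n - ra
    if (nfree < 0) next
    subsets <- if (nfree == 0) list(integer(0))
               else utils::combn(n, nfree, simplify = FALSE)
    for (F in subsets) {
      grids <- if (nfree == 0) list(numeric(0))
               else expand.grid(rep(list(c(FALSE, TRUE)), nfree))
      if (nfree > 0) grids <- split(as.matrix(grids), seq_len(nrow(grids)))
      for (g in grids) {
        fixed <- if (nfree == 0) numeric(0)
                 else ifelse(as.logical(g), ub[F], lb[F])
        ind <- matrix(0, length(F), n)
        if (length(F) > 0) ind[cbind(seq_along(F), F)] <- 1
        M <- rbind(Aact, ind)
        d <- c(rhs, fixed)
        if (qr(M)$rank < n) next
        v <- tryCatch(qr.solve(M, d), error = function(e) NULL)
        if (is.null(v)) next
        if (max(abs(M %*% v - d)) > 1e-7) next
        if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
        if (!is.null(extra) && is.null(act) &&
            sum(extra$a * v) < extra$rhs - 1e-7) next
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  verts
}

oracle_lp_max <- function(obj, S, lb, ub, extra = NULL) {
  verts <- oracle_vertices(S, lb, ub, extra)
  if (length(verts) == 0L) return(NA_real_)
  max(vapply(verts, function(v) sum(obj * v), 0))
}

oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  bd <- troponet:::reaction_bounds(model)
  obj <- as.numeric(colnames(S) == model$objective_id)
  oracle_lp_max(obj, S, bd$lb, bd$ub)
}

oracle_fva <- function(model, rxn, fraction) {
  S <- stoichiometric_matrix(model)
  bd <- troponet:::reaction_bounds(model)
  obj <- as.numeric(colnames(S) == model$objective_id)
  opt <- oracle_lp_max(obj, S, bd$lb, bd$ub)
  extra <- list(a = obj, rhs = fraction * opt)
  verts <- oracle_vertices(S, bd$lb, bd$ub, extra)
  vals <- vapply(verts, function(v) v[[which(colnames(S) == rxn)]], 0)
  c(min = min(vals), max = max(vals))
}

# --- minimal medium oracle: exhaustive subset enumeration -------------------
# growth evaluated through the vertex-enumeration LP oracle, with exchange
# bounds rewritten by hand; subsets scanned by increasing cardinality in
# lexicographic order, mirroring the documented tie-break
oracle_grows_on <- function(model, sub, candidates, target) {
  S <- stoichiometric_matrix(model)
  bd <- troponet:::reaction_bounds(model)
  ex <- exchanges(model)
  for (r in seq_len(ncol(S))) {
    rid <- colnames(S)[r]
    if (rid %in% ex$reaction) {
      met <- ex$metabolite[ex$reaction == rid]
      bd$lb[r] <- if (met %in% sub) -min(candidates[[met]], 1000) else 0
    }
  }
  obj <- as.numeric(colnames(S) == model$objective_id)
  opt <- oracle_lp_max(obj, S, bd$lb, bd$ub)
  !is.na(opt) && opt >= target - 1e-9
}

oracle_minimal_medium <- function(model, growth_target, candidates) {
  ids <- sort(intersect(names(candidates), exchanges(model)$metabolite))
  stopifnot(length(ids) <= 8)
  for (k in 0:length(ids)) {
    subs <- if (k == 0) list(character(0))
            else utils::combn(ids, k, simplify = FALSE)
    for (sub in subs)
      if (oracle_grows_on(model, sub, candidates, growth_target))
        return(sub)
  }
  NULL
}

# --- motif oracle: recursive simple-path DFS --------------------------------
# Works on a plain edge list; returns PM (3 nodes) and PMM (5 nodes) paths
# starting at exudate nodes and ending at terminal metabolites, optionally
# applying the per-(exudate, terminal) shortest-pair filter.
oracle_motifs <- function(edges, exudates, metabolites, shortest = TRUE) {
  adj <- split(edges$to, edges$from)
  terminals <- setdiff(metabolites, unique(edges$from))
  paths <- list()
  walk <- function(node, path) {
    if (length(path) > 5L) return()
    if (length(path) %in% c(3L, 5L) && node %in% terminals)
      paths[[length(paths) + 1L]] <<- path
    for (nxt in adj[[node]])
      if (!nxt %in% path) walk(nxt, c(path, nxt))
  }
  for (ex in exudates) walk(ex, ex)
  if (shortest && length(paths) > 0L) {
    len <- vapply(paths, length, 0L)
    key <- vapply(paths, function(p) paste(p[1], p[length(p)]), "")
    shortest_len <- tapply(len, key, min)
    paths <- paths[len == shortest_len[key]]
  }
  pm <- Filter(function(p) length(p) == 3L, paths)
  pmm <- Filter(function(p) length(p) == 5L, paths)
  list(pm = unique(lapply(pm, paste, collapse = ">")),
       pmm = unique(lapply(pmm, paste, collapse = ">")))
}

# random bipartite exchange network with the attribute schema build_network
# produces; deduplicated edges, no self-reversals needed
random_bipartite_network <- function(seed, n_models = 6, n_mets = 12,
                                     p_uptake = 0.25, p_secrete = 0.25,
                                     n_exudates = 3) {
  set.seed(seed)
  models <- paste0("m", seq_len(n_models))
  mets <- paste0("c", seq_len(n_mets))
  edges <- NULL
  for (mo in models) {
    up <- mets[runif(n_mets) < p_uptake]
    sec <- mets[runif(n_mets) < p_secrete]
    edges <- rbind(edges,
                   if (length(up)) data.frame(from = up, to = mo,
                                              direction = "uptake"),
                   if (length(sec)) data.frame(from = mo, to = sec,
                                               direction = "secretion"))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        direction = character(0))
  edges <- unique(edges)
  exudates <- mets[seq_len(n_exudates)]
  vertices <- rbind(
    data.frame(name = models, type = "model", subtype = NA_character_,
               class = NA_character_),
    data.frame(name = mets, type = "metabolite",
               subtype = ifelse(mets %in% exudates, "exudate", "secreted"),
               class = NA_character_))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  list(graph = g, edges = edges, exudates = exudates, metabolites = mets)
}

# --- closed-form statistics oracles -----------------------------------------
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  k <- length(unique(groups))
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  F <- msb / msw
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE),
       msw = msw, df = N - k)
}

oracle_tukey <- function(values, groups) {
  base <- oracle_anova(values, groups)
  lev <- sort(unique(as.character(groups)))
  ns <- tapply(values, as.character(groups), length)[lev]
  means <- tapply(values, as.character(groups), mean)[lev]
  out <- NULL
  for (i in seq_along(lev)) for (j in seq_len(i - 1L)) {
    se <- sqrt(base$msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    out <- rbind(out, data.frame(
      comparison = paste0(lev[i], "-", lev[j]),
      diff = unname(means[i] - means[j]),
      p_adj = stats::ptukey(q, length(lev), base$df, lower.tail = FALSE)))
  }
  out
}

# exact upper-tail hypergeometric by direct combinatorial sum
oracle_hyper_upper <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}

# --- tiny designed fixtures (<= 6 reactions each) ---------------------------
fix_chain_min <- function(uptake = 10) {
  mets <- rbind(
    data.frame(id = "S0_e", name = "S0", formula = "C6H12O6",
               compartment = "e"),
    data.frame(id = "S1_e", name = "S1", formula = "C6H12O6",
               compartment = "e"))
  gsmm("chain_min", mets, list(
    reaction("EX_S0_e", c(S0_e = -1), -uptake, 1000, is_exchange = TRUE),
    reaction("BIO", c(S0_e = -2, S1_e = 1), 0, 1000),
    reaction("EX_S1_e", c(S1_e = -1), 0, 1000, is_exchange = TRUE)),
    objective_id = "BIO")
}

fix_branch <- function(uptake = 10) {
  mets <- rbind(
    data.frame(id = "S0_e", name = "S0", formula = "C6H12O6",
               compartment = "e"),
    data.frame(id = "P_c", name = "P", formula = "C3H6O3",
               compartment = "c"),
    data.frame(id = "A_e", name = "A", formula = "C3H6O3",
               compartment = "e"),
    data.frame(id = "B_e", name = "B", formula = "C3H6O3",
               compartment = "e"))
  gsmm("branch", mets, list(
    reaction("EX_S0_e", c(S0_e = -1), -uptake, 1000, is_exchange = TRUE),
    reaction("BIO", c(S0_e = -2, P_c = 1), 0, 1000),
    reaction("RXA", c(P_c = -1, A_e = 1), 0, 1000),
    reaction("RXB", c(P_c = -1, B_e = 1), 0, 1000),
    reaction("EX_A_e", c(A_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("EX_B_e", c(B_e = -1), 0, 1000, is_exchange = TRUE)),
    objective_id = "BIO")
}

fix_twosource <- function(uptake = 10) {
  mets <- rbind(
    data.frame(id = "C1_e", name = "C1", formula = "C6H12O6",
               compartment = "e"),
    data.frame(id = "C2_e", name = "C2", formula = "C6H12O6",
               compartment = "e"),
    data.frame(id = "X_c", name = "X", formula = "C6H12O6",
               compartment = "c"),
    data.frame(id = "W_e", name = "W", formula = "C3H6O3",
               compartment = "e"))
  gsmm("twosource", mets, list(
    reaction("EX_C1_e", c(C1_e = -1), -uptake, 1000, is_exchange = TRUE),
    reaction("EX_C2_e", c(C2_e = -1), -uptake, 1000, is_exchange = TRUE),
    reaction("RX1", c(C1_e = -1, X_c = 1), 0, 1000),
    reaction("RX2", c(C2_e = -1, X_c = 1), 0, 1000),
    reaction("BIO", c(X_c = -2, W_e = 1), 0, 1000),
    reaction("EX_W_e", c(W_e = -1), 0, 1000, is_exchange = TRUE)),
    objective_id = "BIO")
}

small_fixture_models <- function() {
  list(fix_chain_min(), fix_branch(), fix_twosource())
}
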