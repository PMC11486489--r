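# chain of depth 2 in which the first organism also secretes an unconsumed
# organic by-product W: exactly one PM and one PMM motif by construction
chain_with_W <- function() {
  f <- c(S0 = "C6H12O6", S1 = "C6H12O6", S2 = "C6H12O6", W = "C3H6O3")
  m1 <- troponet:::toy_model("M1", inputs = c(S0 = 2),
                             outputs = c(S1 = 1, W = 1), formulas = f)
  m2 <- troponet:::toy_model("M2", inputs = c(S1 = 2),
                             outputs = c(S2 = 1), formulas = f)
  res <- run_mcsm(list(m1, m2), medium(c(S0_e = 10)))
  build_network(res)
}

test_that("motif untangling matches the designed chain ground truth", {
  comm <- generate_chain_community(2)
  res <- run_mcsm(comm$models, comm$environment)
  mo <- enumerate_motifs(build_network(res))
  expect_identical(nrow(mo$pm), 0L)
  expect_identical(nrow(mo$pmm), 1L)
  expect_identical(unlist(mo$pmm[1, ], use.names = FALSE),
                   c("S0_e", "M1", "S1_e", "M2", "S2_e"))
  net <- chain_with_W()
  mo2 <- enumerate_motifs(net)
  expect_identical(nrow(mo2$pm), 1L)
  expect_identical(unlist(mo2$pm[1, ], use.names = FALSE),
                   c("S0_e", "M1", "W_e"))
  expect_identical(nrow(mo2$pmm), 1L)
})

test_that("a network without terminal metabolites has no motifs", {
  edges <- data.frame(from = c("x", "m", "y"), to = c("m", "y", "m"),
                      direction = c("uptake", "secretion", "uptake"))
  vertices <- data.frame(
    name = c("x", "m", "y"), type = c("metabolite", "model", "metabolite"),
    subtype = c("exudate", NA, "secreted"), class = NA_character_)
  g <- igraph::graph_from_data_frame(edges, vertices = vertices)
  mo <- enumerate_motifs(g)
  expect_identical(nrow(mo$pm), 0L)
  expect_identical(nrow(mo$pmm), 0L)
})

test_that("motif enumeration equals brute-force DFS on 20 seeded networks", {
  for (seed in 1:20) {
    rb <- random_bipartite_network(seed)
    for (mode in c("shortest", "exhaustive")) {
      mo <- enumerate_motifs(rb$graph, mode = mode)
      ora <- oracle_motifs(rb$edges, rb$exudates, rb$metabolites,
                           shortest = (mode == "shortest"))
      got_pm <- if (nrow(mo$pm)) paste(mo$pm$exudate, mo$pm$model,
                                       mo$pm$metabolite, sep = ">")
                else character(0)
      got_pmm <- if (nrow(mo$pmm))
        paste(mo$pmm$exudate, mo$pmm$model1, mo$pmm$metabolite1,
              mo$pmm$model2, mo$pmm$metabolite2, sep = ">")
        else character(0)
      expect_setequal(got_pm, as.character(unlist(ora$pm)))
      expect_setequal(got_pmm, as.character(unlist(ora$pmm)))
    }
    # exhaustive mode can only add paths
    sh <- enumerate_motifs(rb$graph, mode = "shortest")
    exh <- enumerate_motifs(rb$graph, mode = "exhaustive")
    expect_gte(nrow(exh$pm), nrow(sh$pm))
    expect_gte(nrow(exh$pmm), nrow(sh$pmm))
  }
})

test_that("PMM structural invariants hold on enumerated fixtures", {
  rb <- random_bipartite_network(2, n_models = 8, n_mets = 14)
  mo <- enumerate_motifs(rb$graph)
  deg_out <- igraph::degree(rb$graph, mode = "out")
  expect_gt(nrow(mo$pm), 0)
  expect_gt(nrow(mo$pmm), 0)
  expect_true(all(mo$pmm$model1 != mo$pmm$model2))
  expect_true(all(deg_out[mo$pmm$metabolite2] == 0))
  expect_true(all(deg_out[mo$pmm$metabolite1] > 0))
  expect_true(all(deg_out[mo$pm$metabolite] == 0))
  # every PM-shaped prefix of a PMM uses existing, correctly directed edges
  el <- igraph::as_edgelist(rb$graph)
  keys <- paste(el[, 1], el[, 2])
  for (i in seq_len(nrow(mo$pmm))) {
    p <- unlist(mo$pmm[i, ], use.names = FALSE)
    expect_true(all(paste(p[-5], p[-1]) %in% keys))
  }
  # position-count bookkeeping: both sides sum to the motif count
  ps <- position_statistics(mo$pmm)
  expect_identical(sum(ps$counts$pos1), nrow(mo$pmm))
  expect_identical(sum(ps$counts$pos2), nrow(mo$pmm))
})

test_that("position correlation matches the closed form and rejects degeneracy", {
  pmm <- data.frame(
    exudate = "x",
    model1 = c(rep("a", 10), rep("c", 5)),
    metabolite1 = "i",
    model2 = c(rep("b", 10), rep("c", 5)),
    metabolite2 = "t")
  ps <- position_statistics(pmm)
  # counts: a=(10,0), b=(0,10), c=(5,5); exact Pearson r by direct formula
  x <- c(10, 0, 5); y <- c(0, 10, 5)
  r_exact <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ps$r, r_exact, tolerance = 1e-12)
  expect_lt(ps$r, 0)
  t_stat <- r_exact * sqrt(1 / (1 - r_exact^2))   # n - 2 = 1
  expect_equal(ps$p, 2 * stats::pt(-abs(t_stat), 1), tolerance = 1e-12)
  expect_error(position_statistics(pmm[1:10, ]), ">= 3 models")
  flat <- data.frame(exudate = "x", model1 = c("a", "b", "c"),
                     metabolite1 = "i", model2 = c("a", "b", "c"),
                     metabolite2 = "t")
  expect_error(position_statistics(flat), "zero variance")
})

test_that("class comparison of position counts matches a closed-form oracle", {
  # plant position-1 counts H:{2,3,4}, S:{10,11,12}, NA:{2,3,4} over 9 models
  counts <- c(2, 3, 4, 10, 11, 12, 2, 3, 4)
  mods <- paste0("g", 1:9)
  labels <- label_table(stats::setNames(
    rep(c("H", "S", "NA"), each = 3), mods))
  rows <- rep(seq_along(mods), counts)
  pmm <- data.frame(exudate = "x", model1 = mods[rows], metabolite1 = "i",
                    model2 = sample(rep(mods, length.out = length(rows))),
                    metabolite2 = "t")
  got <- classify_and_count(pmm, labels, position = 1)
  expect_identical(stats::setNames(got$counts$count, got$counts$model),
                   stats::setNames(as.integer(counts), mods))
  ora <- oracle_anova(counts, rep(c("H", "S", "NA"), each = 3))
  expect_equal(got$anova$F, ora$F, tolerance = 1e-9)
  expect_equal(got$anova$p, ora$p, tolerance = 1e-9)
  otk <- oracle_tukey(counts, rep(c("H", "S", "NA"), each = 3))
  merged <- merge(got$tukey, otk, by = "comparison")
  expect_gt(nrow(merged), 0)
  expect_equal(merged$p_adj.x, merged$p_adj.y, tolerance = 1e-8)
  expect_equal(merged$diff.x, merged$diff.y, tolerance = 1e-9)
  # S initiates significantly more motifs than H and NA here
  expect_lt(got$tukey$p_adj[got$tukey$comparison == "S-H"], 0.005)
  # identical class multisets: F = 0, p = 1
  counts2 <- c(1, 2, 1, 2)
  mods2 <- paste0("h", 1:4)
  labels2 <- label_table(stats::setNames(c("H", "H", "S", "S"), mods2))
  pmm2 <- data.frame(exudate = "x", model1 = mods2[rep(1:4, counts2)],
                     metabolite1 = "i",
                     model2 = mods2[rep(c(3, 4, 1, 2), counts2)],
                     metabolite2 = "t")
  got2 <- classify_and_count(pmm2, labels2, position = 1)
  expect_equal(got2$anova$F, 0, tolerance = 1e-12)
  expect_equal(got2$anova$p, 1, tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches exact combinatorial sums", {
  # 10 H and 10 NA paths; compound X consumed in 8 H and 1 NA path
  mods <- c(paste0("H", 1:10), paste0("N", 1:10))
  labels <- label_table(stats::setNames(rep(c("H", "NA"), each = 10), mods))
  exu <- c(rep("X", 8), "u1", "u2", "X", paste0("v", 1:9))
  pm <- data.frame(exudate = exu, model = mods,
                   metabolite = paste0("s", 1:20))
  res <- metabolite_enrichment(pm, labels, role = "consumed")
  rX <- res[res$compound == "X" & res$class == "H", ]
  expect_identical(c(rX$k, rX$n, rX$K, rX$N), c(8L, 10L, 9L, 20L))
  expect_equal(rX$p, oracle_hyper_upper(8, 9, 20, 10), tolerance = 1e-12)
  expect_equal(rX$p, sum(choose(9, 8:9) * choose(11, 10 - (8:9))) /
                 choose(20, 10), tolerance = 1e-12)
  # a compound present in every population path is never enriched
  pm2 <- data.frame(exudate = "Z", model = mods,
                    metabolite = paste0("s", 1:20))
  res2 <- metabolite_enrichment(pm2, labels, role = "consumed")
  expect_equal(res2$p[res2$compound == "Z" & res2$class == "H"], 1,
               tolerance = 1e-12)
  # absent from the tested class (k = 0): p = 1
  pm3 <- pm
  pm3$exudate[pm3$model == "H1"] <- "u9"
  pm3$exudate[1:20] <- ifelse(grepl("^H", pm3$model), "u0", "onlyNA")
  res3 <- metabolite_enrichment(pm3, labels, role = "consumed")
  expect_equal(res3$p[res3$compound == "onlyNA" & res3$class == "H"], 1,
               tolerance = 1e-12)
  # requesting a class with no labeled motifs is an error
  expect_error(metabolite_enrichment(pm, labels, role = "secreted",
                                     classes = "S"),
               "empty enrichment family")
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  set.seed(4)
  mods <- c(paste0("H", 1:30), paste0("N", 1:30), paste0("S", 1:30))
  labels <- label_table(stats::setNames(rep(c("H", "NA", "S"), each = 30),
                                        mods))
  pm <- data.frame(
    exudate = sample(paste0("e", 1:6), 90, replace = TRUE),
    model = mods,
    metabolite = sample(paste0("w", 1:8), 90, replace = TRUE))
  res <- metabolite_enrichment(pm, labels, role = "secreted")
  for (cls in c("H", "S")) {
    fam <- res[res$class == cls, ]
    expect_equal(fam$q, oracle_bh(fam$p), tolerance = 1e-12)
    expect_true(all(fam$q >= fam$p - 1e-12))
    expect_true(all(fam$k <= pmin(fam$n, fam$K)))
    # ordering by p gives monotone q
    o <- order(fam$p)
    expect_true(all(diff(fam$q[o]) >= -1e-12))
  }
})
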