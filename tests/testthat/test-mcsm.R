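test_that("exchange profiles capture forced uptake/secretion coupling", {
  comm <- generate_chain_community(2)
  p1 <- exchange_profile(comm$models[[1]], comm$environment)
  expect_true(p1$grew)
  expect_equal(p1$growth_rate, 5, tolerance = 1e-8)
  expect_true("S0_e" %in% p1$uptaken)
  expect_true("S1_e" %in% p1$secreted)
  # second chain member has no usable carbon in the S0 environment
  p2 <- exchange_profile(comm$models[[2]], comm$environment)
  expect_false(p2$grew)
  expect_identical(p2$uptaken, character(0))
  expect_identical(p2$secreted, character(0))
  # uptake can only come from the offered medium
  expect_true(all(p1$uptaken %in% names(comm$environment)))
})

test_that("relaxing the optimality fraction never shrinks the secretion set", {
  for (seed in 1:10) {
    comm <- generate_random_community(3, 2, 0.4, seed = seed)
    for (m in comm$models) {
      rich <- build_rich_medium(m)
      strict <- exchange_profile(m, rich, fraction = 1)
      relaxed <- exchange_profile(m, rich, fraction = 0.9)
      if (!strict$grew) next
      expect_true(all(strict$secreted %in% relaxed$secreted),
                  label = paste("secretion superset,", m$id, "seed", seed))
    }
  }
})

test_that("succession on chains recovers the planted trophic order", {
  for (depth in c(1, 4)) {
    comm <- generate_chain_community(depth)
    res <- run_mcsm(comm$models, comm$environment)
    expect_identical(res$first_growth[paste0("M", seq_len(depth))],
                     comm$spec$ground_truth$first_growth)
    expect_length(res$iterations, depth + 1L)
    last <- res$iterations[[length(res$iterations)]]
    expect_length(last$new_growers, 0L)
    expect_length(last$new_compounds, 0L)
  }
  # an environment missing the root compound supports nobody
  comm <- generate_chain_community(2)
  res0 <- run_mcsm(comm$models, medium(c(unrelated_e = 10)))
  expect_length(res0$first_growth, 0L)
  expect_length(res0$iterations, 1L)
})

test_that("medium and grower sets grow monotonically and runs are reproducible", {
  comm <- generate_random_community(6, 3, 0.6, seed = 11)
  res <- run_mcsm(comm$models, comm$environment)
  med_size <- 0L
  growers <- character(0)
  for (rec in res$iterations) {
    expect_length(intersect(rec$new_growers, growers), 0L)
    growers <- union(growers, rec$new_growers)
    expect_gte(length(rec$new_compounds), 0L)
    med_size <- med_size + length(rec$new_compounds) + length(rec$injected)
  }
  expect_identical(length(res$cumulative_medium),
                   length(comm$environment) + med_size)
  res2 <- run_mcsm(comm$models, comm$environment)
  expect_equal(res, res2, tolerance = 1e-6)
})

test_that("injections extend growth without ever removing a grower", {
  comm <- generate_chain_community(2)
  # an organism whose sole carbon source arrives only by injection
  extra <- troponet:::toy_model("NEEDY", inputs = c(g3p = 2),
                                outputs = c(gly = 1),
                                formulas = c(g3p = "C3H7O6P",
                                             gly = "C2H5NO2"))
  models <- c(comm$models, list(extra))
  plain <- run_mcsm(models, comm$environment)
  expect_false("NEEDY" %in% names(plain$first_growth))
  inj <- list(list(iteration = 2L, medium = medium(c(g3p_e = 1000))))
  boosted <- run_mcsm(models, comm$environment, injections = inj)
  expect_identical(unname(boosted$first_growth[["NEEDY"]]), 2L)
  expect_true(all(names(plain$first_growth) %in% names(boosted$first_growth)))
  expect_true("g3p_e" %in% boosted$injected_compounds)
  # pending injections keep the run alive even across a quiet iteration
  late <- run_mcsm(comm$models, comm$environment,
                   injections = list(list(iteration = 6L,
                                          medium = medium(c(g3p_e = 1000)))))
  expect_gte(length(late$iterations), 6L)
})

test_that("the three-media screen is ordered rich >= poor+exudates >= poor", {
  exu <- apple_root_exudates()
  models <- c(generate_chain_community(2)$models,
              generate_random_community(3, 2, 0.5, seed = 5)$models)
  for (m in models) {
    sc <- media_growth_screen(m, exu)
    expect_gte(sc$rich, sc$poor_exudates - 1e-8)
    expect_gte(sc$poor_exudates, sc$poor - 1e-8)
    expect_gte(sc$poor, 0.1 - 1e-9)
  }
  # an exudate already inside the poor medium changes nothing
  m1 <- generate_chain_community(1)$models[[1]]
  sc <- media_growth_screen(m1, medium(c(S0_e = 1000)))
  expect_equal(sc$poor_exudates, sc$poor, tolerance = 1e-9)
})

test_that("the rhizosphere environment is the checked union of its two lists", {
  env <- build_rhizosphere_environment()
  expect_length(env, 93L)
  expect_length(attr(env, "exudate_ids"), 33L)
  expect_error(
    build_rhizosphere_environment(
      exudates = medium(c(glc__D_e = 1000)),
      inorganics = medium(c(nh4_e = 1000, glc__D_e = 1000)),
      formulas = c(glc__D_e = "C6H12O6", nh4_e = "H4N")),
    "overlap")
  expect_error(
    build_rhizosphere_environment(
      exudates = medium(c(pyr_e = 1000)),
      inorganics = medium(c(glc__D_e = 1000)),
      formulas = c(pyr_e = "C3H3O3", glc__D_e = "C6H12O6")),
    "organic compound")
  expect_error(
    build_rhizosphere_environment(
      exudates = medium(c(nh4_e = 1000)),
      inorganics = medium(c(pi_e = 1000)),
      formulas = c(nh4_e = "H4N", pi_e = "HO4P")),
    "non-organic")
})

test_that("the organic-P screen finds phosphorus-bearing carbon requirements", {
  needy <- troponet:::toy_model("PDEP", inputs = c(g3p = 2),
                                outputs = c(gly = 1),
                                formulas = c(g3p = "C3H7O6P",
                                             gly = "C2H5NO2"))
  plain <- generate_chain_community(1)$models[[1]]
  amendment <- organic_p_screen(list(needy, plain))
  expect_identical(names(amendment), "g3p_e")
  expect_equal(unname(amendment[["g3p_e"]]), 1000)
})
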