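test_that("annualization follows the class-specific exponents", {
  expect_equal(annualize(1, "adult"), 1)
  expect_equal(annualize(1, "cub"), 1)
  expect_equal(annualize(0.9, "adult"), 0.9^6)
  expect_equal(annualize(0.9, "subadult"), 0.9^6)
  expect_equal(annualize(0.9, "cub"), 0.9^4.795, tolerance = 1e-12)
  expect_error(annualize(1.2, "adult"), "0, 1")
  expect_error(annualize(0, "cub"), "0, 1")
})

test_that("cub mortality arithmetic reproduces both labeled ratios", {
  r <- cub_mortality_rate(309, 279, 53)
  expect_equal(r$mortality, 53 / 226)
  expect_equal(round(r$mortality, 3), 0.235)
  expect_equal(r$mortality_naive, 53 / 279)
  expect_equal(cub_mortality_rate(10, 10, 0)$mortality, 0)
  expect_equal(cub_mortality_rate(10, 10, 5)$mortality, 1)
  expect_error(cub_mortality_rate(5, 0, 0), "eligible")
})

test_that("cub mortality counts are extracted from a history", {
  # 3 cubs enter: one resighted as subadult, one never again (eligible),
  # one too young to have reached age 1 by study end
  T <- 12
  end <- seq(as.Date("2010-06-01"), by = "2 months", length.out = T + 1)[T + 1]
  g <- build_occasion_grid(as.Date("2010-06-01"), end, 2)
  individuals <- data.frame(
    id = c("a", "b", "c"), sex = "U",
    birth_date = as.Date(c("2010-05-01", "2010-05-01", "2011-11-01")),
    death_date = as.Date(NA))
  sightings <- data.frame(
    id = c("a", "a", "b", "c"),
    date = as.Date(c("2010-08-15", "2011-08-15", "2010-08-15", "2012-02-15")))
  h <- build_cjs_history(sightings, individuals, g)
  r <- approximate_cub_mortality(h)
  expect_equal(r$n_first_cub, 3)
  expect_equal(r$n_eligible, 2)
  expect_equal(r$n_never_after, 1)
  expect_equal(r$mortality, 1)
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(31)
  mat <- matrix(rbinom(600, 1, 0.5), 60, 10); mat[, 1] <- 1L
  h <- tiny_history(mat)
  f1 <- suppressWarnings(fit_cjs(h, quick_mcmc(seed = 5, n_iter = 200, n_burnin = 50)))
  f2 <- suppressWarnings(fit_cjs(h, quick_mcmc(seed = 5, n_iter = 200, n_burnin = 50)))
  expect_identical(f1$draws, f2$draws)
})

test_that("with detection forced to 1 the posterior matches the known-fate closed form", {
  cfg <- sim_config(n_clans = 1, initial_clan_size = 120, recruitment_rate = 0,
                    init_class_probs = c(0, 0, 1), mu_p = 20, sigma_p = 0,
                    wet_range_contraction = 1, p_death_obs = 0,
                    study_end = as.Date("2012-06-01"), sex_assignment_k = Inf,
                    seed = 17)
  sim <- simulate_population(cfg)
  g <- build_occasion_grid(cfg$study_start, cfg$study_end, 2)
  h <- build_cjs_history(sim$sightings, sim$individuals, g)
  f <- suppressWarnings(fit_cjs(h, quick_mcmc(seed = 2, n_iter = 1500, n_burnin = 300)))
  # with p = 1 every survival step is observed: phi | data ~ Beta(1+s, 1+f)
  for (sx in c("F", "M")) {
    det <- h$matrix[h$sex == sx, , drop = FALSE]
    s <- f0 <- 0
    for (i in seq_len(nrow(det))) {
      last <- max(which(det[i, ] == 1))
      s <- s + (last - which(det[i, ] == 1)[1])
      f0 <- f0 + (last < ncol(det))
    }
    closed_form <- (1 + s) / (2 + s + f0)
    got <- f$survival$phi_2mo_mean[f$survival$age_class == "adult" &
                                     f$survival$sex == sx]
    expect_lt(abs(got - closed_form), 0.02)
  }
})

test_that("credible intervals shrink as sample size grows", {
  width <- vapply(c(150, 600), function(n) {
    cfg <- sim_config(n_clans = 1, initial_clan_size = n, recruitment_rate = 0,
                      init_class_probs = c(0, 0, 1), wet_range_contraction = 1,
                      p_death_obs = 0, sex_assignment_k = Inf, seed = 23,
                      study_end = as.Date("2015-06-01"))
    sim <- simulate_population(cfg)
    g <- build_occasion_grid(cfg$study_start, cfg$study_end, 2)
    h <- build_cjs_history(sim$sightings, sim$individuals, g)
    f <- fit_cjs(h, quick_mcmc(seed = 3, n_iter = 800, n_burnin = 200))
    s <- f$survival[f$survival$age_class == "adult", ]
    mean(s$phi_annual_upper - s$phi_annual_lower)
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("the collaring contrast behaves under null and planted effects", {
  # null: collaring survival-neutral
  cfg <- recovery_config(seed = 33)
  sim <- simulate_population(cfg)
  g <- build_occasion_grid(cfg$study_start, cfg$study_end, 2)
  h <- build_cjs_history(sim$sightings, sim$individuals, g)
  expect_gt(sum(h$collared), 0)
  ce <- suppressWarnings(collaring_effect(h, quick_mcmc(seed = 4, n_iter = 800, n_burnin = 200)))
  expect_true(ce$spans_zero)
  # planted strong negative effect on collared adults
  cfg2 <- sim_config(seed = 34, wet_range_contraction = 1, range_sd_wet = 3,
                     sex_assignment_k = Inf, p_death_obs = 0,
                     collar_effect_logit = -1.5, collars_per_clan = 6)
  sim2 <- simulate_population(cfg2)
  h2 <- build_cjs_history(sim2$sightings, sim2$individuals,
                          build_occasion_grid(cfg2$study_start,
                                              cfg2$study_end, 2))
  ce2 <- collaring_effect(h2, quick_mcmc(seed = 4, n_iter = 800, n_burnin = 200))
  expect_false(ce2$spans_zero)
  expect_lt(ce2$beta["upper"], 0)
  # degenerate input: everyone collared
  h3 <- h
  h3$collared <- rep(TRUE, nrow(h3$matrix))
  expect_error(collaring_effect(h3), "no contrast")
})

test_that("sex-specific detection recovers planted and null structures", {
  # the generator's sexing process leaves rarely-seen animals unsexed, so
  # detection for the U class must come out lowest
  cfg <- sim_config(seed = 41, wet_range_contraction = 1, range_sd_wet = 3,
                    p_death_obs = 0)
  sim <- simulate_population(cfg)
  g <- build_occasion_grid(cfg$study_start, cfg$study_end, 2)
  h <- build_cjs_history(sim$sightings, sim$individuals, g)
  ps <- fit_sex_specific_p(h, quick_mcmc(seed = 6, n_iter = 800, n_burnin = 200))
  pU <- ps[ps$sex == "U", ]
  pF <- ps[ps$sex == "F", ]; pM <- ps[ps$sex == "M", ]
  expect_lt(pU$upper, pF$lower)
  expect_lt(pU$upper, pM$lower)
  # null: permuting sex labels breaks the link between sexing and detection
  ind2 <- sim$individuals
  set.seed(99)
  ind2$sex <- sample(ind2$sex)
  h0 <- build_cjs_history(sim$sightings, ind2, g)
  ps0 <- fit_sex_specific_p(h0, quick_mcmc(seed = 6, n_iter = 800, n_burnin = 200))
  expect_lt(max(ps0$lower), min(ps0$upper)) # all three intervals overlap
  # absent level
  ind1 <- sim$individuals[sim$individuals$sex == "F", ]
  s1 <- sim$sightings[sim$sightings$id %in% ind1$id, ]
  h1 <- build_cjs_history(s1, ind1, g)
  expect_error(fit_sex_specific_p(h1), "sex level")
})

test_that("the convergence flag mirrors the R-hat table", {
  set.seed(51)
  mat <- matrix(rbinom(80, 1, 0.5), 8, 10); mat[, 1] <- 1L
  h <- tiny_history(mat)
  f <- suppressWarnings(fit_cjs(h, mcmc_config(n_iter = 60, n_burnin = 0,
                                               seed = 1)))
  expect_identical(f$converged,
                   all(f$diagnostics$rhat < 1.1, na.rm = TRUE))
})
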