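test_that("simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_clans = 3, initial_clan_size = 8,
                    study_end = as.Date("2012-06-01"), seed = 42)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$sightings, b$sightings)
  expect_identical(a$truth$detected, b$truth$detected)
})

test_that("survivor counts match the binomial expectation", {
  # 100 adults, annual survival 0.86, 14 months = 7 occasions so the 7th
  # records the state after 6 two-month survival steps (one full year)
  survivors <- vapply(1:500, function(s) {
    sim <- simulate_population(sim_config(
      n_clans = 1, initial_clan_size = 100, recruitment_rate = 0,
      init_class_probs = c(0, 0, 1), study_start = as.Date("2010-06-01"),
      study_end = as.Date("2011-08-01"), p_death_obs = 0, seed = s))
    sum(sim$truth$alive[, 7])
  }, numeric(1))
  expect_lt(abs(mean(survivors) - 86), 3)
})

test_that("detection heterogeneity overdisperses per-individual counts", {
  base <- list(n_clans = 1, initial_clan_size = 400, recruitment_rate = 0,
               init_class_probs = c(0, 0, 1),
               phi_annual = c(cub = 1, subadult = 1, adult = 1),
               wet_range_contraction = 1, seed = 5)
  v <- vapply(c(0, 1), function(sg) {
    sim <- do.call(sim_config, c(base, list(sigma_p = sg)))
    var(rowSums(simulate_population(sim)$truth$detected))
  }, numeric(1))
  expect_gt(v[2], v[1])
})

test_that("no sighting postdates death or predates birth", {
  sim <- simulate_population(sim_config(n_clans = 4, initial_clan_size = 15,
                                        study_end = as.Date("2014-06-01"),
                                        seed = 9))
  tr <- sim$truth$individuals
  m <- merge(sim$sightings, tr, by = "id")
  expect_true(all(m$date >= m$birth_date))
  expect_true(all(is.na(m$death_date) | m$date <= m$death_date))
  # detected implies alive in that occasion
  expect_true(all(!sim$truth$detected | sim$truth$alive))
})

test_that("survival 1 and recruitment 0 conserve population size exactly", {
  sim <- simulate_population(sim_config(
    n_clans = 2, initial_clan_size = 30, recruitment_rate = 0,
    phi_annual = c(cub = 1, subadult = 1, adult = 1),
    study_end = as.Date("2013-06-01"), seed = 3))
  expect_true(all(colSums(sim$truth$alive) == 60))
})

test_that("marginal detection frequency matches the logit-normal mean", {
  cfg <- sim_config(n_clans = 1, initial_clan_size = 500, recruitment_rate = 0,
                    init_class_probs = c(0, 0, 1),
                    phi_annual = c(cub = 1, subadult = 1, adult = 1),
                    wet_range_contraction = 1, sigma_p = 0.8, seed = 11,
                    study_end = as.Date("2013-06-01"))
  sim <- simulate_population(cfg)
  obs <- mean(sim$truth$detected)
  expected <- logitnormal_mean(cfg$mu_p, cfg$sigma_p)
  # individuals share eps across occasions: mc error driven by n = 500
  expect_lt(abs(obs - expected), 3 * 0.2 / sqrt(500))
})

test_that("runaway recruitment trips the population cap", {
  expect_error(simulate_population(sim_config(
    n_clans = 2, initial_clan_size = 10, recruitment_rate = 400,
    pop_cap = 500, study_end = as.Date("2012-06-01"), seed = 1)),
    "pop_cap")
})

test_that("wet-season sightings are restricted to core clans", {
  cfg <- sim_config(seed = 2, study_end = as.Date("2013-06-01"))
  sim <- simulate_population(cfg)
  wet <- season_of(sim$sightings$date)$season == "wet"
  expect_true(all(sim$sightings$clan[wet] %in% 1:6))
  expect_gt(length(unique(sim$sightings$clan[!wet])), 6)
})

test_that("sighting scatter reproduces the configured spread", {
  cfg <- sim_config(n_clans = 1, clan_centers = matrix(0, 1, 2),
                    initial_clan_size = 200, recruitment_rate = 0,
                    init_class_probs = c(0, 0, 1),
                    phi_annual = c(cub = 1, subadult = 1, adult = 1),
                    wet_range_contraction = 1, range_sd_dry = 2,
                    range_sd_wet = 2, extra_sightings_rate = 0, seed = 6)
  s <- simulate_population(cfg)$sightings
  expect_gt(nrow(s), 5e3)
  expect_lt(abs(sd(s$x_km) - 2), 0.06)
  expect_lt(abs(sd(s$y_km) - 2), 0.06)
})

test_that("null contraction leaves wet and dry spreads indistinguishable", {
  cfg <- sim_config(n_clans = 1, clan_centers = matrix(0, 1, 2),
                    initial_clan_size = 150, recruitment_rate = 0,
                    init_class_probs = c(0, 0, 1),
                    phi_annual = c(cub = 1, subadult = 1, adult = 1),
                    wet_range_contraction = 1, range_sd_dry = 2,
                    range_sd_wet = 2, seed = 8)
  s <- simulate_population(cfg)$sightings
  wet <- season_of(s$date)$season == "wet"
  expect_lt(abs(sd(s$x_km[wet]) / sd(s$x_km[!wet]) - 1), 0.05)
})

test_that("written tables and truth dump round-trip through disk", {
  sim <- simulate_population(sim_config(n_clans = 2, initial_clan_size = 10,
                                        study_end = as.Date("2012-06-01"),
                                        seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_sim_data(sim, dir)
  ind <- read.csv(paths["individuals"])
  expect_identical(nrow(ind), nrow(sim$individuals))
  tr <- jsonlite::read_json(paths["truth"])
  expect_equal(tr$sigma_p, sim$truth$sigma_p)
})
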