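test_that("the bi-monthly study grid has the expected structure", {
  g <- build_occasion_grid(as.Date("2010-06-01"), as.Date("2019-12-01"), 2)
  expect_equal(nrow(g), 57)
  expect_true(all(g$end[-57] == g$start[-1]))          # contiguous
  expect_equal(g$start[1], as.Date("2010-06-01"))
  expect_equal(g$end[57], as.Date("2019-12-01"))
  expect_equal(nrow(build_occasion_grid(as.Date("2010-06-01"),
                                        as.Date("2010-08-01"), 2)), 1)
  expect_error(build_occasion_grid(as.Date("2010-06-01"),
                                   as.Date("2010-09-01"), 2),
               "remainder 1 month")
})

test_that("dates map to the correct season and season-year", {
  s <- season_of(as.Date(c("2014-07-01", "2014-03-10", "2013-12-15",
                           "2014-05-01", "2014-04-30", "2014-11-30")))
  expect_equal(s$season, c("dry", "wet", "wet", "dry", "wet", "dry"))
  expect_equal(s$season_year, c(2014, 2014, 2014, 2014, 2014, 2014))
})

test_that("age-class boundaries are assigned upward on anniversaries", {
  b <- as.Date("2012-01-01")
  expect_equal(assign_age_class(b, as.Date("2012-07-01")), "cub")
  expect_equal(assign_age_class(b, as.Date("2013-01-01")), "subadult") # 1st birthday
  expect_equal(assign_age_class(b, as.Date("2014-12-31")), "subadult")
  expect_equal(assign_age_class(b, as.Date("2015-01-01")), "adult")    # 3rd birthday
  expect_equal(assign_age_class(b, as.Date("2022-01-01")), "adult")
  expect_error(assign_age_class(b, as.Date("2011-12-31")), "precedes")
})

make_tables <- function() {
  individuals <- data.frame(
    id = c("A", "B", "C"), sex = c("F", "M", "U"),
    birth_date = as.Date(c("2005-01-01", "2012-01-01", "2005-06-01")),
    death_date = as.Date(c(NA, NA, "2015-01-01")),
    collared = c(TRUE, FALSE, FALSE))
  sightings <- data.frame(
    id = c("A", "A", "A", "B", "C"),
    date = as.Date(c("2010-11-15", "2010-11-20", "2011-07-01",
                     "2014-06-15", "2012-01-05")))
  list(individuals = individuals, sightings = sightings)
}

test_that("encounter histories collapse sightings and exclude known deaths", {
  d <- make_tables()
  g <- build_occasion_grid(as.Date("2010-06-01"), as.Date("2019-12-01"), 2)
  h <- build_cjs_history(d$sightings, d$individuals, g)
  # C has a known death date: excluded
  expect_equal(rownames(h$matrix), c("A", "B"))
  expect_equal(h$n_excluded_dead, 1L)
  # A: two sightings in occasion 3 collapse to one; another in occasion 7
  expect_equal(which(h$matrix["A", ] == 1), c(3L, 7L))
  expect_equal(unname(h$first["A"]), 3L)
  # B born 2012-01-01 sighted 2014-06-15: subadult at that occasion
  occ_b <- which(h$matrix["B", ] == 1)
  expect_equal(unname(h$age_class["B", occ_b]), "subadult")
  # age classes never regress
  for (i in seq_len(nrow(h$matrix))) {
    codes <- match(h$age_class[i, ], c("cub", "subadult", "adult"))
    expect_true(all(diff(codes) >= 0))
  }
})

test_that("out-of-grid sightings are dropped with a warning", {
  d <- make_tables()
  d$sightings$date[5] <- as.Date("2020-05-01")
  d$individuals$death_date[] <- NA
  g <- build_occasion_grid(as.Date("2010-06-01"), as.Date("2019-12-01"), 2)
  expect_warning(h <- build_cjs_history(d$sightings, d$individuals, g),
                 "1 sighting")
  expect_equal(h$n_dropped_sightings, 1L)
})

test_that("histories from the simulator reproduce the latent detection matrix", {
  cfg <- sim_config(n_clans = 3, initial_clan_size = 12, p_death_obs = 0,
                    study_end = as.Date("2014-06-01"), seed = 21)
  sim <- simulate_population(cfg)
  g <- build_occasion_grid(cfg$study_start, cfg$study_end, 2)
  h <- build_cjs_history(sim$sightings, sim$individuals, g)
  truth_det <- sim$truth$detected[match(rownames(h$matrix),
                                        sim$truth$individuals$id), ]
  expect_identical(unname(h$matrix == 1L), unname(truth_det))
})

test_that("seasonal windows have 5 wet and 7 dry monthly occasions", {
  s <- data.frame(
    id = c("A", "A", "B", "A", "B", "B"),
    date = as.Date(c("2015-05-03", "2015-05-20", "2015-11-10",
                     "2014-12-20", "2015-01-10", "2015-04-29")),
    x_km = 0, y_km = 0)
  w <- build_seasonal_histories(s)
  expect_setequal(names(w), c("dry-2015", "wet-2015"))
  expect_equal(ncol(w[["dry-2015"]]$matrix), 7)
  expect_equal(ncol(w[["wet-2015"]]$matrix), 5)
  # two May sightings of A collapse to a single monthly detection
  expect_equal(w[["dry-2015"]]$matrix["A", "2015-05"], 1L)
  expect_equal(sum(w[["dry-2015"]]$matrix["A", ]), 1L)
  # December sighting belongs to the following wet-season label
  expect_equal(w[["wet-2015"]]$matrix["A", "2014-12"], 1L)
  # all member coordinates retained
  expect_equal(nrow(w[["wet-2015"]]$points), 3)
})

test_that("seasonal matrix mass equals distinct individual-months", {
  sim <- simulate_population(sim_config(n_clans = 3, initial_clan_size = 10,
                                        study_end = as.Date("2013-06-01"),
                                        seed = 13))
  w <- build_seasonal_histories(sim$sightings)
  for (k in names(w)) {
    s <- sim$sightings
    se <- season_of(s$date)
    sel <- se$season == w[[k]]$season & se$season_year == w[[k]]$year
    pairs <- unique(paste(s$id[sel], format(s$date[sel], "%Y-%m")))
    expect_equal(sum(w[[k]]$matrix), length(pairs))
  }
})
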