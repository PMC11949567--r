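#' Configuration for the clan-structured population simulator
#'
#' Builds a validated configuration for [simulate_population()]. Defaults
#' emulate the long-term study the package is designed around: 11 clans
#' monitored June 2010 - November 2019, staggered entry of roughly 650-700
#' known individuals, bi-monthly detection with individual logit-normal
#' heterogeneity, a wet-season (December-April) contraction of the observed
#' area to a core set of clans, and a sex-assignment process in which rarely
#' seen animals stay unsexed.
#'
#' @param n_clans number of clans.
#' @param clan_centers n_clans x 2 matrix of planar clan-center coordinates
#'   (km); default a loose grid ~6 km apart.
#' @param initial_clan_size individuals per clan at study start.
#' @param study_start,study_end study window (half-open, first-of-month).
#' @param phi_annual annual apparent survival: either a named vector over age
#'   classes (applied to both sexes) or a 3 x 2 matrix (rows cub/subadult/
#'   adult, columns F/M). Defaults are the high survival rates typical of a
#'   low-competition system (cub 0.75, subadult 0.99, adult 0.86).
#' @param recruitment_rate expected cubs per clan per year (births pulsed
#'   uniformly through the year).
#' @param mu_p mean detection propensity per 2-month occasion on the
#'   log-odds scale (default `logit(0.575)`).
#' @param sigma_p sd of the individual detection deviation (log-odds scale).
#' @param sex_assignment_k rate constant of the sexing process: an
#'   individual detected `d` times is ever sexed with probability
#'   `1 - exp(-k d)`.
#' @param range_sd_wet,range_sd_dry sd (km) of sighting scatter around the
#'   clan center in each season.
#' @param wet_range_contraction scalar in (0, 1]: the fraction of clans
#'   (rounded, at least one) observable in the wet season. At 1 all clans
#'   are observed year-round.
#' @param init_class_probs length-3 probabilities of cub/subadult/adult for
#'   individuals present at study start.
#' @param first_detectable_age_months age at which a cub becomes detectable
#'   (den emergence); the average first-detection age the annualization rule
#'   is built on.
#' @param extra_sightings_rate Poisson rate of additional sightings per
#'   detected occasion beyond the first.
#' @param collars_per_clan adult females collared per clan.
#' @param p_death_obs probability a death in the population is actually
#'   observed (known death).
#' @param collar_effect_logit logit-scale shift applied to the 2-month
#'   survival of collared adults (0 = collaring is survival-neutral, the
#'   null the collaring check should not reject).
#' @param pop_cap hard cap on live population size; exceeding it aborts the
#'   simulation (runaway recruitment guard).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return object of class `hyena_sim_config`.
#' @export
sim_config <- function(n_clans = 11,
                       clan_centers = NULL,
                       initial_clan_size = 21,
                       study_start = as.Date("2010-06-01"),
                       study_end = as.Date("2019-12-01"),
                       phi_annual = c(cub = 0.75, subadult = 0.99, adult = 0.86),
                       recruitment_rate = 5.0,
                       mu_p = log(0.575 / 0.425),
                       sigma_p = 0.8,
                       sex_assignment_k = 0.11,
                       range_sd_wet = 2,
                       range_sd_dry = 3,
                       wet_range_contraction = 6 / 11,
                       init_class_probs = c(cub = 0.2, subadult = 0.25, adult = 0.55),
                       first_detectable_age_months = 2.41,
                       extra_sightings_rate = 1.5,
                       collars_per_clan = 2,
                       p_death_obs = 0.05,
                       collar_effect_logit = 0,
                       pop_cap = 10000,
                       seed = 1) {
  if (is.vector(phi_annual)) {
    stopifnot(all(AGE_LEVELS %in% names(phi_annual)))
    phi_annual <- cbind(F = phi_annual[AGE_LEVELS], M = phi_annual[AGE_LEVELS])
  }
  phi_annual <- as.matrix(phi_annual)
  rownames(phi_annual) <- AGE_LEVELS; colnames(phi_annual) <- c("F", "M")
  if (is.null(clan_centers)) {
    k <- ceiling(sqrt(n_clans))
    g <- expand.grid(x = seq_len(k), y = seq_len(k))[seq_len(n_clans), ]
    clan_centers <- cbind(x = g$x * 6, y = g$y * 6)
  }
  clan_centers <- as.matrix(clan_centers)
  cfg <- list(n_clans = as.integer(n_clans), clan_centers = clan_centers,
              initial_clan_size = as.integer(initial_clan_size),
              study_start = as.Date(study_start), study_end = as.Date(study_end),
              phi_annual = phi_annual, recruitment_rate = recruitment_rate,
              mu_p = mu_p, sigma_p = sigma_p,
              sex_assignment_k = sex_assignment_k,
              range_sd_wet = range_sd_wet, range_sd_dry = range_sd_dry,
              wet_range_contraction = wet_range_contraction,
              init_class_probs = init_class_probs / sum(init_class_probs),
              first_detectable_age_months = first_detectable_age_months,
              extra_sightings_rate = extra_sightings_rate,
              collars_per_clan = as.integer(collars_per_clan),
              p_death_obs = p_death_obs,
              collar_effect_logit = collar_effect_logit, pop_cap = pop_cap,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "hyena_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_clans >= 1, nrow(cfg$clan_centers) == cfg$n_clans,
            cfg$study_end > cfg$study_start,
            all(cfg$phi_annual > 0), all(cfg$phi_annual <= 1),
            cfg$sigma_p >= 0, cfg$recruitment_rate >= 0,
            cfg$wet_range_contraction > 0, cfg$wet_range_contraction <= 1,
            cfg$range_sd_wet > 0, cfg$range_sd_dry > 0,
            cfg$p_death_obs >= 0, cfg$p_death_obs <= 1)
  invisible(cfg)
}

core_clans <- function(cfg) seq_len(max(1L, round(cfg$wet_range_contraction * cfg$n_clans)))

# an occasion counts as wet when it starts in Dec-Apr
occasion_is_wet <- function(start) {
  m <- lubridate::month(start)
  m <= 4 | m == 12
}

#' Simulate a clan-structured hyena population and its detection record
#'
#' Agent-based simulation on the bi-monthly occasion grid. Each individual
#' carries a Gaussian detection deviation on the log-odds scale; its
#' per-occasion detection probability is `invlogit(mu_p + eps_i)`. Survival
#' per 2-month step is the class- and sex-specific annual rate to the power
#' 1/6, using the age class at the occasion midpoint. Cubs become detectable
#' at `first_detectable_age_months`. In wet-season occasions only the core
#' clans are observable. An individual's sex is recorded as `"U"` unless a
#' sexing draw (probability increasing with its number of detections)
#' succeeds.
#'
#' @param config a [sim_config()].
#' @return list with `individuals` (known individuals only: `id`, `clan`,
#'   `sex`, `birth_date`, `death_date` for known deaths, `collared`),
#'   `sightings` (`id`, `date`, `x_km`, `y_km`, `clan`) and `truth`
#'   (class `hyena_truth`: all individuals with true sex/death/eps, latent
#'   alive and detected matrices, the occasion grid and the generating
#'   parameters).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  grid <- build_occasion_grid(config$study_start, config$study_end, 2)
  T <- nrow(grid)
  wet_occ <- occasion_is_wet(grid$start)
  core <- core_clans(config)
  min_age_days <- config$first_detectable_age_months * 365.25 / 12

  n0 <- config$n_clans * config$initial_clan_size
  cls0 <- sample(AGE_LEVELS, n0, replace = TRUE, prob = config$init_class_probs)
  age0 <- ifelse(cls0 == "cub", runif(n0, 0.25, 1),
          ifelse(cls0 == "subadult", runif(n0, 1, 3), runif(n0, 3, 12)))
  clan <- rep(seq_len(config$n_clans), each = config$initial_clan_size)
  birth <- config$study_start - round(age0 * 365.25)
  sex_true <- sample(c("F", "M"), n0, replace = TRUE)
  eps <- rnorm(n0, 0, config$sigma_p)
  death <- rep(as.Date(NA), n0)
  alive_now <- rep(TRUE, n0)

  # collaring: adult females at study start (the monitoring backbone)
  collared <- rep(FALSE, n0)
  for (cl in seq_len(config$n_clans)) {
    cand <- which(clan == cl & sex_true == "F" & cls0 == "adult")
    if (length(cand) > 0)
      collared[cand[seq_len(min(config$collars_per_clan, length(cand)))]] <- TRUE
  }

  alive_mat <- list(); det_mat <- list()
  for (occ in seq_len(T)) {
    n <- length(birth)
    alive_rec <- alive_now
    detectable <- alive_now &
      (as.numeric(grid$start[occ] - birth) >= min_age_days) &
      (!wet_occ[occ] | clan %in% core)
    p_i <- invlogit(config$mu_p + eps)
    det <- detectable & (rbinom(n, 1, p_i) == 1)
    alive_mat[[occ]] <- alive_rec; det_mat[[occ]] <- det

    if (occ < T) {
      # survival over (occ, occ+1) by age class at the occasion midpoint
      cls <- assign_age_class(birth, pmax(grid$midpoint[occ], birth))
      phi_step <- config$phi_annual[cbind(match(cls, AGE_LEVELS),
                                          match(sex_true, c("F", "M")))]^(1 / 6)
      if (config$collar_effect_logit != 0) {
        hit <- collared & cls == "adult"
        phi_step[hit] <- invlogit(logit(phi_step[hit]) +
                                    config$collar_effect_logit)
      }
      die <- alive_now & (runif(n) > phi_step)
      death[die] <- grid$end[occ]
      alive_now[die] <- FALSE
      # recruitment, pulsed uniformly in time
      nb <- rpois(config$n_clans, config$recruitment_rate / 6)
      if (sum(nb) > 0) {
        nbtot <- sum(nb)
        bdates <- grid$start[occ] +
          floor(runif(nbtot) * as.numeric(grid$end[occ] - grid$start[occ]))
        clan <- c(clan, rep(seq_len(config$n_clans), nb))
        birth <- c(birth, bdates)
        sex_true <- c(sex_true, sample(c("F", "M"), nbtot, replace = TRUE))
        eps <- c(eps, rnorm(nbtot, 0, config$sigma_p))
        death <- c(death, rep(as.Date(NA), nbtot))
        alive_now <- c(alive_now, rep(TRUE, nbtot))
        collared <- c(collared, rep(FALSE, nbtot))
      }
      if (sum(alive_now) > config$pop_cap)
        stop("population exceeded `pop_cap`: runaway recruitment; lower `recruitment_rate` or raise the cap")
    }
  }
  n <- length(birth)
  pad <- function(v) c(v, rep(FALSE, n - length(v)))
  alive <- vapply(alive_mat, pad, logical(n))
  detected <- vapply(det_mat, pad, logical(n))
  ids <- sprintf("H%04d", seq_len(n))

  # sighting skeleton: >=1 dated sighting per detected (individual, occasion)
  di <- which(detected, arr.ind = TRUE)
  n_per <- 1L + rpois(nrow(di), config$extra_sightings_rate)
  idx <- rep(di[, 1], n_per); occs <- rep(di[, 2], n_per)
  span <- as.numeric(grid$end[occs] - grid$start[occs])
  sightings <- data.frame(
    id = ids[idx],
    date = grid$start[occs] + floor(runif(length(idx)) * span),
    clan = clan[idx])
  sightings <- sightings[order(sightings$date, sightings$id), ]
  rownames(sightings) <- NULL

  # sexing success increases with how often the animal was seen
  n_det <- rowSums(detected)
  p_sexed <- ifelse(n_det == 0, 0, 1 - exp(-config$sex_assignment_k * n_det))
  sexed <- rbinom(n, 1, p_sexed) == 1
  sex_obs <- ifelse(sexed, sex_true, "U")

  known <- n_det > 0
  death_known <- !is.na(death) & (runif(n) < config$p_death_obs)
  individuals <- data.frame(
    id = ids[known], clan = clan[known], sex = sex_obs[known],
    birth_date = birth[known],
    death_date = as.Date(ifelse(death_known[known], death[known], NA),
                         origin = "1970-01-01"),
    collared = collared[known])
  rownames(individuals) <- NULL

  truth <- structure(list(
    individuals = data.frame(id = ids, clan = clan, sex_true = sex_true,
                             birth_date = birth, death_date = death,
                             eps = eps),
    alive = alive, detected = detected, grid = grid,
    phi_annual = config$phi_annual, mu_p = config$mu_p,
    sigma_p = config$sigma_p, core_clans = core,
    sightings_skeleton = sightings), class = "hyena_truth")

  sightings <- simulate_sighting_locations(truth, config)
  list(individuals = individuals, sightings = sightings, truth = truth)
}

#' Attach planar coordinates to simulated sightings
#'
#' Draws each sighting's location from a bivariate normal around its clan
#' center, with season-specific spread (`range_sd_wet` in December-April,
#' `range_sd_dry` otherwise). Wet-season sightings only exist for core
#' clans, which [simulate_population()] enforces upstream in the detection
#' process.
#'
#' @param truth a `hyena_truth` object from [simulate_population()].
#' @param config the matching [sim_config()].
#' @return the sightings data frame with `x_km`, `y_km` columns added.
#' @export
simulate_sighting_locations <- function(truth, config) {
  stopifnot(inherits(truth, "hyena_truth"))
  set.seed(config$seed + 1L)
  s <- truth$sightings_skeleton
  wet <- season_of(s$date)$season == "wet"
  sdv <- ifelse(wet, config$range_sd_wet, config$range_sd_dry)
  ctr <- config$clan_centers[s$clan, , drop = FALSE]
  s$x_km <- ctr[, 1] + rnorm(nrow(s), 0, sdv)
  s$y_km <- ctr[, 2] + rnorm(nrow(s), 0, sdv)
  s
}

#' @export
print.hyena_sim_config <- function(x, ...) {
  cat(sprintf("Simulator config: %d clans x %d initial, %s to %s, seed %d\n",
              x$n_clans, x$initial_clan_size, x$study_start, x$study_end, x$seed))
  cat("  annual survival (F):",
      paste(sprintf("%s %.2f", AGE_LEVELS, x$phi_annual[, "F"]), collapse = ", "), "\n")
  cat(sprintf("  detection: mu_p %.3f (p %.3f), sigma_p %.2f\n",
              x$mu_p, invlogit(x$mu_p), x$sigma_p))
  invisible(x)
}

#' @export
print.hyena_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d individuals, %d occasions, %d ever detected\n",
              nrow(x$individuals), ncol(x$alive), sum(rowSums(x$detected) > 0)))
  invisible(x)
}

#' Write simulated data to plain-text files
#'
#' Writes the individuals and sightings tables as CSV and the ground-truth
#' generating parameters (class-specific survival, detection mean and sd,
#' per-individual deviations) as JSON for parameter-recovery work.
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pi <- file.path(dir, "individuals.csv")
  ps <- file.path(dir, "sightings.csv")
  pt <- file.path(dir, "truth.json")
  write.csv(sim$individuals, pi, row.names = FALSE)
  write.csv(sim$sightings, ps, row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    phi_annual = as.data.frame(tr$phi_annual), mu_p = tr$mu_p,
    sigma_p = tr$sigma_p,
    eps = setNames(as.list(tr$individuals$eps), tr$individuals$id)),
    pt, auto_unbox = TRUE, digits = NA)
  invisible(c(individuals = pi, sightings = ps, truth = pt))
}
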