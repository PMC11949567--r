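#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: either a simulator
#' configuration or paths to individuals/sightings CSV files, the occasion
#' grid, MCMC settings, the augmentation factor, utilization-distribution
#' settings, and output control.
#'
#' @param sim a [sim_config()], or `NULL` when reading data from files.
#' @param individuals,sightings CSV paths (schemas as written by
#'   [write_sim_data()]); ignored when `sim` is given.
#' @param grid_start,grid_end occasion-grid bounds; default to the
#'   simulator's study window when `sim` is given.
#' @param mcmc an [mcmc_config()].
#' @param factor augmentation factor for closed models.
#' @param bandwidth,isopleth_level,grid_n KUD settings (see [fit_kud()],
#'   [isopleth_area()]).
#' @param model closed model(s) to fit: `"both"` (DIC comparison), `"Mh"`
#'   or `"M0"`.
#' @param seasons optional character filter of windows (e.g. `"dry-2015"`).
#' @param impute_wet_years wet-season years whose area is imputed from the
#'   mean 2013-2019 wet area (skipped when those years are absent).
#' @param check_collaring,sex_p run the collaring-survival check and the
#'   sex-specific detection variant (extra fits).
#' @param outdir output directory for tables, logs and polygons, or `NULL`.
#' @param seed run seed, recorded in the provenance block; overrides the
#'   seed in `mcmc`.
#' @return object of class `hyena_run_config`.
#' @export
run_config <- function(sim = NULL, individuals = NULL, sightings = NULL,
                       grid_start = as.Date("2010-06-01"),
                       grid_end = as.Date("2019-12-01"),
                       mcmc = mcmc_config(), factor = 3,
                       bandwidth = "reference", isopleth_level = 0.90,
                       grid_n = 400, model = c("both", "Mh", "M0"),
                       seasons = NULL, impute_wet_years = c(2011, 2012),
                       check_collaring = FALSE, sex_p = FALSE,
                       outdir = NULL, seed = 1) {
  model <- match.arg(model)
  if (is.null(sim)) {
    if (is.null(individuals) || is.null(sightings))
      stop("provide either `sim` or both `individuals` and `sightings` paths")
    for (p in c(individuals, sightings))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    stopifnot(inherits(sim, "hyena_sim_config"))
    grid_start <- sim$study_start; grid_end <- sim$study_end
  }
  mcmc$seed <- as.integer(seed)
  structure(list(sim = sim, individuals = individuals, sightings = sightings,
                 grid_start = grid_start, grid_end = grid_end, mcmc = mcmc,
                 factor = factor, bandwidth = bandwidth,
                 isopleth_level = isopleth_level, grid_n = grid_n,
                 model = model, seasons = seasons,
                 impute_wet_years = impute_wet_years,
                 check_collaring = check_collaring, sex_p = sex_p,
                 outdir = outdir, seed = as.integer(seed)),
            class = "hyena_run_config")
}

read_individuals <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$birth_date <- as.Date(d$birth_date)
  if ("death_date" %in% names(d)) d$death_date <- as.Date(d$death_date)
  d
}

read_sightings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' Run the full demographic pipeline
#'
#' Executes, in order: encounter-history construction (bi-monthly CJS grid
#' and seasonal monthly windows), the CJS survival fit with its cub-
#' mortality verification (plus optional collaring and sex-specific
#' detection checks), per-season closed abundance (with DIC model choice
#' when `model = "both"`), and utilization-distribution density mapping
#' with wet-season area imputation where configured. Every filtering step
#' is logged with counts. A failure in any stage aborts with the stage name
#' and the partial results gathered so far attached to the error condition.
#'
#' @param config a [run_config()].
#' @return object of class `hyena_run_report`; see the package vignette.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hyena_run_config"))
  log <- list(); partial <- list()
  note <- function(stage, ...) {
    entry <- list(stage = stage, ...)
    log[[length(log) + 1]] <<- entry
    message(sprintf("[%s] %s", stage,
                    paste(names(entry)[-1], unlist(entry[-1]),
                          sep = "=", collapse = " ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, partial = partial, log = log))))
  }

  dat <- stage("load", {
    if (!is.null(config$sim)) {
      sim <- simulate_population(config$sim)
      note("load", source = "simulator", individuals = nrow(sim$individuals),
           sightings = nrow(sim$sightings))
      sim
    } else {
      ind <- read_individuals(config$individuals)
      sgt <- read_sightings(config$sightings)
      note("load", source = config$sightings, individuals = nrow(ind),
           sightings = nrow(sgt))
      list(individuals = ind, sightings = sgt, truth = NULL)
    }
  })
  partial$data <- dat

  grid <- stage("occasion_grid",
                build_occasion_grid(config$grid_start, config$grid_end, 2))
  history <- stage("encounters", {
    h <- build_cjs_history(dat$sightings, dat$individuals, grid)
    note("encounters", individuals_in = nrow(dat$individuals),
         excluded_known_dead = h$n_excluded_dead,
         analyzed = nrow(h$matrix), occasions = ncol(h$matrix))
    h
  })
  partial$history <- history

  cjs <- stage("cjs_survival", fit_cjs(history, config$mcmc))
  note("cjs_survival", individuals = cjs$n_individuals,
       converged = cjs$converged)
  partial$cjs <- cjs
  cubmort <- stage("cub_mortality", approximate_cub_mortality(history))
  note("cub_mortality", eligible = cubmort$n_eligible,
       never_after = cubmort$n_never_after,
       mortality = round(cubmort$mortality, 4))
  collaring <- NULL
  if (config$check_collaring)
    collaring <- stage("collaring_effect", collaring_effect(history, config$mcmc))
  sexp <- NULL
  if (config$sex_p)
    sexp <- stage("sex_specific_p", fit_sex_specific_p(history, config$mcmc))

  windows <- stage("seasonal_histories", {
    w <- build_seasonal_histories(dat$sightings)
    if (!is.null(config$seasons)) w <- w[intersect(names(w), config$seasons)]
    note("seasonal_histories", windows = length(w))
    w
  })
  if (length(windows) == 0) stop("no seasonal windows to analyze")

  fits <- list(); dic_rows <- list(); areas <- list(); rings <- list()
  for (k in names(windows)) {
    win <- windows[[k]]
    res <- stage(paste0("closed_", k), {
      if (config$model == "both") {
        f0 <- fit_closed(win, "M0", config$mcmc, config$factor)
        fh <- fit_closed(win, "Mh", config$mcmc, config$factor)
        dic_rows[[k]] <- data.frame(
          window = k, season = win$season, year = win$year,
          DIC_M0 = dic(f0), DIC_Mh = dic(fh),
          delta_DIC = dic(f0) - dic(fh),
          preferred = if (dic(fh) < dic(f0)) "Mh" else "M0")
        if (dic(fh) <= dic(f0)) fh else f0
      } else fit_closed(win, config$model, config$mcmc, config$factor)
    })
    note(paste0("closed_", k), model = res$model, n_obs = res$n_obs,
         N_median = unname(res$summary["median"]))
    fits[[k]] <- res
    if (nrow(win$points) >= 5 &&
        all(c("x_km", "y_km") %in% names(win$points))) {
      kud <- stage(paste0("kud_", k),
                   fit_kud(win$points, config$bandwidth, config$grid_n))
      areas[[k]] <- isopleth_area(kud, config$isopleth_level)
      rings[[k]] <- isopleth_rings(kud, config$isopleth_level)
    }
  }

  # wet-season area imputation for configured years
  wet_areas <- unlist(areas[grep("^wet-", names(areas))])
  names(wet_areas) <- sub("^wet-", "", names(wet_areas))
  dens <- list()
  for (k in names(fits)) {
    win <- windows[[k]]
    src <- "estimated"; a <- areas[[k]]
    if (win$season == "wet" && win$year %in% config$impute_wet_years &&
        all(as.character(2013:2019) %in% names(wet_areas))) {
      a <- as.numeric(impute_wet_area(wet_areas))
      src <- "imputed_mean_wet_2013_2019"
    }
    if (is.null(a)) { note(paste0("density_", k), skipped = "no area"); next }
    dens[[k]] <- density_estimate(fits[[k]], a, win$season, win$year, src)
  }
  density_table <- do.call(rbind, lapply(names(dens), function(k)
    data.frame(window = k, season = dens[[k]]$season, year = dens[[k]]$year,
               area_source = dens[[k]]$area_source,
               t(dens[[k]]$summary))))

  report <- structure(list(
    cjs = cjs,
    survival = cjs$survival, detection = cjs$detection,
    cjs_diagnostics = cjs$diagnostics, converged = cjs$converged,
    cub_mortality = cubmort, collaring = collaring, sex_p = sexp,
    dic_table = if (length(dic_rows)) do.call(rbind, dic_rows),
    density_table = density_table,
    closed_fits = fits, density = dens, areas = areas, rings = rings,
    log = log,
    provenance = list(package = "hyenademog",
                      version = as.character(utils::packageVersion("hyenademog")),
                      seed = config$seed)),
    class = "hyena_run_report")
  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @export
print.hyena_run_report <- function(x, ...) {
  cat("Hyena demography run report\n===========================\n")
  cat(sprintf("Seed %d, package version %s\n\n", x$provenance$seed,
              x$provenance$version))
  cat("Annual survival (mean [95% CRI]):\n")
  s <- x$survival
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %s  %.2f [%.2f, %.2f]\n", s$age_class[i], s$sex[i],
                s$phi_annual_mean[i], s$phi_annual_lower[i],
                s$phi_annual_upper[i]))
  cat(sprintf("\nCub mortality check: %d/%d never resighted after age 1 -> %.1f%%\n",
              x$cub_mortality$n_never_after, x$cub_mortality$n_eligible,
              100 * x$cub_mortality$mortality))
  if (!is.null(x$density_table)) {
    cat("\nSeasonal density (median [95% CRI], /km^2):\n")
    d <- x$density_table
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-9s N=%3.0f A=%7.1f km^2  D=%.2f [%.2f, %.2f]%s\n",
                  d$window[i], d$N_median[i], d$A_km2[i], d$D_median[i],
                  d$D_lower[i], d$D_upper[i],
                  if (d$area_source[i] != "estimated") " (imputed area)" else ""))
  }
  invisible(x)
}

#' Write a run report's tables and polygons to disk
#'
#' Emits the survival, detection, density and DIC tables as CSV at full
#' precision, the survival-model posterior draws as a columnar CSV, the
#' machine event log as JSON lines, isopleth polygons as GeoJSON, and the
#' provenance block as JSON.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$survival, file.path(dir, "survival.csv"), row.names = FALSE)
  write.csv(report$detection, file.path(dir, "detection.csv"), row.names = FALSE)
  if (!is.null(report$density_table))
    write.csv(report$density_table, file.path(dir, "density.csv"),
              row.names = FALSE)
  if (!is.null(report$dic_table))
    write.csv(report$dic_table, file.path(dir, "dic.csv"), row.names = FALSE)
  draws <- do.call(rbind, lapply(seq_along(report$cjs$draws), function(ch)
    data.frame(chain = ch, iteration = seq_len(nrow(report$cjs$draws[[ch]])),
               report$cjs$draws[[ch]], check.names = FALSE)))
  write.csv(draws, file.path(dir, "cjs_draws.csv"), row.names = FALSE)
  writeLines(vapply(report$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(dir, "events.jsonl"))
  for (k in names(report$rings))
    write_isopleth_geojson(report$rings[[k]],
                           file.path(dir, paste0("isopleth_", k, ".geojson")))
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Write isopleth rings as GeoJSON
#'
#' @param rings list of ring data frames from [isopleth_rings()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_isopleth_geojson <- function(rings, path) {
  feats <- lapply(rings, function(r) {
    coords <- cbind(r$x, r$y)
    if (nrow(coords) > 0 && any(coords[1, ] != coords[nrow(coords), ]))
      coords <- rbind(coords, coords[1, ])
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(coords)),
                                                   function(i) coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot seasonal density estimates over time
#'
#' @param x a `hyena_run_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hyena_run_report <- function(x, ...) {
  d <- x$density_table
  if (is.null(d) || nrow(d) == 0) stop("report contains no density table")
  col <- ifelse(d$season == "wet", "steelblue", "darkorange")
  graphics::plot(d$year, d$D_median, pch = 19, col = col,
                 ylim = range(c(d$D_lower, d$D_upper)),
                 xlab = "Year", ylab = expression(hat(D) ~ (km^-2)), ...)
  graphics::arrows(d$year, d$D_lower, d$year, d$D_upper, angle = 90,
                   code = 3, length = 0.03, col = col)
  graphics::legend("topright", legend = c("dry", "wet"), pch = 19,
                   col = c("darkorange", "steelblue"), bty = "n")
  invisible(x)
}
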