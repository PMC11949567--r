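#' Build a grid of contiguous capture occasions
#'
#' Divides a study window into contiguous, non-overlapping, half-open
#' calendar bins of fixed width in months. The default demographic grid is
#' bi-monthly: June 2010 to December 2010-exclusive-of-2019 spans 114 months
#' and yields 57 two-month occasions.
#'
#' @param start,end `Date` (or coercible) study bounds; the grid covers
#'   `[start, end)`. Both must fall on the same day of month.
#' @param width_months bin width in whole months (default 2).
#' @return An object of class `occasion_grid`: a data frame with columns
#'   `occasion`, `start`, `end`, `midpoint`, and attributes `width_months`.
#' @examples
#' g <- build_occasion_grid(as.Date("2010-06-01"), as.Date("2019-12-01"))
#' nrow(g) # 57
#' @export
build_occasion_grid <- function(start, end, width_months = 2) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("`end` must be after `start`")
  if (lubridate::mday(start) != lubridate::mday(end))
    stop("`start` and `end` must fall on the same day of the month")
  span <- 12L * (lubridate::year(end) - lubridate::year(start)) +
    (lubridate::month(end) - lubridate::month(start))
  rem <- span %% width_months
  if (rem != 0)
    stop(sprintf(
      "study window of %d months is not divisible by %d-month occasions (remainder %d month%s)",
      span, width_months, rem, if (rem == 1) "" else "s"))
  n <- span %/% width_months
  starts <- start %m+% months(width_months * (seq_len(n) - 1L))
  ends <- start %m+% months(width_months * seq_len(n))
  mids <- starts + as.numeric(ends - starts) / 2
  g <- data.frame(occasion = seq_len(n), start = starts, end = ends,
                  midpoint = mids)
  attr(g, "width_months") <- width_months
  class(g) <- c("occasion_grid", class(g))
  g
}

#' @importFrom lubridate %m+% years
NULL

#' Season and season-year of a calendar date
#'
#' The study system has a wet season (December-April) and a dry season
#' (May-November). December is attached to the following year's wet season,
#' so wet-2014 runs December 2013 through April 2014.
#'
#' @param d `Date` vector (or coercible).
#' @return data frame with columns `season` (`"wet"`/`"dry"`) and
#'   `season_year`.
#' @examples
#' season_of(as.Date(c("2014-07-01", "2014-03-10", "2013-12-15")))
#' @export
season_of <- function(d) {
  d <- as.Date(d)
  m <- lubridate::month(d)
  y <- lubridate::year(d)
  wet <- m <= 4 | m == 12
  data.frame(season = ifelse(wet, "wet", "dry"),
             season_year = ifelse(m == 12, y + 1L, y))
}

#' Assign a hyena to an age class
#'
#' Age classes are cub (0-1 years), subadult (1-3 years) and adult
#' (3+ years). Boundaries are assigned upward: an individual on its first
#' (third) birthday is a subadult (adult). Anniversaries are computed on the
#' calendar, not by day counts.
#'
#' @param birth_date,at `Date` vectors (recycled).
#' @return character vector in `c("cub", "subadult", "adult")`.
#' @export
assign_age_class <- function(birth_date, at) {
  birth_date <- as.Date(birth_date); at <- as.Date(at)
  if (any(at < birth_date, na.rm = TRUE))
    stop("`at` precedes `birth_date` for some individuals")
  cls <- rep("cub", max(length(birth_date), length(at)))
  cls[at >= birth_date %m+% years(1)] <- "subadult"
  cls[at >= birth_date %m+% years(3)] <- "adult"
  cls
}

AGE_LEVELS <- c("cub", "subadult", "adult")
SEX_LEVELS <- c("F", "M", "U")

occasion_of <- function(d, grid) {
  # half-open [start, end); NA outside the grid span
  idx <- findInterval(as.numeric(as.Date(d)), as.numeric(grid$start))
  idx[idx == 0] <- NA
  out_of_range <- !is.na(idx) & as.Date(d) >= grid$end[pmin(idx, nrow(grid))]
  idx[out_of_range] <- NA
  idx
}

#' Build the bi-monthly Cormack-Jolly-Seber encounter history
#'
#' Collapses sightings into a binary individuals-by-occasions matrix.
#' Individuals with a known death date are excluded (their inclusion would
#' require joint recovery/recapture modelling); sightings outside the grid
#' span are dropped with a warning. The age class of each individual at each
#' occasion is evaluated at the occasion midpoint.
#'
#' @param sightings data frame with columns `id`, `date`.
#' @param individuals data frame with columns `id`, `sex`, `birth_date`,
#'   `death_date` (NA when not known dead) and optionally `collared`.
#' @param grid an [build_occasion_grid()] object.
#' @return An object of class `encounter_history`: list with `matrix`
#'   (binary, rownames = id), `first` (first-detection occasion),
#'   `age_class` (n x T character matrix), `sex`, `collared`, `grid`, and
#'   exclusion counts `n_excluded_dead`, `n_dropped_sightings`.
#' @export
build_cjs_history <- function(sightings, individuals, grid) {
  stopifnot(all(c("id", "date") %in% names(sightings)),
            all(c("id", "sex", "birth_date") %in% names(individuals)))
  if (!all(sightings$id %in% individuals$id))
    stop("sightings reference individuals absent from `individuals`")
  dead <- if ("death_date" %in% names(individuals))
    !is.na(individuals$death_date) else rep(FALSE, nrow(individuals))
  n_dead <- sum(dead)
  keep <- individuals[!dead, , drop = FALSE]

  occ_all <- occasion_of(sightings$date, grid)
  n_drop <- sum(is.na(occ_all))
  if (n_drop > 0)
    warning(sprintf("%d sighting(s) outside the occasion grid were dropped", n_drop))
  sel <- !is.na(occ_all) & sightings$id %in% keep$id
  s <- sightings[sel, , drop = FALSE]
  occ_s <- occ_all[sel]

  ids <- sort(unique(s$id))
  if (length(ids) == 0) stop("no usable sightings")
  T <- nrow(grid)
  mat <- matrix(0L, length(ids), T, dimnames = list(ids, NULL))
  mat[cbind(match(s$id, ids), occ_s)] <- 1L

  info <- keep[match(ids, keep$id), , drop = FALSE]
  first <- apply(mat, 1, function(r) which(r == 1L)[1])
  age <- matrix(NA_character_, length(ids), T, dimnames = list(ids, NULL))
  for (j in seq_len(T)) # pre-birth occasions clamp to "cub"; they precede
    # first detection and never enter the conditional likelihood
    age[, j] <- assign_age_class(info$birth_date,
                                 pmax(grid$midpoint[j], info$birth_date))
  structure(list(
    matrix = mat, first = first,
    age_class = age,
    sex = factor(as.character(info$sex), levels = SEX_LEVELS),
    collared = if ("collared" %in% names(info)) as.logical(info$collared)
               else rep(FALSE, length(ids)),
    birth_date = as.Date(info$birth_date),
    grid = grid,
    n_excluded_dead = n_dead, n_dropped_sightings = n_drop),
    class = "encounter_history")
}

#' @export
print.encounter_history <- function(x, ...) {
  cat(sprintf("Encounter history: %d individuals x %d occasions\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  excluded known deaths: %d; dropped out-of-grid sightings: %d\n",
              x$n_excluded_dead, x$n_dropped_sightings))
  print(table(sex = x$sex))
  invisible(x)
}

#' Build seasonal monthly capture histories for closed-population models
#'
#' Splits sightings into wet (December-April, 5 monthly occasions) and dry
#' (May-November, 7 monthly occasions) windows per year. Each window keeps
#' only individuals detected at least once in it (as closed models require)
#' and retains every member sighting's coordinates for the utilization-
#' distribution area estimate.
#'
#' @param sightings data frame with `id`, `date` and optionally `x_km`,
#'   `y_km`.
#' @return named list of `season_window` objects (`"dry-2015"` etc.), each
#'   with `season`, `year`, `matrix` (individuals x months), `months`
#'   (first-of-month Dates) and `points` (coordinates of member sightings).
#' @export
build_seasonal_histories <- function(sightings) {
  stopifnot(all(c("id", "date") %in% names(sightings)))
  d <- as.Date(sightings$date)
  se <- season_of(d)
  key <- paste(se$season, se$season_year, sep = "-")
  out <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    season <- sub("-.*", "", k)
    year <- as.integer(sub(".*-", "", k))
    month_starts <- if (season == "wet")
      as.Date(sprintf("%d-12-01", year - 1L)) %m+% months(0:4)
    else
      as.Date(sprintf("%d-05-01", year)) %m+% months(0:6)
    ids <- sort(unique(sightings$id[sel]))
    m <- matrix(0L, length(ids), length(month_starts),
                dimnames = list(ids, format(month_starts, "%Y-%m")))
    mi <- findInterval(as.numeric(d[sel]),
                       as.numeric(month_starts))
    m[cbind(match(sightings$id[sel], ids), mi)] <- 1L
    pts <- sightings[sel, intersect(c("id", "date", "x_km", "y_km"),
                                    names(sightings)), drop = FALSE]
    out[[k]] <- structure(
      list(season = season, year = year, matrix = m,
           months = month_starts, points = pts),
      class = "season_window")
  }
  if (length(out) == 0) message("no non-empty seasonal windows")
  out
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("%s season %d: %d individuals x %d monthly occasions, %d sightings\n",
              x$season, x$year, nrow(x$matrix), ncol(x$matrix), nrow(x$points)))
  invisible(x)
}
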