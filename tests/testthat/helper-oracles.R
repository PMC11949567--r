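# Independent oracles and small fixture builders, kept free of the code
# paths they check.

# CJS likelihood by exhaustive enumeration over the death interval:
# the individual is alive through occasion d (d = first..T) and, if d < T,
# dies in the interval (d, d+1).
cjs_loglik_enum <- function(y, first, phi, p) {
  T <- length(y)
  if (length(phi) == 1) phi <- rep(phi, T - 1)
  tot <- 0
  for (d in first:T) {
    if (d < T && any(y[(d + 1):T] == 1)) next # detection after death: impossible
    pr <- 1
    if (d > first) pr <- pr * prod(phi[first:(d - 1)])
    if (d < T) pr <- pr * (1 - phi[d])
    if (d > first) {
      occ <- (first + 1):d
      pr <- pr * prod(ifelse(y[occ] == 1, p, 1 - p))
    }
    tot <- tot + pr
  }
  log(tot)
}

# dense trapezoid integration of the logit-normal detection mixture,
# independent of the Gauss-Hermite path
logitnormal_mean <- function(mu, sigma, n = 20000) {
  if (sigma == 0) return(plogis(mu))
  x <- seq(mu - 8 * sigma, mu + 8 * sigma, length.out = n)
  f <- plogis(x) * dnorm(x, mu, sigma)
  sum((f[-1] + f[-n]) / 2 * diff(x))
}

# minimal hand-built encounter history (single sex/age path)
tiny_history <- function(mat, first = NULL, sex = "F", age = "adult",
                         birth = as.Date("2000-01-01")) {
  n <- nrow(mat); T <- ncol(mat)
  end <- seq(as.Date("2010-06-01"), by = "2 months", length.out = T + 1)[T + 1]
  grid <- build_occasion_grid(as.Date("2010-06-01"), end, 2)
  structure(list(
    matrix = mat,
    first = if (is.null(first)) apply(mat, 1, function(r) which(r == 1)[1]) else first,
    age_class = matrix(age, n, T),
    sex = factor(rep_len(sex, n), levels = c("F", "M", "U")),
    collared = rep(FALSE, n),
    birth_date = rep(birth, n),
    grid = grid, n_excluded_dead = 0L, n_dropped_sightings = 0L),
    class = "encounter_history")
}

# model-matched generator settings for parameter-recovery checks: no
# wet-season observability gap, every individual sexed
recovery_config <- function(seed) {
  sim_config(seed = seed, wet_range_contraction = 1, range_sd_wet = 3,
             sex_assignment_k = Inf, p_death_obs = 0.02)
}

quick_mcmc <- function(seed = 1, n_iter = 800, n_burnin = 200) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, seed = seed)
}

# closed-capture matrix with logit-normal heterogeneity, detected rows only
sim_closed_matrix <- function(N, J, p_mean, sigma = 0) {
  eps <- rnorm(N, 0, sigma)
  p <- plogis(qlogis(p_mean) + eps)
  y <- matrix(rbinom(N * J, 1, rep(p, J)), N, J)
  y[rowSums(y) > 0, , drop = FALSE]
}
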