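# Rank-normalized split-chain convergence diagnostics (Vehtari et al. style).

as_chain_matrix <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least 2 chains are required")
  x
}

split_halves <- function(m) {
  n <- floor(nrow(m) / 2)
  cbind(m[seq_len(n), , drop = FALSE],
        m[seq_len(n) + (nrow(m) - n), , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- qnorm((rank(m, ties.method = "average") - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Rank-normalized split R-hat: each chain is halved, all draws are replaced
#' by normal scores of their pooled ranks, and the classic between/within
#' variance ratio is computed on the result. Values near 1 indicate mixing;
#' values above 1.1 are treated as non-convergence throughout the package.
#'
#' @param x matrix of draws (iterations x chains) or list of equal-length
#'   chain vectors.
#' @return scalar R-hat.
#' @export
rhat <- function(x) {
  m <- rank_normalize(split_halves(as_chain_matrix(x)))
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws, computed on rank-normalized split
#' chains with the chain-averaged autocorrelation and Geyer's initial
#' monotone positive sequence truncation.
#'
#' @inheritParams rhat
#' @return scalar ESS.
#' @export
ess_bulk <- function(x) {
  m <- rank_normalize(split_halves(as_chain_matrix(x)))
  n <- nrow(m); nc <- ncol(m)
  if (all(abs(m - m[1]) < 1e-12)) return(NA_real_)
  lag_max <- min(n - 1L, 500L)
  acov <- vapply(seq_len(nc), function(j)
    drop(acf(m[, j], lag.max = lag_max, type = "covariance",
             plot = FALSE, demean = TRUE)$acf) * (n - 1) / n,
    numeric(lag_max + 1))
  W <- mean(acov[1, ] * n / (n - 1))
  B <- n * var(colMeans(m))
  var_plus <- W * (n - 1) / n + B / n
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer pairing: Gamma_k = rho_{2k} + rho_{2k+1}, truncated at the first
  # negative pair and forced non-increasing
  K <- floor(length(rho) / 2)
  G <- rho[2 * seq_len(K) - 1] + rho[2 * seq_len(K)]
  stop_at <- which(G < 0)[1]
  if (!is.na(stop_at)) G <- G[seq_len(max(stop_at - 1, 1))]
  if (length(G) > 1) G <- cummin(G)
  tau <- max(2 * sum(G) - 1, 1 / log10(nc * n + 10))
  min(nc * n / tau, nc * n)
}

#' Convergence diagnostics for every monitored parameter
#'
#' @param draws list of per-chain draw matrices with identical column names.
#' @return data frame with `parameter`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  stopifnot(is.list(draws), length(draws) >= 2)
  pars <- colnames(draws[[1]])
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_)
  for (i in seq_along(pars)) {
    ch <- lapply(draws, function(d) d[, pars[i]])
    if (sd(unlist(ch)) < 1e-12) { out$rhat[i] <- 1; next }
    out$rhat[i] <- rhat(ch)
    out$ess[i] <- ess_bulk(ch)
  }
  out
}
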