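#' Augment an observed capture matrix with all-zero pseudo-histories
#'
#' Parameter-expanded data augmentation recasts unknown population size as
#' zero inflation: `M = ceiling(factor * n_obs)` total rows, each with an
#' inclusion indicator, so abundance is the posterior sum of indicators.
#'
#' @param observed binary matrix, one row per detected individual (every
#'   row must have at least one detection).
#' @param factor augmentation factor >= 1; 1 degenerately forces
#'   `N <= n_obs` and is allowed with a warning.
#' @return object of class `augmented_history`: `matrix` (M x J),
#'   `n_obs`, `M`.
#' @export
augment <- function(observed, factor = 3) {
  observed <- as.matrix(observed)
  if (nrow(observed) == 0 || ncol(observed) == 0) stop("empty capture matrix")
  if (!all(observed %in% c(0, 1))) stop("capture matrix must be binary")
  if (any(rowSums(observed) == 0))
    stop("observed rows with no detection are not allowed; augmentation adds the zeros")
  if (factor < 1) stop("`factor` must be >= 1")
  if (factor == 1)
    warning("factor = 1: no augmentation, abundance is forced <= number observed")
  M <- ceiling(factor * nrow(observed))
  aug <- rbind(observed,
               matrix(0L, M - nrow(observed), ncol(observed)))
  structure(list(matrix = aug, n_obs = nrow(observed), M = M),
            class = "augmented_history")
}

# marginal per-row likelihood table over row totals s = 0..J for the
# heterogeneous model, via Gauss-Hermite quadrature
mh_lik_table <- function(mu, sigma, J, gh) {
  p <- invlogit(mu + sqrt(2) * sigma * gh$x)
  w <- gh$w / sqrt(pi)
  vapply(0:J, function(s) sum(w * p^s * (1 - p)^(J - s)), numeric(1))
}

closed_deviance <- function(s, J, psi, lik_s) {
  # lik_s: length J+1 vector of P(row | included) by row total
  -2 * sum(log(psi * lik_s[s + 1] + (1 - psi) * (s == 0)))
}

#' Fit a Bayesian closed-population abundance model
#'
#' Closed capture-recapture with data augmentation, fitted by Gibbs/
#' Metropolis sampling. `"M0"` shares a single detection probability
#' (conjugate updates throughout); `"Mh"` gives every real or pseudo
#' individual a logit-normal detection deviation, `p_i = invlogit(mu_p +
#' eps_i)`. Priors: inclusion probability psi ~ Uniform(0,1); p (or
#' invlogit(mu_p)) ~ Uniform(0,1); sigma_p ~ Uniform(0, sigma_max).
#'
#' The per-draw deviance used for DIC marginalizes both the inclusion
#' indicators and (for Mh) the individual deviations, so the DIC focus is
#' (psi, detection hyperparameters).
#'
#' If the upper 2.5% of posterior N draws hit the augmented size M the fit
#' is flagged `pileup = TRUE` and a refit with a larger factor is advised.
#'
#' @param x a `season_window` (from [build_seasonal_histories()]) or a
#'   binary capture matrix with one row per detected individual.
#' @param model `"M0"` or `"Mh"`.
#' @param mcmc an [mcmc_config()].
#' @param factor augmentation factor passed to [augment()].
#' @return object of class `closed_fit`: posterior draws of `N`, `psi` and
#'   detection parameters per chain, deviance draws, `dic` components,
#'   summary, diagnostics and flags.
#' @export
fit_closed <- function(x, model = c("Mh", "M0"), mcmc = mcmc_config(),
                       factor = 3) {
  model <- match.arg(model)
  win <- NULL
  if (inherits(x, "season_window")) { win <- x; x <- x$matrix }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least 2 occasions are required")
  if (nrow(x) < 2) stop("at least 2 detected individuals are required")
  aug <- augment(x, factor)
  J <- ncol(aug$matrix); M <- aug$M
  s <- rowSums(aug$matrix)
  obs <- s > 0
  gh <- pracma::gaussHermite(20)

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    psi <- runif(1, 0.2, 0.8)
    w <- obs | (runif(M) < psi)
    if (model == "M0") {
      p <- runif(1, 0.2, 0.8)
    } else {
      mu <- rnorm(1, 0, 0.5); sigma <- runif(1, 0.3, 1.5)
      eps <- rnorm(M, 0, sigma)
      mu_step <- 0.2; eps_step <- 0.8; sig_step <- 0.3
      mu_acc <- 0; eps_acc <- 0; sig_acc <- 0
    }
    total <- mcmc$n_burnin + mcmc$n_iter
    keep <- matrix(NA_real_, mcmc$n_iter,
                   if (model == "M0") 4L else 5L)
    colnames(keep) <- if (model == "M0") c("N", "psi", "p", "deviance")
                      else c("N", "psi", "mu_p", "sigma_p", "deviance")
    for (it in seq_len(total)) {
      if (model == "M0") {
        inc <- which(w)
        p <- rbeta(1, 1 + sum(s[inc]), 1 + length(inc) * J - sum(s[inc]))
        pw <- psi * (1 - p)^J
        pw <- pw / (pw + 1 - psi)
        w[!obs] <- runif(sum(!obs)) < pw
      } else {
        p_i <- invlogit(mu + eps)
        pw <- psi * (1 - p_i[!obs])^J
        pw <- pw / (pw + 1 - psi)
        w[!obs] <- runif(sum(!obs)) < pw
        inc <- which(w)
        # eps: Metropolis for included rows, prior refresh for excluded
        prop <- eps + eps_step * rnorm(M)
        ll_cur <- s * log(p_i) + (J - s) * log(1 - p_i)
        p_prop <- invlogit(mu + prop)
        ll_prop <- s * log(p_prop) + (J - s) * log(1 - p_prop)
        lr <- ll_prop - ll_cur +
          dnorm(prop, 0, sigma, log = TRUE) - dnorm(eps, 0, sigma, log = TRUE)
        acc <- w & (log(runif(M)) < lr)
        eps[acc] <- prop[acc]
        eps[!w] <- rnorm(sum(!w), 0, sigma)
        eps_acc <- eps_acc + mean(acc[w])
        # mu
        p_i <- invlogit(mu + eps)
        mu_prop <- mu + mu_step * rnorm(1)
        pp <- invlogit(mu_prop + eps)
        lr <- sum(s[inc] * (log(pp[inc]) - log(p_i[inc])) +
                  (J - s[inc]) * (log(1 - pp[inc]) - log(1 - p_i[inc]))) +
          log(invlogit(mu_prop) * (1 - invlogit(mu_prop))) -
          log(invlogit(mu) * (1 - invlogit(mu)))
        if (log(runif(1)) < lr) { mu <- mu_prop; mu_acc <- mu_acc + 1 }
        # sigma
        sig_prop <- sigma * exp(sig_step * rnorm(1))
        if (sig_prop < mcmc$sigma_max) {
          lr <- log(sig_prop / sigma) +
            sum(dnorm(eps, 0, sig_prop, log = TRUE) -
                dnorm(eps, 0, sigma, log = TRUE))
          if (log(runif(1)) < lr) { sigma <- sig_prop; sig_acc <- sig_acc + 1 }
        }
      }
      psi <- rbeta(1, 1 + sum(w), 1 + M - sum(w))
      if (model == "Mh" && it <= mcmc$n_burnin && it %% 50 == 0) {
        adj <- function(step, rate) step * exp(if (rate > 0.44) 0.1 else -0.1)
        mu_step <- adj(mu_step, mu_acc / 50); mu_acc <- 0
        sig_step <- adj(sig_step, sig_acc / 50); sig_acc <- 0
        eps_step <- adj(eps_step, eps_acc / 50); eps_acc <- 0
      }
      if (it > mcmc$n_burnin) {
        k <- it - mcmc$n_burnin
        if (model == "M0") {
          lik_s <- p^(0:J) * (1 - p)^(J - (0:J))
          keep[k, ] <- c(sum(w), psi, p, closed_deviance(s, J, psi, lik_s))
        } else {
          lik_s <- mh_lik_table(mu, sigma, J, gh)
          keep[k, ] <- c(sum(w), psi, mu, sigma,
                         closed_deviance(s, J, psi, lik_s))
        }
      }
    }
    chains[[ch]] <- keep
  }

  all_draws <- do.call(rbind, chains)
  Nd <- all_draws[, "N"]
  pileup <- unname(quantile(Nd, 0.975)) >= M
  if (pileup)
    warning("posterior abundance piles up at the augmented size M; refit with a larger `factor`",
            call. = FALSE)
  # DIC with plug-in deviance at posterior means of the focus parameters
  dbar <- mean(all_draws[, "deviance"])
  if (model == "M0") {
    lik_hat <- mean(all_draws[, "p"])^(0:J) *
      (1 - mean(all_draws[, "p"]))^(J - (0:J))
  } else {
    lik_hat <- mh_lik_table(mean(all_draws[, "mu_p"]),
                            mean(all_draws[, "sigma_p"]), J, gh)
  }
  dhat <- closed_deviance(s, J, mean(all_draws[, "psi"]), lik_hat)
  pD <- dbar - dhat
  dic <- dbar + pD
  diag_pars <- setdiff(colnames(all_draws), "deviance")
  diag <- mcmc_diagnostics(lapply(chains, function(d) d[, diag_pars, drop = FALSE]))
  summary <- c(summarize_draws(Nd), n_obs = aug$n_obs)
  structure(list(model = model, draws = chains, N = Nd,
                 summary = summary,
                 dic = c(DIC = dic, Dbar = dbar, Dhat = dhat, pD = pD),
                 pileup = pileup, M = M, n_obs = aug$n_obs,
                 diagnostics = diag, season = win$season, year = win$year,
                 mcmc = mcmc),
            class = "closed_fit")
}

#' @export
print.closed_fit <- function(x, ...) {
  hdr <- if (!is.null(x$season))
    sprintf(" [%s %d]", x$season, x$year) else ""
  cat(sprintf("Closed %s fit%s: %d observed, M = %d\n", x$model, hdr,
              x$n_obs, x$M))
  cat(sprintf("  N-hat median %.0f [95%% CRI %.0f, %.0f], DIC %.1f (pD %.1f)\n",
              x$summary["median"], x$summary["lower"], x$summary["upper"],
              x$dic["DIC"], x$dic["pD"]))
  if (x$pileup) cat("  ** augmentation pile-up: increase `factor` **\n")
  invisible(x)
}

#' Deviance information criterion of a closed-model fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior means)` (plug-in form).
#' Differences above 10 are treated as decisive model preference.
#'
#' @param fit a [fit_closed()] result.
#' @return scalar DIC.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "closed_fit"))
  d <- unname(fit$dic["DIC"])
  if (!is.finite(d)) stop("non-finite deviance draws")
  d
}
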