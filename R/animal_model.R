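#' Bayesian animal model for a quantitative trait on a pedigree
#'
#' Fits, by Gibbs sampling, the mixed model
#' \deqn{y = 1\mu + a + (m) + e, \quad a \sim N(0, \sigma^2_a A),\quad
#'       m \sim N(0, \sigma^2_m I_{dams}),\quad e \sim N(0, \sigma^2_e I)}
#' where `A` is a relatedness (additive relationship) matrix over the
#' phenotyped individuals and `m` is an optional maternal common-environment
#' effect shared by larvae of the same dam. Narrow-sense heritability is
#' derived per retained iteration as
#' `h2 = sigma2_a / (sigma2_a + sigma2_e (+ sigma2_m))`.
#'
#' Variance components carry non-informative inverse-gamma(0.001, 0.001)
#' priors by default; the intercept has a flat prior. The sampler works in
#' the eigenbasis of `A` so each sweep is O(n^2), which makes study-scale
#' chains (1.5e6 iterations, thinning 50, 10% burn-in) feasible; the desk
#' default is 2e4 iterations with the same thinning and burn-in fractions.
#'
#' @param y numeric trait vector (finite, non-degenerate).
#' @param A relatedness matrix, `length(y) x length(y)`, PSD (a one-off
#'   jitter of 1e-8 is applied if the eigenvalues dip marginally below
#'   zero; genuinely indefinite matrices are an error suggesting
#'   [nearest_psd()]).
#' @param dam_ids maternal identities per individual; non-NULL fits the
#'   maternal random effect.
#' @param iterations,thinning,burn_in_fraction chain settings.
#' @param prior_shape,prior_scale inverse-gamma hyperparameters shared by
#'   all variance components.
#' @param seed integer RNG seed.
#' @return object of class `animal_model`: list with `chains` (data.frame
#'   of retained samples of `mu`, `sigma2_a`, `sigma2_e`, optional
#'   `sigma2_m`, and `h2`), `summary` (per-parameter posterior mean, sd,
#'   mode, 95% HPD bounds), `dic`, `pd`, `a_hat` (posterior mean breeding
#'   values), `maternal`, `y`, and the call settings.
#' @seealso [compare_dic()], [mcmc_diagnostics()], [relatedness_tabular()],
#'   [relatedness_matrix_sibclass()]
#' @export
fit_animal_model <- function(y, A, dam_ids = NULL,
                             iterations = 2e4, thinning = 50,
                             burn_in_fraction = 0.1,
                             prior_shape = 0.001, prior_scale = 0.001,
                             seed = 1L) {
  n <- length(y)
  if (!all(is.finite(y))) stop("trait vector must be finite")
  if (stats::var(y) <= 0) stop("degenerate trait: zero variance")
  if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
    stop("A must be a ", n, " x ", n, " matrix matching y")
  maternal <- !is.null(dam_ids)
  if (maternal && length(dam_ids) != n) stop("dam_ids must match y")

  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("A is not positive semi-definite even after jitter; ",
         "consider nearest_psd(A)")
  d <- pmax(eg$values, 1e-8)          # one-off jitter for marginal negatives
  U <- eg$vectors

  burn <- floor(iterations * burn_in_fraction)
  keep_n <- floor((iterations - burn) / thinning)
  if (keep_n < 2L) stop("chain settings retain fewer than 2 samples")

  set.seed(as.integer(seed))
  vy <- stats::var(y)
  s2a <- vy / 2; s2e <- vy / 2; s2m <- if (maternal) vy / 4 else 0
  mu <- mean(y)
  b <- rep(0, n)                      # breeding values in the eigenbasis
  if (maternal) {
    dam <- factor(dam_ids)
    dmat <- stats::model.matrix(~ dam - 1)
    ndam <- nlevels(dam)
    ng <- colSums(dmat)
    mg <- rep(0, ndam)
  }
  m_vec <- rep(0, n)

  cols <- c("mu", "sigma2_a", "sigma2_e", if (maternal) "sigma2_m", "h2")
  chains <- matrix(NA_real_, keep_n, length(cols), dimnames = list(NULL, cols))
  b_sum <- rep(0, n); m_sum <- if (maternal) rep(0, length(mg)) else NULL
  dev_sum <- 0
  s2e_keep <- numeric(keep_n); mu_sum <- 0
  kept <- 0L
  a0 <- prior_shape; b0 <- prior_scale

  # the whole sweep runs in the eigenbasis of A, where every conditional is
  # diagonal: only O(n) (plus O(n * n_dams) for the maternal cross-terms)
  # per iteration
  yt <- drop(crossprod(U, y))         # U'y
  u1 <- drop(crossprod(U, rep(1, n))) # U'1
  ybar <- mean(y)
  if (maternal) {
    Ud <- crossprod(U, dmat)          # n x ndam
    mt <- rep(0, n)                   # U'm
  } else mt <- rep(0, n)

  for (it in seq_len(iterations)) {
    # intercept (flat prior): mean(y - a - m) = ybar - u1'b/n - ng'mg/n
    mbar <- if (maternal) sum(ng * mg) / n else 0
    mu <- stats::rnorm(1L, ybar - sum(u1 * b) / n - mbar, sqrt(s2e / n))
    # breeding values: diagonal full conditional in the eigenbasis
    tstar <- yt - mu * u1 - mt
    prec <- 1 / s2e + 1 / (s2a * d)
    b <- stats::rnorm(n, (tstar / s2e) / prec, sqrt(1 / prec))
    # maternal effects
    if (maternal) {
      sg <- drop(crossprod(dmat, y)) - mu * ng - drop(crossprod(Ud, b))
      pg <- ng / s2e + 1 / s2m
      mg <- stats::rnorm(ndam, (sg / s2e) / pg, sqrt(1 / pg))
      mt <- drop(Ud %*% mg)
      s2m <- 1 / stats::rgamma(1L, a0 + ndam / 2, b0 + sum(mg^2) / 2)
    }
    # variance components
    s2a <- 1 / stats::rgamma(1L, a0 + n / 2, b0 + sum(b^2 / d) / 2)
    ess <- sum((yt - mu * u1 - mt - b)^2)   # ||e||^2, rotation-invariant
    s2e <- 1 / stats::rgamma(1L, a0 + n / 2, b0 + ess / 2)

    if (it > burn && (it - burn) %% thinning == 0L) {
      kept <- kept + 1L
      h2 <- s2a / (s2a + s2e + if (maternal) s2m else 0)
      chains[kept, ] <- c(mu, s2a, s2e, if (maternal) s2m, h2)
      b_sum <- b_sum + b
      mu_sum <- mu_sum + mu
      if (maternal) m_sum <- m_sum + mg
      dev_sum <- dev_sum + n * log(2 * pi * s2e) + ess / s2e
      s2e_keep[kept] <- s2e
    }
  }
  chains <- as.data.frame(chains[seq_len(kept), , drop = FALSE])

  # DIC from the conditional (on random effects) Gaussian deviance
  a_hat <- drop(U %*% (b_sum / kept))
  mu_hat <- mu_sum / kept
  m_hat_vec <- if (maternal) drop(dmat %*% (m_sum / kept)) else rep(0, n)
  s2e_hat <- mean(s2e_keep[seq_len(kept)])
  e_hat <- y - mu_hat - a_hat - m_hat_vec
  d_bar <- dev_sum / kept
  d_hat <- sum(log(2 * pi * s2e_hat) + e_hat^2 / s2e_hat)
  pd <- d_bar - d_hat
  dic <- d_bar + pd

  summ <- do.call(rbind, lapply(names(chains), function(p) {
    ch <- chains[[p]]
    posterior_summary(ch, support = if (p == "h2") c(0, 1) else NULL)
  }))
  summ <- data.frame(parameter = names(chains), summ)

  structure(list(chains = chains, summary = summ, dic = dic, pd = pd,
                 a_hat = stats::setNames(a_hat, names(y)),
                 maternal = maternal, y = y,
                 settings = list(iterations = iterations, thinning = thinning,
                                 burn_in_fraction = burn_in_fraction,
                                 prior_shape = prior_shape,
                                 prior_scale = prior_scale, seed = seed)),
            class = "animal_model")
}

# posterior mean/sd, KDE mode (512-point grid, Silverman bandwidth,
# restricted to the support when given) and 95% HPD interval
posterior_summary <- function(x, support = NULL, prob = 0.95) {
  if (is.null(support)) {
    dens <- stats::density(x, n = 512)
  } else {
    dens <- stats::density(x, n = 512, from = support[1L], to = support[2L])
  }
  hpd <- hpd_interval(x, prob)
  data.frame(mean = mean(x), sd = stats::sd(x),
             mode = dens$x[which.max(dens$y)],
             hpd_low = hpd[1L], hpd_high = hpd[2L])
}

#' Highest-posterior-density interval from samples
#'
#' Shortest interval containing a `prob` fraction of the sorted samples.
#'
#' @param x numeric sample vector.
#' @param prob coverage probability.
#' @return length-2 numeric `(low, high)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Bayesian animal model (Gibbs),",
      if (x$maternal) "additive + maternal" else "additive", "random effects\n")
  cat("  n =", length(x$y), " retained samples =", nrow(x$chains), "\n")
  h2 <- x$summary[x$summary$parameter == "h2", ]
  cat(sprintf("  h2: mean %.2f (sd %.2f), mode %.2f, 95%% HPD [%.2f, %.2f]\n",
              h2$mean, h2$sd, h2$mode, h2$hpd_low, h2$hpd_high))
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic, x$pd))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  out <- object$summary
  attr(out, "dic") <- object$dic
  class(out) <- c("summary.animal_model", "data.frame")
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  df <- x; class(df) <- "data.frame"
  print(format(df, digits = 3), row.names = FALSE)
  cat("DIC:", format(attr(x, "dic"), digits = 5), "\n")
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
residuals.animal_model <- function(object, ...) {
  mu_hat <- object$summary$mean[object$summary$parameter == "mu"]
  object$y - mu_hat - object$a_hat
}

#' @export
plot.animal_model <- function(x, parameter = "h2", ...) {
  ch <- x$chains[[parameter]]
  if (is.null(ch)) stop("no chain for parameter '", parameter, "'")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(ch, type = "l", xlab = "retained iteration",
                 ylab = parameter, main = "trace", ...)
  if (parameter == "h2") {
    graphics::plot(stats::density(ch, from = 0, to = 1), main = "posterior",
                   xlab = parameter)
  } else {
    graphics::plot(stats::density(ch), main = "posterior", xlab = parameter)
  }
  invisible(x)
}

#' Compare nested animal models by DIC
#'
#' Computes the DIC difference between a model without and a model with the
#' maternal random effect (both fitted to the same trait vector). Following
#' the usual rule of thumb, the added effect is declared "no improvement"
#' when it fails to lower the DIC by at least 2 units.
#'
#' @param fit_without,fit_with `animal_model` fits of the same `y`.
#' @return list with `delta_dic` (`DIC_without - DIC_with`; positive means
#'   the maternal model fits better) and `verdict` ("improvement" /
#'   "no improvement").
#' @export
compare_dic <- function(fit_without, fit_with) {
  stopifnot(inherits(fit_without, "animal_model"),
            inherits(fit_with, "animal_model"))
  if (!isTRUE(all.equal(fit_without$y, fit_with$y)))
    stop("the two fits are not based on the same trait vector")
  delta <- fit_without$dic - fit_with$dic
  list(delta_dic = delta,
       verdict = if (delta >= 2) "improvement" else "no improvement")
}

#' MCMC chain diagnostics
#'
#' Lag-k autocorrelations (k up to 50) and Geyer's initial-monotone-sequence
#' effective sample size, computed from the even/odd pair sums of the
#' autocorrelation function.
#'
#' @param chain numeric vector of at least 10 samples.
#' @param max_lag largest autocorrelation lag reported.
#' @return list with `ess`, `autocorrelation` (named numeric, lags
#'   1..max_lag) and `n`. A constant chain yields `ess = NA` with a warning.
#' @export
mcmc_diagnostics <- function(chain, max_lag = 50L) {
  n <- length(chain)
  if (n < 10L) stop("chain too short for diagnostics (need >= 10)")
  if (stats::var(chain) == 0) {
    warning("constant chain: effective sample size undefined")
    return(list(ess = NA_real_,
                autocorrelation = stats::setNames(rep(NA_real_, max_lag),
                                                  paste0("lag", seq_len(max_lag))),
                n = n))
  }
  lag_max <- min(max_lag, n - 2L)
  rho <- drop(stats::acf(chain, lag.max = n - 2L, plot = FALSE)$acf)
  # Geyer pair sums Gamma_k = rho_{2k} + rho_{2k+1}: keep while positive,
  # then enforce monotone non-increase
  npair <- (length(rho) - 1L) %/% 2L
  gam <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1L] - 1L)]
  if (length(gam) > 1L) gam <- cummin(gam)
  tau <- max(-1 + 2 * sum(gam), 1e-8)
  list(ess = min(n, n / tau),
       autocorrelation = stats::setNames(rho[seq_len(lag_max) + 1L],
                                         paste0("lag", seq_len(lag_max))),
       n = n)
}
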