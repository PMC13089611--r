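#' Split-chain Gelman-Rubin potential scale reduction
#'
#' Each chain is split in half before computing the between/within variance
#' ratio, so within-chain trends inflate the statistic.  Parameters with
#' zero within-chain variance are reported as `NA`.
#'
#' @param draws A `posterior_draws` or an iterations x chains matrix for a
#'   single parameter.
#' @param pars Optional parameter names (default: all).
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(draws, pars = NULL) {
  if (inherits(draws, "posterior_draws")) {
    nm <- dimnames(draws$draws)[[3]]
    if (is.null(pars)) pars <- nm
    return(vapply(pars, function(p) rhat(draws$draws[, , p]), numeric(1)))
  }
  m <- as.matrix(draws)                 # iterations x chains
  n <- nrow(m)
  if (n < 4 || ncol(m) < 2) stop("need >= 2 chains with >= 4 draws")
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(m)), function(ci)
    cbind(m[seq_len(half), ci], m[(n - half + 1):n, ci])))
  nn <- nrow(splits)
  w <- mean(apply(splits, 2, stats::var))
  if (!is.finite(w) || w <= .Machine$double.eps) return(NA_real_)
  b <- nn * stats::var(colMeans(splits))
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Posterior predictive replicates of the response
#'
#' For `n_rep` randomly chosen posterior draws, simulates a full replicated
#' response vector from the log-normal observation model and summarizes how
#' the observed data sit within the replicate distribution.
#'
#' @param draws A `posterior_draws`.
#' @param data The `model_data` the draws were fitted to.
#' @param n_rep Number of replicated datasets (0 gives an empty result).
#' @param seed RNG seed for the replicate simulation.
#' @return List: `y_rep` (n_rep x n matrix), `summary` (data.frame of
#'   observed vs replicated mean/sd/quantiles and their tail probabilities).
#' @export
posterior_predictive <- function(draws, data, n_rep = 200, seed = 1) {
  if (n_rep == 0)
    return(list(y_rep = matrix(numeric(), 0, length(data$y)), summary = NULL))
  set.seed(seed)
  m <- pooled_draws(draws)
  pick <- sample.int(nrow(m), n_rep, replace = n_rep > nrow(m))
  n <- length(data$y)
  acols <- paste0("alpha[", seq_len(data$n_tree), "]")
  gcols <- paste0("gamma[", seq_len(data$n_site), "]")
  bcols <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second", "b_mix_second")
  y_rep <- matrix(NA_real_, n_rep, n)
  for (k in seq_along(pick)) {
    s <- pick[k]
    mu <- as.numeric(data$X %*% m[s, bcols]) +
      m[s, "sigma_alpha"] * m[s, acols][data$tree] +
      m[s, "sigma_gamma"] * m[s, gcols][data$site]
    y_rep[k, ] <- stats::rlnorm(n, mu, m[s, "sigma"])
  }
  stat <- function(f) apply(y_rep, 1, f)
  obs <- c(mean = mean(data$y), sd = stats::sd(data$y),
           q10 = unname(stats::quantile(data$y, 0.1)),
           q90 = unname(stats::quantile(data$y, 0.9)))
  reps <- cbind(mean = stat(mean), sd = stat(stats::sd),
                q10 = stat(function(v) stats::quantile(v, 0.1)),
                q90 = stat(function(v) stats::quantile(v, 0.9)))
  summ <- data.frame(
    stat = names(obs), observed = as.numeric(obs),
    rep_mean = colMeans(reps),
    rep_q025 = apply(reps, 2, stats::quantile, 0.025),
    rep_q975 = apply(reps, 2, stats::quantile, 0.975),
    p_tail = vapply(seq_along(obs), function(j)
      mean(reps[, j] >= obs[j]), numeric(1)))
  list(y_rep = y_rep, summary = summ)
}

#' Bayesian R-squared
#'
#' Per posterior draw, the share of modelled variance: on the log
#' (linear-predictor) scale var(mu) / (var(mu) + sigma^2); on the response
#' scale the variance of the log-normal means against the mean log-normal
#' variance.
#'
#' @param draws A `posterior_draws`.
#' @param data The fitted `model_data`.
#' @param scale `"log"` (default) or `"response"`.
#' @return Numeric vector, one R^2 per pooled draw.
#' @export
bayes_r2 <- function(draws, data, scale = c("log", "response")) {
  scale <- match.arg(scale)
  m <- pooled_draws(draws)
  acols <- paste0("alpha[", seq_len(data$n_tree), "]")
  gcols <- paste0("gamma[", seq_len(data$n_site), "]")
  bcols <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second", "b_mix_second")
  vapply(seq_len(nrow(m)), function(s) {
    mu <- as.numeric(data$X %*% m[s, bcols]) +
      m[s, "sigma_alpha"] * m[s, acols][data$tree] +
      m[s, "sigma_gamma"] * m[s, gcols][data$site]
    sig2 <- m[s, "sigma"]^2
    if (scale == "log") {
      v <- stats::var(mu)
      v / (v + sig2)
    } else {
      mm <- exp(mu + sig2 / 2)
      vv <- (exp(sig2) - 1) * exp(2 * mu + sig2)
      stats::var(mm) / (stats::var(mm) + mean(vv))
    }
  }, numeric(1))
}

#' Generalized Pareto shape estimate for a sample of tail exceedances
#'
#' Empirical-Bayes profile estimator (the standard method for PSIS tail
#' fitting), with the usual weak shape regularization towards 0.5.
#'
#' @param x Positive exceedances over the tail threshold.
#' @param regularize Apply the n/(n+10) shrinkage of the shape towards 0.5.
#' @return List with `k` (shape) and `sigma` (scale).
#' @export
gpd_fit <- function(x, regularize = TRUE) {
  x <- sort(x[is.finite(x) & x > 0])
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  kfun <- function(th) vapply(th, function(t) mean(log1p(-t * x)), numeric(1))
  kv <- kfun(theta)
  lth <- n * (log(-theta / kv) - kv - 1)
  lth[!is.finite(lth)] <- -Inf
  w <- exp(lth - max(lth)); w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (regularize) k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

#' Pareto-smoothed importance-sampling influence diagnostics
#'
#' For each observation, forms leave-one-out importance ratios
#' 1 / p(y_i | theta_s) across posterior draws, fits a generalized Pareto
#' distribution to the largest min(20%, 3 sqrt(S)) ratios, and reports the
#' tail-shape estimate k.  Observations with k > 0.7 are flagged as highly
#' influential.
#'
#' @param draws A `posterior_draws`.
#' @param data The fitted `model_data`.
#' @param thin Thinning passed to [pointwise_loglik].
#' @param flag_threshold Influence flag cutoff (default 0.7).
#' @return data.frame: obs, k, flagged.
#' @export
pareto_k <- function(draws, data, thin = 1, flag_threshold = 0.7) {
  ll <- pointwise_loglik(draws, data, thin = thin)
  S <- nrow(ll)
  n_tail <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  ks <- vapply(seq_len(ncol(ll)), function(i) {
    lr <- -ll[, i]                       # log importance ratios
    lr <- lr - max(lr)
    r <- exp(lr)
    cutoff <- sort(r, decreasing = TRUE)[n_tail + 1]
    exceed <- r[r > cutoff] - cutoff
    if (length(exceed) < 5) return(NA_real_)
    gpd_fit(exceed)$k
  }, numeric(1))
  data.frame(obs = seq_len(ncol(ll)), k = ks,
             flagged = !is.na(ks) & ks > flag_threshold)
}
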