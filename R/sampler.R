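#' Sampler configuration
#'
#' @param chains Number of chains (default 4).
#' @param iter Total iterations per chain, including warmup (default 6000).
#' @param warmup Burn-in iterations discarded per chain (default 2000).
#' @param seed Integer RNG seed.
#' @param likelihood If `FALSE`, sample from the priors only (prior
#'   predictive of the parameters; used for prior checks).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(chains = 4, iter = 6000, warmup = 2000, seed = 1,
                           likelihood = TRUE) {
  stopifnot(chains >= 1, warmup < iter, warmup >= 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 likelihood = isTRUE(likelihood)),
            class = "sampler_config")
}

# One-dimensional slice sampler (Neal 2003, stepping out + shrinkage).
slice1 <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  for (i in seq_len(max_steps)) { if (logf(L) <= z) break; L <- L - w }
  for (i in seq_len(max_steps)) { if (logf(R) <= z) break; R <- R + w }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Truncated-normal draw on (0, Inf) by inverse CDF.
rtnorm_pos <- function(mean, sd) {
  plo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(1, plo, 1)
  x <- stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
  if (!is.finite(x) || x <= 0) x <- abs(mean) * 1e-6 + 1e-8
  x
}

# Conditional scale update used by the interweaving step: p(s | effects b)
# with b_t ~ N(0, s^2) and half-normal(0, prior_sd) prior on s, sampled on
# the log scale.
slice_scale_given_effects <- function(s0, b, prior_sd) {
  sumb2 <- sum(b^2); k <- length(b)
  logf <- function(u) {
    -k * u - exp(-2 * u) * sumb2 / 2 - exp(2 * u) / (2 * prior_sd^2) + u
  }
  exp(slice1(log(s0), logf, w = 0.5))
}

run_chain <- function(data, priors, config, chain_id) {
  set.seed((config$seed %% 100000L) * 10007L + chain_id)
  n <- length(data$y); r <- log(data$y)
  X <- data$X; P <- ncol(X)
  Tn <- data$n_tree; S <- data$n_site
  like <- config$likelihood
  # membership matrices and the fixed cross-products of the joint design
  Mt <- matrix(0, n, Tn); Mt[cbind(seq_len(n), data$tree)] <- 1
  Ms <- matrix(0, n, S); Ms[cbind(seq_len(n), data$site)] <- 1
  XtX <- crossprod(X); XtMt <- crossprod(X, Mt); XtMs <- crossprod(X, Ms)
  MtMs <- crossprod(Mt, Ms)
  n_t <- tabulate(data$tree, Tn); n_s <- tabulate(data$site, S)
  Xtr <- as.numeric(crossprod(X, r))
  Mtr <- as.numeric(crossprod(Mt, r)); Msr <- as.numeric(crossprod(Ms, r))
  K <- P + Tn + S
  iP <- seq_len(P); iT <- P + seq_len(Tn); iS <- P + Tn + seq_len(S)
  prior_prec <- c(rep(1 / priors$beta_sd^2, P), rep(1, Tn + S))
  # initial state
  beta <- stats::rnorm(P, 0, 0.5)
  alpha <- stats::rnorm(Tn); gam <- stats::rnorm(S)
  sigma <- 0.5; sa <- 0.5; sg <- 0.5
  n_keep <- config$iter - config$warmup
  pnames <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second",
              "b_mix_second", "sigma", "sigma_alpha", "sigma_gamma",
              paste0("alpha[", seq_len(Tn), "]"),
              paste0("gamma[", seq_len(S), "]"))
  out <- matrix(NA_real_, n_keep, length(pnames),
                dimnames = list(NULL, pnames))
  prior_sd <- priors$scale_sd
  for (it in seq_len(config$iter)) {
    if (like) {
      # --- (beta, alpha, gamma) | scales: one joint Gaussian draw.
      # Sampling all location parameters in one block removes the slow
      # ridge between the drought-level coefficients and the site effects.
      H <- matrix(0, K, K)
      H[iP, iP] <- XtX
      H[iP, iT] <- sa * XtMt;        H[iT, iP] <- t(H[iP, iT])
      H[iP, iS] <- sg * XtMs;        H[iS, iP] <- t(H[iP, iS])
      H[iT, iT] <- diag(sa^2 * n_t, Tn)
      H[iT, iS] <- sa * sg * MtMs;   H[iS, iT] <- t(H[iT, iS])
      H[iS, iS] <- diag(sg^2 * n_s, S)
      H <- H / sigma^2
      diag(H) <- diag(H) + prior_prec
      bvec <- c(Xtr, sa * Mtr, sg * Msr) / sigma^2
      ch <- chol(H)
      m <- backsolve(ch, forwardsolve(t(ch), bvec))
      u <- as.numeric(m + backsolve(ch, stats::rnorm(K)))
      beta <- u[iP]; alpha <- u[iT]; gam <- u[iS]
      xb <- as.numeric(X %*% beta)
      # --- sigma_alpha | alpha, rest: truncated-normal conjugate,
      # then an ancillarity-sufficiency interweaving step
      r2 <- r - xb - sg * gam[data$site]
      ua <- alpha[data$tree]
      prec_s <- 1 / prior_sd^2 + sum(ua^2) / sigma^2
      mean_s <- sum(ua * r2) / sigma^2 / prec_s
      sa <- rtnorm_pos(mean_s, 1 / sqrt(prec_s))
      b_eff <- sa * alpha
      sa <- slice_scale_given_effects(sa, b_eff, prior_sd)
      alpha <- b_eff / sa
      # --- sigma_gamma likewise
      r3 <- r - xb - sa * alpha[data$tree]
      ug <- gam[data$site]
      prec_sg <- 1 / prior_sd^2 + sum(ug^2) / sigma^2
      mean_sg <- sum(ug * r3) / sigma^2 / prec_sg
      sg <- rtnorm_pos(mean_sg, 1 / sqrt(prec_sg))
      g_eff <- sg * gam
      sg <- slice_scale_given_effects(sg, g_eff, prior_sd)
      gam <- g_eff / sg
      # --- sigma | rest: slice on log scale
      sse <- sum((r - xb - sa * alpha[data$tree] - sg * gam[data$site])^2)
      logf_sig <- function(uu) {
        -n * uu - exp(-2 * uu) * sse / 2 - exp(2 * uu) / (2 * prior_sd^2) + uu
      }
      sigma <- exp(slice1(log(sigma), logf_sig, w = 0.5))
    } else {
      beta <- stats::rnorm(P, 0, priors$beta_sd)
      alpha <- stats::rnorm(Tn); gam <- stats::rnorm(S)
      sigma <- abs(stats::rnorm(1, 0, prior_sd))
      sa <- abs(stats::rnorm(1, 0, prior_sd))
      sg <- abs(stats::rnorm(1, 0, prior_sd))
    }
    if (it > config$warmup)
      out[it - config$warmup, ] <- c(beta, sigma, sa, sg, alpha, gam)
  }
  out
}

#' Sample the posterior of the drought-response model
#'
#' Blocked Gibbs sampler for the hierarchical log-normal regression.  On the
#' log scale the model is linear-Gaussian, so regression coefficients and
#' the non-centred tree and site effects have exact Gaussian full
#' conditionals; the effect scales are drawn from their truncated-normal
#' conditionals followed by an ancillarity-sufficiency interweaving step,
#' and the residual scale by slice sampling.  Deterministic for a fixed
#' seed.
#'
#' @param data A `model_data` from [make_model_data].
#' @param priors A [prior_spec].
#' @param config A [sampler_config].
#' @return A `posterior_draws`: array `draws` (iterations x chains x
#'   parameters), plus data/config references.
#' @export
sample_posterior <- function(data, priors = prior_spec(),
                             config = sampler_config()) {
  chains <- lapply(seq_len(config$chains), function(ci)
    run_chain(data, priors, config, ci))
  arr <- array(NA_real_, dim = c(nrow(chains[[1]]), config$chains,
                                 ncol(chains[[1]])),
               dimnames = list(NULL, NULL, colnames(chains[[1]])))
  for (ci in seq_along(chains)) arr[, ci, ] <- chains[[ci]]
  structure(list(draws = arr, config = config, priors = priors,
                 n_tree = data$n_tree, n_site = data$n_site),
            class = "posterior_draws")
}

#' Pool the chains of a `posterior_draws` into one matrix
#' @param draws A `posterior_draws`.
#' @return Matrix (chains * iterations) x parameters.
#' @export
pooled_draws <- function(draws) {
  d <- draws$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(ci) d[, ci, ]))
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_draws> %d draws x %d chains x %d parameters\n",
              d[1], d[2], d[3]))
  invisible(x)
}
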