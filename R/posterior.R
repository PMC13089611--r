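#' Prior specification for the drought-response model
#'
#' Weakly informative priors: normal(0, 1) on every regression coefficient
#' and half-normal(0, 1) on the residual and varying-effect scales.
#'
#' @param beta_sd Coefficient prior SD.
#' @param scale_sd Half-normal SD of sigma, sigma_alpha, sigma_gamma.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(beta_sd = 1, scale_sd = 1) {
  stopifnot(beta_sd > 0, scale_sd > 0)
  structure(list(beta_sd = beta_sd, scale_sd = scale_sd),
            class = "prior_spec")
}

half_normal_lpdf <- function(x, sd) {
  ifelse(x <= 0, -Inf, 0.5 * log(2 / pi) - log(sd) - x^2 / (2 * sd^2))
}

# Linear predictor mu_i for a parameter state.
linpred <- function(par, data) {
  as.numeric(data$X %*% par$beta) +
    par$sigma_alpha * par$alpha[data$tree] +
    par$sigma_gamma * par$gamma[data$site]
}

#' Joint log-posterior density of the hierarchical log-normal model
#'
#' The observation model is y_i ~ lognormal(mu_i, sigma) with
#' mu_i = X beta + sigma_alpha * alpha_tree(i) + sigma_gamma * gamma_site(i)
#' and no overall intercept (both drought-level indicators carry their own
#' coefficient).  Tree and site effects are non-centred: alpha, gamma are
#' standard-normal, scaled inside mu.  Scale parameters are supplied on the
#' log scale and the log-density includes the change-of-variable Jacobian.
#'
#' @param par Named list: beta (length-6 numeric, order ci, mix, dbh, first,
#'   second, mix_second), alpha, gamma (effect vectors), log_sigma,
#'   log_sigma_alpha, log_sigma_gamma.
#' @param data A `model_data` (see [make_model_data]).
#' @param priors A [prior_spec].
#' @return Scalar joint log density (log-likelihood + log-priors +
#'   Jacobians).
#' @export
log_posterior <- function(par, data, priors = prior_spec()) {
  p <- par
  p$sigma <- exp(par$log_sigma)
  p$sigma_alpha <- exp(par$log_sigma_alpha)
  p$sigma_gamma <- exp(par$log_sigma_gamma)
  if (any(!is.finite(c(p$beta, p$alpha, p$gamma, p$sigma, p$sigma_alpha,
                       p$sigma_gamma))))
    stop("non-finite parameter value")
  mu <- linpred(p, data)
  ll <- sum(stats::dlnorm(data$y, meanlog = mu, sdlog = p$sigma, log = TRUE))
  lp <- sum(stats::dnorm(p$beta, 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(p$alpha, log = TRUE)) +
    sum(stats::dnorm(p$gamma, log = TRUE)) +
    half_normal_lpdf(p$sigma, priors$scale_sd) +
    half_normal_lpdf(p$sigma_alpha, priors$scale_sd) +
    half_normal_lpdf(p$sigma_gamma, priors$scale_sd) +
    par$log_sigma + par$log_sigma_alpha + par$log_sigma_gamma  # Jacobians
  ll + lp
}

#' Pointwise log-likelihood matrix
#'
#' @param draws A `posterior_draws` (see [sample_posterior]).
#' @param data A `model_data`.
#' @param thin Keep every `thin`-th pooled draw (default 1).
#' @return Matrix draws x observations of log lognormal densities.
#' @export
pointwise_loglik <- function(draws, data, thin = 1) {
  m <- pooled_draws(draws)
  m <- m[seq(1, nrow(m), by = thin), , drop = FALSE]
  n <- length(data$y)
  out <- matrix(NA_real_, nrow(m), n)
  bcols <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second", "b_mix_second")
  acols <- paste0("alpha[", seq_len(data$n_tree), "]")
  gcols <- paste0("gamma[", seq_len(data$n_site), "]")
  for (s in seq_len(nrow(m))) {
    mu <- as.numeric(data$X %*% m[s, bcols]) +
      m[s, "sigma_alpha"] * m[s, acols][data$tree] +
      m[s, "sigma_gamma"] * m[s, gcols][data$site]
    out[s, ] <- stats::dlnorm(data$y, mu, m[s, "sigma"], log = TRUE)
  }
  out
}
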