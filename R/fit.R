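#' Posterior effect summaries
#'
#' Posterior mean with 66% and 95% credible intervals per top-level
#' parameter — the display convention for standardized effect plots.
#'
#' @param draws A `posterior_draws`.
#' @param pars Parameters to summarize (default: the nine top-level ones).
#' @return data.frame: parameter, mean, q17, q83, q2.5, q97.5.
#' @export
effect_summary <- function(draws, pars = NULL) {
  m <- pooled_draws(draws)
  if (is.null(pars))
    pars <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second",
              "b_mix_second", "sigma", "sigma_alpha", "sigma_gamma")
  rows <- lapply(pars, function(p) {
    v <- m[, p]
    data.frame(parameter = p, mean = mean(v),
               q17 = unname(stats::quantile(v, 0.17)),
               q83 = unname(stats::quantile(v, 0.83)),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)))
  })
  do.call(rbind, rows)
}

#' Predicted admixture-by-drought interaction surface
#'
#' Posterior predicted relative growth change over an admixture grid for
#' each drought event, with the other predictors held at their means
#' (z = 0) and varying effects at zero: the marginal mixture-effect curves.
#'
#' @param draws A `posterior_draws`.
#' @param data The fitted `model_data` (supplies the admixture scaling).
#' @param mix_pct Admixture grid in percent (default 0-100 by 5).
#' @return data.frame: drought_label, admixture_pct, mean, q2.5, q97.5
#'   (percent response).
#' @export
interaction_surface <- function(draws, data, mix_pct = seq(0, 100, 5)) {
  m <- pooled_draws(draws)
  ctr <- data$scaling$center["admixture_pct"]
  scl <- data$scaling$scale["admixture_pct"]
  z <- (mix_pct - ctr) / scl
  rows <- list()
  for (lab in c("first", "second")) {
    for (k in seq_along(z)) {
      mu <- m[, "b_mix"] * z[k] +
        (if (lab == "first") m[, "b_first"]
         else m[, "b_second"] + m[, "b_mix_second"] * z[k])
      pred <- 100 * exp(mu + m[, "sigma"]^2 / 2)  # log-normal mean, percent
      rows[[length(rows) + 1L]] <- data.frame(
        drought_label = lab, admixture_pct = mix_pct[k],
        mean = mean(pred),
        q2.5 = unname(stats::quantile(pred, 0.025)),
        q97.5 = unname(stats::quantile(pred, 0.975)))
    }
  }
  do.call(rbind, rows)
}

#' Fit the drought-response model for one species in one region
#'
#' Runs the full modelling stage: predictor standardization, collinearity
#' screening (VIF), posterior sampling, convergence diagnostics,
#' posterior predictive checking, Bayesian R-squared, and PSIS influence
#' flags, returning everything in one bundle.  Influential observations are
#' reported, never dropped automatically; refit after removal is an
#' explicit caller action.
#'
#' @param responses Rows of [drought_response_table] for one species x
#'   region (>= 10 trees across >= 2 sites).
#' @param config A [sampler_config].
#' @param priors A [prior_spec].
#' @param n_rep Posterior predictive replicates.
#' @param psis_thin Thinning for the pointwise log-likelihood.
#' @return A `species_fit` list: data, draws, vif, rhat, effects,
#'   interaction, ppc, r2, pareto.
#' @export
fit_species_model <- function(responses, config = sampler_config(),
                              priors = prior_spec(), n_rep = 200,
                              psis_thin = 4) {
  if (length(unique(responses$site)) < 2)
    stop("need >= 2 sites")
  if (length(unique(responses$tree_id)) < 10)
    stop("need >= 10 trees")
  data <- make_model_data(responses)
  v <- vif(cbind(data$X[, c("ci", "mix", "dbh")],
                 second = data$X[, "second"]))
  draws <- sample_posterior(data, priors, config)
  top <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second",
           "b_mix_second", "sigma", "sigma_alpha", "sigma_gamma")
  structure(
    list(data = data, draws = draws, vif = v,
         rhat = rhat(draws, top),
         effects = effect_summary(draws),
         interaction = interaction_surface(draws, data),
         ppc = posterior_predictive(draws, data, n_rep = n_rep,
                                    seed = config$seed),
         r2 = bayes_r2(draws, data),
         pareto = pareto_k(draws, data, thin = psis_thin)),
    class = "species_fit")
}

#' @export
print.species_fit <- function(x, ...) {
  cat("<species_fit>", length(x$data$y), "observations,",
      x$data$n_tree, "trees,", x$data$n_site, "sites\n")
  cat("max R-hat:", round(max(x$rhat, na.rm = TRUE), 4),
      "| mean Bayesian R2 (log scale):", round(mean(x$r2), 3),
      "| influential obs:", sum(x$pareto$flagged, na.rm = TRUE), "\n")
  print(x$effects, digits = 3)
  invisible(x)
}
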