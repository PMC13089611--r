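test_that("standardization round-trips and rejects constants", {
  set.seed(31)
  x <- cbind(a = stats::rnorm(50, 5, 2), b = stats::runif(50))
  sc <- standardize(x)
  expect_equal(unname(colMeans(sc$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$z, 2, stats::sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unstandardize(sc$z, sc), x, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(standardize(cbind(a = rep(1, 10), b = 1:10)), "zero-variance")
})

test_that("VIF matches its closed form and reports collinearity as Inf", {
  set.seed(32)
  n <- 200
  # columns exactly orthogonal to each other and to the intercept
  z <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 2), n, 2))))[, 2:3] * sqrt(n)
  colnames(z) <- c("p1", "p2")
  expect_equal(unname(vif(z)), c(1, 1), tolerance = 1e-10)
  # construct a pair with sample correlation exactly 0.8
  r <- 0.8
  x2 <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
  v <- vif(cbind(a = z[, 1], b = x2))
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  dup <- cbind(a = z[, 1], b = z[, 1], c = z[, 2])
  expect_true(any(is.infinite(vif(dup))))
})

test_that("the joint log-posterior matches an independent oracle to 1e-8", {
  for (k in 1:5) {
    data <- random_model_fixture(n = 10, seed = 300 + k)
    par <- random_par(data, 400 + k)
    expect_equal(log_posterior(par, data),
                 oracle_log_posterior(par, data), tolerance = 1e-8)
  }
  # closed-form single-observation check: y = 1, all parameters neutral
  data1 <- random_model_fixture(n = 4, seed = 99)
  data1$y <- rep(1, 4)
  par0 <- list(beta = rep(0, 6), alpha = rep(0, data1$n_tree),
               gamma = rep(0, data1$n_site), log_sigma = 0,
               log_sigma_alpha = 0, log_sigma_gamma = 0)
  ll_only <- log_posterior(par0, data1) -
    (sum(stats::dnorm(rep(0, 6), log = TRUE)) +
       sum(stats::dnorm(rep(0, data1$n_tree + data1$n_site), log = TRUE)) +
       3 * (0.5 * log(2 / pi) - 0.5))
  expect_equal(ll_only, 4 * (-0.5 * log(2 * pi)), tolerance = 1e-10)
})

test_that("scaling the responses obeys the log-normal change of variable", {
  # if Y ~ lognormal(mu, s), then 2Y ~ lognormal(mu + log 2, s):
  # shifting both drought-level coefficients by log 2 moves every mu by
  # log 2, so the likelihood drops by exactly n log 2 and only the prior
  # on those two coefficients changes
  data <- random_model_fixture(n = 12, seed = 77)
  par <- random_par(data, 78)
  lp1 <- log_posterior(par, data)
  data2 <- data; data2$y <- 2 * data$y
  par2 <- par; par2$beta[4:5] <- par$beta[4:5] + log(2)
  prior_delta <- sum(stats::dnorm(par2$beta[4:5], log = TRUE)) -
    sum(stats::dnorm(par$beta[4:5], log = TRUE))
  lp2 <- log_posterior(par2, data2)
  expect_equal(lp2 - lp1, -12 * log(2) + prior_delta, tolerance = 1e-10)
})

test_that("prior-only sampling reproduces the prior scales", {
  data <- random_model_fixture(n = 20, seed = 55)
  cfg <- sampler_config(chains = 4, iter = 2500, warmup = 500, seed = 3,
                        likelihood = FALSE)
  draws <- sample_posterior(data, config = cfg)
  m <- pooled_draws(draws)
  for (p in c("b_ci", "b_mix", "b_dbh", "b_first", "b_second",
              "b_mix_second")) {
    expect_lt(abs(stats::sd(m[, p]) - 1), 0.05)
    expect_lt(abs(mean(m[, p])), 0.05)
  }
  # half-normal(0,1) scales have mean sqrt(2/pi)
  expect_equal(mean(m[, "sigma"]), sqrt(2 / pi), tolerance = 0.03)
})

test_that("sampling is deterministic under a fixed seed", {
  data <- random_model_fixture(n = 16, seed = 56)
  cfg <- sampler_config(chains = 2, iter = 200, warmup = 50, seed = 42)
  d1 <- sample_posterior(data, config = cfg)
  d2 <- sample_posterior(data, config = cfg)
  expect_identical(d1$draws, d2$draws)
  # chain order does not change pooled summaries
  perm <- d1$draws[, 2:1, ]
  expect_equal(mean(perm[, , "b_mix"]), mean(d1$draws[, , "b_mix"]))
})

test_that("split-chain R-hat separates converged from divergent chains", {
  set.seed(60)
  iid <- matrix(stats::rnorm(4 * 2000), 2000, 4)
  r <- rhat(iid)
  expect_gt(r, 0.999); expect_lt(r, 1.01)
  apart <- cbind(stats::rnorm(1000, 0), stats::rnorm(1000, 5))
  expect_gt(rhat(apart), 1.5)
  flat <- cbind(rep(1, 100), rep(1, 100))
  expect_true(is.na(rhat(flat)))
})

test_that("a known interaction is recovered from synthetic data", {
  rs <- make_recovery_responses(3)
  oak <- rs[rs$species == "oak", ]
  fit <- fit_species_model(
    oak, config = sampler_config(chains = 4, iter = 1500, warmup = 500,
                                 seed = 5), n_rep = 100)
  expect_true(all(fit$vif < 3))
  es <- fit$effects
  tr <- truth_vector(truth_record())
  # interaction sign: majority posterior mass positive
  m <- pooled_draws(fit$draws)
  expect_gt(mean(m[, "b_mix_second"] > 0), 0.5)
  int <- es[es$parameter == "b_mix_second", ]
  expect_gt(tr[6], int$q2.5); expect_lt(tr[6], int$q97.5)
  expect_true(all(fit$rhat < 1.05, na.rm = TRUE))
  # posterior predictive self-consistency: observed mean inside the
  # central 95% of replicated means
  ppc <- fit$ppc$summary
  obs_mean <- ppc[ppc$stat == "mean", ]
  expect_gt(obs_mean$observed, obs_mean$rep_q025)
  expect_lt(obs_mean$observed, obs_mean$rep_q975)
})

test_that("Bayesian R2 tracks the generative variance share", {
  # a design where the variance components are well identified (many sites,
  # negligible tree effects: with two rows per tree the tree scale and the
  # residual scale are otherwise hard to separate), so the plug-in truth is
  # a fair yardstick
  tg <- make_fake_targets(150, seed = 91, n_site = 6)
  ev <- data.frame(label = c("first", "second"), year = c(2018L, 2022L))
  tr <- truth_record(sigma_alpha = 0.02)
  g <- simulate_growth(tg, 2010:2023, ev, truth = tr, seed = 92)
  resp <- merge(g$truth_responses,
                tg[, c("target_id", "dbh", "ci_overall", "admixture_pct")],
                by.x = "tree_id", by.y = "target_id")
  md <- make_model_data(resp)
  draws <- sample_posterior(md, config = sampler_config(
    chains = 2, iter = 1500, warmup = 500, seed = 93))
  gen_var <- stats::var(resp$mu)
  gen_r2 <- gen_var / (gen_var + tr$sigma^2)
  expect_lt(abs(mean(bayes_r2(draws, md)) - gen_r2), 0.05)
})

test_that("Bayesian R2 limits behave on handcrafted draws", {
  data <- random_model_fixture(n = 30, seed = 70)
  mk_draws <- function(beta, sigma) {
    pn <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second", "b_mix_second",
            "sigma", "sigma_alpha", "sigma_gamma",
            paste0("alpha[", seq_len(data$n_tree), "]"),
            paste0("gamma[", seq_len(data$n_site), "]"))
    arr <- array(0, dim = c(4, 2, length(pn)), dimnames = list(NULL, NULL, pn))
    for (j in 1:6) arr[, , j] <- beta[j]
    arr[, , "sigma"] <- sigma
    structure(list(draws = arr, n_tree = data$n_tree, n_site = data$n_site),
              class = "posterior_draws")
  }
  # sigma -> 0 with varying mu: R2 -> 1
  r2_hi <- bayes_r2(mk_draws(c(1, 1, 1, 0.5, -0.5, 0.3), 1e-8), data)
  expect_true(all(r2_hi > 0.999))
  # beta = 0, effects = 0: R2 = 0
  r2_lo <- bayes_r2(mk_draws(rep(0, 6), 0.5), data)
  expect_true(all(r2_lo == 0))
})

test_that("generalized Pareto shapes are recovered from known samples", {
  set.seed(81)
  ks <- replicate(10, {
    u <- stats::runif(400)
    x <- 1 * ((1 - u)^(-0.5) - 1) / 0.5    # GPD, shape 0.5, scale 1
    gpd_fit(x)$k
  })
  expect_true(all(abs(ks - 0.5) < 0.15))
  # bounded (uniform) exceedances imply a light tail
  set.seed(82)
  ku <- replicate(10, gpd_fit(stats::runif(400))$k)
  expect_true(all(ku < 0.3))
})

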