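# Shared fixtures built in code.

# Two-site / 60-trees-per-species design with known generative truth:
# the covariates come from simulated stands, the responses from the
# hierarchical log-normal generator.
make_recovery_responses <- function(seed, truth = truth_record()) {
  st1 <- simulate_stand(stand_config(seed = (seed * 31 + 1) %% 2147483647))
  st2 <- simulate_stand(stand_config(seed = (seed * 31 + 2) %% 2147483647))
  t1 <- st1$targets; t1$site <- "s1"; t1$target_id <- paste0("A", t1$target_id)
  t2 <- st2$targets; t2$site <- "s2"; t2$target_id <- paste0("B", t2$target_id)
  tg <- rbind(t1, t2)
  ev <- data.frame(label = c("first", "second"), year = c(2018L, 2022L))
  g <- simulate_growth(tg, 1975:2023, ev, truth = truth,
                       seed = (seed * 7 + 3) %% 2147483647)
  merge(g$truth_responses,
        tg[, c("target_id", "dbh", "ci_overall", "admixture_pct")],
        by.x = "tree_id", by.y = "target_id")
}

# A lightweight covariate table that skips the spatial simulation, for
# model-only tests.
make_fake_targets <- function(n, seed, n_site = 2) {
  set.seed(seed)
  data.frame(
    target_id = sprintf("T%04d", seq_len(n)),
    species = "oak",
    site = paste0("s", rep_len(seq_len(n_site), n)),
    dbh = stats::rlnorm(n, log(30), 0.3),
    ci_overall = stats::rlnorm(n, log(2), 0.5),
    admixture_pct = stats::runif(n, 0, 100))
}

truth_vector <- function(truth) {
  c(truth$beta_ci, truth$beta_mix, truth$beta_dbh, truth$beta_first,
    truth$beta_second, truth$beta_mix_second, truth$sigma,
    truth$sigma_alpha, truth$sigma_gamma)
}

top_params <- c("b_ci", "b_mix", "b_dbh", "b_first", "b_second",
                "b_mix_second", "sigma", "sigma_alpha", "sigma_gamma")

# Independent implementation of the joint posterior density used as the
# oracle for log_posterior: assembled term by term from normal densities,
# never calling the package's own helpers.
oracle_log_posterior <- function(par, data, beta_sd = 1, scale_sd = 1) {
  sig <- exp(par$log_sigma)
  sa <- exp(par$log_sigma_alpha)
  sg <- exp(par$log_sigma_gamma)
  mu <- as.numeric(data$X %*% par$beta) + sa * par$alpha[data$tree] +
    sg * par$gamma[data$site]
  ly <- log(data$y)
  ll <- sum(-0.5 * log(2 * pi) - log(sig) - (ly - mu)^2 / (2 * sig^2) - ly)
  lpn <- function(x, s) sum(-0.5 * log(2 * pi) - log(s) - x^2 / (2 * s^2))
  lhn <- function(x, s) log(2) + (-0.5 * log(2 * pi) - log(s) - x^2 / (2 * s^2))
  ll + lpn(par$beta, beta_sd) + lpn(par$alpha, 1) + lpn(par$gamma, 1) +
    lhn(sig, scale_sd) + lhn(sa, scale_sd) + lhn(sg, scale_sd) +
    par$log_sigma + par$log_sigma_alpha + par$log_sigma_gamma
}

random_model_fixture <- function(n, seed) {
  set.seed(seed)
  n_tree <- ceiling(n / 2)
  resp <- data.frame(
    tree_id = rep(sprintf("T%02d", seq_len(n_tree)), each = 2)[seq_len(n)],
    site = rep(c("s1", "s2"), length.out = n),
    drought_label = rep(c("first", "second"), length.out = n),
    response_pct = stats::rlnorm(n, log(70), 0.4),
    dbh = stats::rlnorm(n, log(30), 0.2),
    ci_overall = stats::rlnorm(n, log(2), 0.4),
    admixture_pct = stats::runif(n, 0, 100))
  # a tree's covariates and site must be constant across its rows
  for (col in c("site", "dbh", "ci_overall", "admixture_pct"))
    resp[[col]] <- stats::ave(resp[[col]], resp$tree_id, FUN = function(v) v[1])
  make_model_data(resp)
}

random_par <- function(data, seed) {
  set.seed(seed)
  list(beta = stats::rnorm(6, 0, 0.5),
       alpha = stats::rnorm(data$n_tree),
       gamma = stats::rnorm(data$n_site),
       log_sigma = stats::rnorm(1, -1, 0.3),
       log_sigma_alpha = stats::rnorm(1, -1.5, 0.4),
       log_sigma_gamma = stats::rnorm(1, -1.5, 0.4))
}
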