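#' Stand generator configuration
#'
#' Defaults emulate a two-species mixed stand sampled along a three-category
#' admixture gradient: 10 target trees per category per species, a clumped
#' species (Thomas cluster process) against a uniformly dispersed one, and
#' log-normal dbh distributions.
#'
#' @param species Two species labels (first one is the clumped species in
#'   clustered mode).
#' @param n_per_category Target trees per admixture category per species.
#' @param mode `"clustered"` or `"uniform"` spatial structure.
#' @param extent Square plot side length in m.
#' @param density Stems per ha per species.
#' @param dbh_meanlog,dbh_sdlog Log-normal dbh parameters per species (cm).
#' @param cluster_parents Thomas parent intensity (per ha) for the clumped
#'   species.
#' @param cluster_sd Gaussian offspring dispersion (m).
#' @param seed RNG seed.
#' @param max_retries Stand regenerations allowed before giving up on the
#'   admixture-category quota.
#' @return A `stand_config` list.
#' @export
stand_config <- function(species = c("oak", "pine"), n_per_category = 10,
                         mode = c("clustered", "uniform"), extent = 180,
                         density = c(450, 350),
                         dbh_meanlog = log(c(28, 34)),
                         dbh_sdlog = c(0.35, 0.25),
                         cluster_parents = 12, cluster_sd = 4,
                         seed = 1, max_retries = 25) {
  mode <- match.arg(mode)
  stopifnot(length(species) == 2, n_per_category > 0, extent > 14)
  structure(list(species = species, n_per_category = n_per_category,
                 mode = mode, extent = extent, density = density,
                 dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
                 cluster_parents = cluster_parents, cluster_sd = cluster_sd,
                 seed = as.integer(seed), max_retries = max_retries),
            class = "stand_config")
}

# Thomas cluster process in a square window (points per m^2 via expected
# total = density; parents uniform, offspring Gaussian around parents).
rthomas <- function(extent, n_expected, parents_per_ha, cluster_sd) {
  area_ha <- extent^2 / 1e4
  n_par <- stats::rpois(1, max(parents_per_ha * area_ha, 1))
  if (n_par == 0) n_par <- 1
  px <- stats::runif(n_par, 0, extent); py <- stats::runif(n_par, 0, extent)
  per_cluster <- n_expected / n_par
  xs <- ys <- numeric(0)
  for (i in seq_len(n_par)) {
    k <- stats::rpois(1, per_cluster)
    if (k == 0) next
    xs <- c(xs, stats::rnorm(k, px[i], cluster_sd))
    ys <- c(ys, stats::rnorm(k, py[i], cluster_sd))
  }
  keep <- xs >= 0 & xs <= extent & ys >= 0 & ys <= extent
  cbind(x = xs[keep], y = ys[keep])
}

simulate_stand_once <- function(config) {
  ext <- config$extent
  area_ha <- ext^2 / 1e4
  pts <- list()
  for (si in 1:2) {
    n_exp <- config$density[si] * area_ha
    xy <- if (config$mode == "clustered" && si == 1)
      rthomas(ext, n_exp, config$cluster_parents, config$cluster_sd)
    else {
      n <- stats::rpois(1, n_exp)
      cbind(x = stats::runif(n, 0, ext), y = stats::runif(n, 0, ext))
    }
    dbh <- pmax(stats::rlnorm(nrow(xy), config$dbh_meanlog[si],
                              config$dbh_sdlog[si]), 1)
    pts[[si]] <- data.frame(x = xy[, 1], y = xy[, 2],
                            species = config$species[si], dbh = dbh)
  }
  trees <- do.call(rbind, pts)
  trees$id <- seq_len(nrow(trees))
  trees
}

neighborhood_of <- function(trees, i, radius = 7) {
  t0 <- trees[i, ]
  d <- sqrt((trees$x - t0$x)^2 + (trees$y - t0$y)^2)
  sel <- which(d > 0 & d <= radius & trees$id != t0$id)
  data.frame(species = trees$species[sel], dbh_cm = trees$dbh[sel],
             distance_m = d[sel], dead = rep(FALSE, length(sel)))
}

#' Simulate a stem-mapped stand with an admixture gradient
#'
#' Generates tree positions (Thomas cluster process for the clumped species,
#' homogeneous Poisson for the dispersed one), assigns log-normal dbh,
#' computes each candidate's 7-m neighbourhood, and selects
#' `n_per_category` target trees per admixture category per species
#' (categories from the realized competition-based admixture).  If a
#' category quota cannot be met the whole stand is regenerated up to
#' `max_retries` times before an error.
#'
#' @param config A [stand_config].
#' @return List: `records` (named [neighborhood_record] list for the
#'   targets), `targets` (data.frame with coordinates, dbh, CI, admixture
#'   and category), `trees` (the full stem map).
#' @export
simulate_stand <- function(config = stand_config()) {
  set.seed(config$seed)
  for (attempt in seq_len(config$max_retries)) {
    trees <- simulate_stand_once(config)
    buffer <- 7
    cand <- which(trees$x >= buffer & trees$x <= config$extent - buffer &
                    trees$y >= buffer & trees$y <= config$extent - buffer &
                    trees$dbh >= 10)
    info <- lapply(cand, function(i) {
      nb <- neighborhood_of(trees, i)
      rec <- neighborhood_record(paste0("T", i), trees$species[i],
                                 trees$dbh[i], nb)
      ci_all <- hegyi_ci(rec, "all")
      if (ci_all <= 0) return(NULL)
      adm <- min(max(100 * hegyi_ci(rec, "interspecific") / ci_all, 0), 100)
      list(rec = rec, row = data.frame(
        id = i, species = trees$species[i], dbh = trees$dbh[i],
        x = trees$x[i], y = trees$y[i], ci_overall = ci_all,
        admixture_pct = adm,
        category = as.character(admixture_category(adm))))
    })
    info <- info[!vapply(info, is.null, logical(1))]
    tab <- do.call(rbind, lapply(info, `[[`, "row"))
    cats <- levels(admixture_category(0))
    chosen <- integer(0)
    ok <- TRUE
    for (sp in config$species) for (cc in cats) {
      pool <- which(tab$species == sp & tab$category == cc)
      if (length(pool) < config$n_per_category) { ok <- FALSE; break }
      chosen <- c(chosen, sample(pool, config$n_per_category))
    }
    if (!ok) next
    sel <- info[chosen]
    targets <- do.call(rbind, lapply(sel, `[[`, "row"))
    targets$target_id <- sprintf("%s%02d",
                                 toupper(substr(targets$species, 1, 1)),
                                 stats::ave(seq_len(nrow(targets)),
                                            targets$species, FUN = seq_along))
    records <- lapply(seq_along(sel), function(k) {
      r <- sel[[k]]$rec
      r$target_id <- targets$target_id[k]
      r
    })
    names(records) <- targets$target_id
    rownames(targets) <- NULL
    return(list(records = records, targets = targets, trees = trees))
  }
  stop("could not meet the admixture-category quota after ",
       config$max_retries, " stand regenerations; enlarge the extent or ",
       "adjust densities")
}

#' Simulate monthly site climate with designated drought years
#'
#' Seasonal sinusoidal temperature normals and stochastic monthly
#' precipitation; in configured drought years the growing-season months get
#' suppressed precipitation and a widened diurnal temperature range (raised
#' maxima), pushing the water-balance window sums into the lower tail so
#' that the SPEI pipeline flags exactly those years.
#'
#' @param years Integer year range (>= 30 years for stable SPEI fitting).
#' @param drought_years Years to force dry.
#' @param seed RNG seed.
#' @param latitude Site latitude (deg).
#' @param site Site label.
#' @param drought_months Months forced in drought years (default 3:8).
#' @param prcp_factor Multiplier on drought-month precipitation.
#' @param temp_boost Added to drought-month maximum temperature (degC).
#' @return A [climate_table].
#' @export
simulate_climate <- function(years, drought_years = integer(), seed = 1,
                             latitude = 48, site = "site1",
                             drought_months = 3:8, prcp_factor = 0.35,
                             temp_boost = 3) {
  stopifnot(length(years) >= 30)
  set.seed(seed)
  grid <- expand.grid(month = 1:12, year = years)
  m <- grid$month
  tmean <- 9 - 9.5 * cos(2 * pi * (m - 1) / 12) + stats::rnorm(nrow(grid), 0, 0.8)
  range_half <- 4.5 + stats::rnorm(nrow(grid), 0, 0.3)
  # monthly precipitation is right-skewed; gamma(4, 18) gives mean 72 mm
  prcp <- stats::rgamma(nrow(grid), shape = 4, scale = 18)
  dry <- grid$year %in% drought_years & m %in% drought_months
  prcp[dry] <- prcp[dry] * prcp_factor
  tmax <- tmean + abs(range_half)
  tmax[dry] <- tmax[dry] + temp_boost
  tmean[dry] <- tmean[dry] + temp_boost / 2
  tmin <- 2 * tmean - tmax   # keeps tmean centred between tmin and tmax
  climate_table(
    data.frame(year = grid$year, month = m, prcp_mm = prcp,
               tmean_c = tmean, tmin_c = tmin, tmax_c = tmax),
    site = site, latitude = latitude)
}

#' Ground-truth parameter record for the growth generator
#'
#' Generative values of every model parameter, stored alongside simulated
#' data so that fits can be checked against the truth.
#'
#' @param beta_ci,beta_mix,beta_dbh Standardized covariate effects (log
#'   scale).
#' @param beta_first,beta_second Drought-timing levels on the log
#'   response-ratio scale (-0.29 is about a 75% response, -0.51 about 60%).
#' @param beta_mix_second Admixture-by-second-drought interaction.
#' @param sigma Residual SD (log scale).
#' @param sigma_alpha,sigma_gamma Tree and site effect scales.
#' @param ar1 Lag-1 autocorrelation of the baseline growth index.
#' @param rwi_sd Marginal SD of the baseline growth index.
#' @param common_share Fraction of baseline index variance shared by all
#'   trees of a site (the common year-to-year signal that gives chronologies
#'   their inter-series correlation).
#' @return A `truth_record` list.
#' @export
truth_record <- function(beta_ci = -0.05, beta_mix = 0.10, beta_dbh = -0.05,
                         beta_first = -0.29, beta_second = -0.51,
                         beta_mix_second = 0.30, sigma = 0.30,
                         sigma_alpha = 0.15, sigma_gamma = 0.20,
                         ar1 = 0.6, rwi_sd = 0.15, common_share = 0.5) {
  stopifnot(sigma > 0, sigma_alpha > 0, sigma_gamma > 0, abs(ar1) < 1,
            common_share >= 0, common_share < 1)
  structure(list(beta_ci = beta_ci, beta_mix = beta_mix, beta_dbh = beta_dbh,
                 beta_first = beta_first, beta_second = beta_second,
                 beta_mix_second = beta_mix_second, sigma = sigma,
                 sigma_alpha = sigma_alpha, sigma_gamma = sigma_gamma,
                 ar1 = ar1, rwi_sd = rwi_sd, common_share = common_share),
            class = "truth_record")
}

# Stationary AR(1) around 1 with marginal sd `sd`.
ar1_series <- function(n, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  1 + x
}

#' Simulate per-tree growth indices with known drought responses
#'
#' Baseline ring-width indices follow a stationary AR(1) around 1.  For each
#' drought event, the tree's response ratio y (percent) is drawn from the
#' hierarchical log-normal model — standardized covariates (within species
#' and site set), drought-timing levels, the admixture-by-second-drought
#' interaction, and non-centred tree-in-site effects — and the drought-year
#' index is set to (y/100) times the mean index of the two preceding years,
#' so that the pipeline's response extraction recovers y exactly.
#'
#' @param targets Target table from [simulate_stand] with a `site` column.
#' @param years Year range of the growth series.
#' @param events data.frame: label ("first"/"second"), year.
#' @param truth A [truth_record].
#' @param seed RNG seed.
#' @param pre_window Pre-drought averaging window (years).
#' @return List: `rwi` (named `rwi_series` list), `truth_responses`
#'   (tree x event table with the exact generative response and linear
#'   predictor), `effects` (drawn tree and site effects), `truth`.
#' @export
simulate_growth <- function(targets, years, events, truth = truth_record(),
                            seed = 1, pre_window = 2) {
  set.seed(seed)
  stopifnot(all(events$year %in% years),
            all(events$year - pre_window >= min(years)))
  n <- nrow(targets)
  if (is.null(targets$site)) targets$site <- "site1"
  sites <- sort(unique(targets$site))
  gamma_s <- stats::rnorm(length(sites))
  alpha_t <- stats::rnorm(n)
  # standardize covariates within species (models are fitted per species)
  z <- matrix(NA_real_, n, 3,
              dimnames = list(NULL, c("ci", "mix", "dbh")))
  for (sp in unique(targets$species)) {
    idx <- targets$species == sp
    z[idx, ] <- standardize(targets[idx, c("ci_overall", "admixture_pct",
                                           "dbh")])$z
  }
  # shared year-to-year growth signal per site (common climate forcing)
  sd_common <- truth$rwi_sd * sqrt(truth$common_share)
  sd_idio <- truth$rwi_sd * sqrt(1 - truth$common_share)
  common <- lapply(sites, function(s)
    ar1_series(length(years), truth$ar1, max(sd_common, 1e-12)) - 1)
  names(common) <- sites
  rwi <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    x <- ar1_series(length(years), truth$ar1, max(sd_idio, 1e-12)) +
      common[[targets$site[i]]]
    names(x) <- years
    for (k in seq_len(nrow(events))) {
      ev_year <- events$year[k]
      lab <- events$label[k]
      mu <- truth$beta_ci * z[i, "ci"] + truth$beta_mix * z[i, "mix"] +
        truth$beta_dbh * z[i, "dbh"] +
        (if (lab == "second") truth$beta_second else truth$beta_first) +
        (if (lab == "second") truth$beta_mix_second * z[i, "mix"] else 0) +
        truth$sigma_alpha * alpha_t[i] +
        truth$sigma_gamma * gamma_s[match(targets$site[i], sites)]
      ratio <- stats::rlnorm(1, mu, truth$sigma)   # mu on the log-ratio scale
      pre_years <- (ev_year - pre_window):(ev_year - 1)
      pre_mean <- mean(x[as.character(pre_years)])
      x[as.character(ev_year)] <- ratio * pre_mean
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        tree_id = targets$target_id[i], site = targets$site[i],
        species = targets$species[i], drought_label = lab,
        drought_year = ev_year, response_pct = 100 * ratio, mu = mu)
    }
    rwi[[targets$target_id[i]]] <- structure(
      list(tree_id = targets$target_id[i], years = years,
           rwi = unname(x), fitted = rep(1, length(years))),
      class = "rwi_series")
  }
  list(rwi = rwi, truth_responses = do.call(rbind, truth_rows),
       effects = list(alpha = alpha_t, gamma = gamma_s, sites = sites),
       truth = truth)
}
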