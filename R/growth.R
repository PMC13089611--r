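#' Convert a ring-width series to basal-area increments
#'
#' Annual basal-area increment bai_t = pi * (r_t^2 - r_{t-1}^2) in cm^2,
#' where r is the stem radius at breast height.  Two radius anchors are
#' supported.  `"outside-in"` (default) pins the final radius to `dbh / 2`
#' and reconstructs earlier radii by subtracting the measured widths, which
#' respects the tree's measured size; `"inside-out"` starts from r = 0 and
#' accumulates widths, which is exact for complete-to-pith series.
#'
#' @param tree A `tree_series` (see [merge_cores]) or any list with fields
#'   `years` and `width_mm`.
#' @param dbh Diameter at breast height in cm (required for outside-in).
#' @param mode `"outside-in"` or `"inside-out"`.
#' @return A `bai_series`: tree_id, years, bai (cm^2 yr^-1).
#' @export
to_bai <- function(tree, dbh = NULL, mode = c("outside-in", "inside-out")) {
  mode <- match.arg(mode)
  w_cm <- tree$width_mm / 10                       # ring widths in cm
  n <- length(w_cm)
  if (mode == "inside-out") {
    r <- cumsum(w_cm)
    r_prev <- c(0, r[-n])
  } else {
    if (is.null(dbh) || !is.finite(dbh) || dbh <= 0)
      stop("outside-in anchoring needs a positive dbh (cm)")
    r_final <- dbh / 2
    r <- r_final - rev(cumsum(rev(w_cm))) + w_cm   # radius at the end of year t
    r_prev <- r - w_cm
    if (any(r_prev < -1e-9)) {
      bad <- tree$years[which(r_prev < -1e-9)[1]]
      stop("outside-in anchor produces a negative interior radius in year ",
           bad, "; dbh smaller than cumulative width")
    }
    r_prev <- pmax(r_prev, 0)
  }
  structure(
    list(tree_id = tree$tree_id, years = tree$years,
         bai = pi * (r^2 - r_prev^2)),
    class = "bai_series")
}

# Second-difference penalized smoother (discrete cubic smoothing spline).
# The frequency response of the penalized fit is H(f) = 1/(1 + lambda *
# (2 sin(pi f))^4); choosing lambda = (2 sin(pi / cutoff))^-4 puts 50%
# amplitude at wavelength `cutoff` years.
smoothing_spline_fit <- function(x, cutoff_years) {
  n <- length(x)
  lambda <- (2 * sin(pi / cutoff_years))^-4
  D <- diff(diag(n), differences = 2)              # (n-2) x n
  A <- diag(n) + lambda * crossprod(D)
  as.numeric(solve(A, x))
}

#' Detrend a growth series to dimensionless ring-width indices
#'
#' Fits a cubic smoothing spline whose frequency response passes 50% at the
#' given wavelength and divides the observed values by the fitted curve
#' (ratio detrending), yielding indices with mean approximately 1.
#'
#' @param values Numeric growth values (ring width or BAI), all finite.
#' @param years Matching consecutive calendar years.
#' @param cutoff_years Wavelength (years) at which the spline's amplitude
#'   response is 0.5; default 30.
#' @param tree_id Identifier carried into the result.
#' @return An `rwi_series`: tree_id, years, rwi, fitted.
#' @export
detrend_spline <- function(values, years = seq_along(values),
                           cutoff_years = 30, tree_id = NA_character_) {
  if (inherits(values, "bai_series")) {
    tree_id <- values$tree_id; years <- values$years; values <- values$bai
  } else if (inherits(values, "tree_series")) {
    tree_id <- values$tree_id; years <- values$years; values <- values$width_mm
  }
  n <- length(values)
  if (n < 15) stop("series too short to detrend (< 15 years)")
  if (any(!is.finite(values))) stop("non-finite growth values")
  fitted <- smoothing_spline_fit(values, cutoff_years)
  floor_val <- max(mean(abs(values)) * 1e-4, .Machine$double.eps)
  fitted <- pmax(fitted, floor_val)
  if (all(fitted <= floor_val))
    stop("degenerate spline fit: fitted curve not positive")
  structure(
    list(tree_id = tree_id, years = years, rwi = values / fitted,
         fitted = fitted),
    class = "rwi_series")
}

# Tukey's biweight robust location, tuning constant c = 9, MAD scale.
tukey_biweight <- function(x, c = 9, tol = 1e-8, max_iter = 50) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- stats::median(x)
  for (i in seq_len(max_iter)) {
    s <- stats::median(abs(x - m))
    if (s <= .Machine$double.eps) return(m)
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol * (1 + abs(m))) return(m_new)
    m <- m_new
  }
  m
}

#' Build a site x species chronology by robust averaging
#'
#' Per year, the chronology index is Tukey's biweight robust mean (tuning
#' constant 9, median-absolute-deviation scale) of the ring-width indices of
#' all series covering that year; with fewer than four contributing series
#' the arithmetic mean is used instead.
#'
#' @param rwi_set List of `rwi_series`.
#' @param site,species Labels stored on the chronology.
#' @return A `chronology`: site, species, years, index, sample_depth.
#' @export
build_chronology <- function(rwi_set, site = NA_character_,
                             species = NA_character_) {
  stopifnot(length(rwi_set) >= 1L)
  yr_min <- min(vapply(rwi_set, function(s) s$years[1], numeric(1)))
  yr_max <- max(vapply(rwi_set, function(s) s$years[length(s$years)], numeric(1)))
  years <- yr_min:yr_max
  mat <- matrix(NA_real_, nrow = length(years), ncol = length(rwi_set))
  for (j in seq_along(rwi_set)) {
    s <- rwi_set[[j]]
    mat[match(s$years, years), j] <- s$rwi
  }
  depth <- rowSums(!is.na(mat))
  if (all(depth == 0L)) stop("no series cover any year")
  index <- rep(NA_real_, length(years))
  for (i in seq_along(years)) {
    v <- mat[i, !is.na(mat[i, ])]
    if (length(v) == 0L) next
    index[i] <- if (length(v) < 4) mean(v) else tukey_biweight(v)
  }
  keep <- depth >= 1L
  structure(
    list(site = site, species = species, years = years[keep],
         index = index[keep], sample_depth = as.integer(depth[keep])),
    class = "chronology")
}

# Overlapping-year pairs among a set of rwi series, with a minimum overlap.
overlap_pairs <- function(rwi_set, min_overlap) {
  n <- length(rwi_set)
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    yi <- rwi_set[[i]]$years; yj <- rwi_set[[j]]$years
    common <- intersect(yi, yj)
    if (length(common) >= min_overlap)
      pairs[[length(pairs) + 1L]] <- list(
        i = i, j = j,
        xi = rwi_set[[i]]$rwi[match(common, yi)],
        xj = rwi_set[[j]]$rwi[match(common, yj)])
  }
  pairs
}

#' Mean inter-series correlation (rbar)
#'
#' Mean of the Pearson correlations over all series pairs whose common
#' period is at least `min_overlap` years, each correlation computed on
#' that pair's overlap.
#'
#' @param rwi_set List of `rwi_series` (>= 2).
#' @param min_overlap Minimum pairwise overlap in years (default 20).
#' @return Scalar rbar.
#' @export
interseries_rbar <- function(rwi_set, min_overlap = 20) {
  stopifnot(length(rwi_set) >= 2L)
  pairs <- overlap_pairs(rwi_set, min_overlap)
  if (length(pairs) == 0L)
    stop("no series pair overlaps by at least ", min_overlap, " years")
  mean(vapply(pairs, function(p) stats::cor(p$xi, p$xj), numeric(1)))
}

#' Expressed population signal (EPS)
#'
#' eps = n * rbar / (n * rbar + (1 - rbar)): how well a chronology of n
#' series represents the hypothetical population chronology.
#'
#' @param rbar Mean inter-series correlation in [0, 1].
#' @param n Number of series (>= 1).
#' @return Scalar in [0, 1].
#' @export
eps <- function(rbar, n) {
  if (any(rbar < 0))
    stop("rbar < 0 is outside the EPS domain (raw value: ", rbar, ")")
  stopifnot(all(rbar <= 1), all(n >= 1))
  n * rbar / (n * rbar + (1 - rbar))
}

#' Gleichlaeufigkeit (sign-agreement) of a set of series
#'
#' For each qualifying pair, year-to-year first differences are reduced to
#' signs and scored 1 - |s1 - s2| / 2 (equal signs score 1, opposite signs 0,
#' a zero difference against a non-zero one 0.5); the pair value is the mean
#' score and the set value the mean over pairs.
#'
#' @inheritParams interseries_rbar
#' @return Scalar in [0, 1].
#' @export
glk <- function(rwi_set, min_overlap = 20) {
  stopifnot(length(rwi_set) >= 2L)
  pairs <- overlap_pairs(rwi_set, min_overlap)
  if (length(pairs) == 0L)
    stop("no series pair overlaps by at least ", min_overlap, " years")
  glk_pair <- function(p) {
    s1 <- sign(diff(p$xi)); s2 <- sign(diff(p$xj))
    mean(1 - abs(s1 - s2) / 2)
  }
  mean(vapply(pairs, glk_pair, numeric(1)))
}

#' Sample autocorrelation of a growth series at lags 1..max_lag
#'
#' @param series An `rwi_series` or numeric vector.
#' @param max_lag Highest lag.
#' @return Named numeric vector of autocorrelations.
#' @export
lag_autocorrelation <- function(series, max_lag = 2) {
  x <- if (inherits(series, "rwi_series")) series$rwi else as.numeric(series)
  if (length(x) <= max_lag + 10)
    stop("series too short for max_lag = ", max_lag)
  if (stats::sd(x) <= .Machine$double.eps)
    stop("constant series: autocorrelation undefined")
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  stats::setNames(as.numeric(ac), paste0("lag", seq_len(max_lag)))
}

#' Chronology summary statistics table
#'
#' One row per chronology: series count, span with at least `min_depth`
#' series, mean basal-area increment, rbar, glk and eps — the conventional
#' descriptive table for site chronologies.
#'
#' @param rwi_sets Named list; each element a list of `rwi_series` for one
#'   site x species chronology.
#' @param bai_sets Optional matching named list of `bai_series` lists used
#'   for the mean BAI column (mean over trees of per-tree means within
#'   `bai_period`).
#' @param meta Optional data.frame with columns `label`, `site`, `species`,
#'   `dbh_mean`, `dbh_sd` matched by names of `rwi_sets`.
#' @param min_depth Sample depth defining the reported period (default 5).
#' @param min_overlap Passed to [interseries_rbar] and [glk].
#' @param bai_period Optional year range c(from, to) for the BAI summary.
#' @return data.frame with one row per chronology.
#' @export
chronology_stats <- function(rwi_sets, bai_sets = NULL, meta = NULL,
                             min_depth = 5, min_overlap = 20,
                             bai_period = NULL) {
  rows <- lapply(names(rwi_sets), function(lab) {
    rs <- rwi_sets[[lab]]
    chron <- build_chronology(rs)
    ok <- chron$sample_depth >= min_depth
    period <- if (any(ok))
      paste0(min(chron$years[ok]), "-", max(chron$years[ok])) else NA_character_
    rb <- interseries_rbar(rs, min_overlap)
    bai_mean <- bai_sd <- NA_real_
    if (!is.null(bai_sets) && !is.null(bai_sets[[lab]])) {
      per_tree <- vapply(bai_sets[[lab]], function(b) {
        sel <- if (is.null(bai_period)) rep(TRUE, length(b$years))
               else b$years >= bai_period[1] & b$years <= bai_period[2]
        mean(b$bai[sel])
      }, numeric(1))
      bai_mean <- mean(per_tree); bai_sd <- stats::sd(per_tree)
    }
    data.frame(label = lab, n = length(rs), period = period,
               bai_mean = bai_mean, bai_sd = bai_sd,
               rbar = rb, glk = glk(rs, min_overlap),
               eps = eps(rb, length(rs)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) out <- merge(meta, out, by = "label", sort = FALSE)
  out
}
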