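#' Monthly climate table constructor / validator
#'
#' @param df data.frame with columns year, month, prcp_mm, tmean_c, tmin_c,
#'   tmax_c (monthly precipitation in mm, temperatures in degrees C).
#' @param site Site label.
#' @param latitude Site latitude in decimal degrees.
#' @return The validated data.frame with attributes `site` and `latitude`,
#'   class `climate_table`.
#' @export
climate_table <- function(df, site = NA_character_, latitude) {
  need <- c("year", "month", "prcp_mm", "tmean_c", "tmin_c", "tmax_c")
  if (!all(need %in% names(df)))
    stop("climate table needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$year, df$month), need]
  if (any(df$tmin_c > df$tmean_c + 1e-9) || any(df$tmean_c > df$tmax_c + 1e-9))
    stop("temperature ordering violated (need tmin <= tmean <= tmax)")
  idx <- df$year * 12 + df$month
  if (any(diff(idx) != 1L))
    stop("months are not consecutive / record has gaps")
  attr(df, "site") <- site
  attr(df, "latitude") <- latitude
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Read a climate CSV (year, month, prcp_mm, tmean_c, tmin_c, tmax_c)
#' @param path CSV file path.
#' @param site,latitude Passed to [climate_table].
#' @export
read_climate_csv <- function(path, site = NA_character_, latitude) {
  climate_table(utils::read.csv(path), site = site, latitude = latitude)
}

# Daily extraterrestrial radiation (FAO-56), MJ m^-2 day^-1.
ra_day_mj <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(pmax(x, -1), 1))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

MID_MONTH_DOY <- c(15, 46, 75, 105, 136, 166, 197, 228, 258, 289, 319, 350)
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Extraterrestrial radiation for a month
#'
#' FAO-56 daily extraterrestrial radiation evaluated at the mid-month day,
#' returned in evaporation-equivalent mm per day (1 MJ m^-2 day^-1 = 0.408
#' mm day^-1).
#'
#' @param latitude Decimal degrees, |latitude| < 66.5 (no polar day/night).
#' @param month Month 1-12.
#' @return Ra in mm day^-1.
#' @export
extraterrestrial_radiation <- function(latitude, month) {
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes (|lat| >= 66.5) unsupported")
  stopifnot(all(month %in% 1:12))
  0.408 * ra_day_mj(latitude, MID_MONTH_DOY[month])
}

#' Monthly potential evapotranspiration by the Hargreaves equation
#'
#' PET = 0.0023 * Ra * (tmean + 17.8) * sqrt(tmax - tmin) per day, summed
#' over the days of the month and floored at zero.
#'
#' @param table A [climate_table].
#' @return data.frame year, month, pet_mm.
#' @export
hargreaves_pet <- function(table) {
  lat <- attr(table, "latitude")
  if (is.null(lat)) stop("climate table lacks a latitude attribute")
  if (any(table$tmax_c < table$tmin_c)) {
    bad <- which(table$tmax_c < table$tmin_c)[1]
    stop(sprintf("tmax < tmin at year %d month %d", table$year[bad],
                 table$month[bad]))
  }
  ra <- extraterrestrial_radiation(lat, table$month)
  pet_day <- 0.0023 * ra * (table$tmean_c + 17.8) * sqrt(table$tmax_c - table$tmin_c)
  pet <- pmax(pet_day, 0) * DAYS_IN_MONTH[table$month]
  data.frame(year = table$year, month = table$month, pet_mm = pet)
}

#' Monthly climatic water balance D = P - PET
#'
#' @param table A [climate_table].
#' @param pet Output of [hargreaves_pet] aligned to the same months.
#' @return data.frame year, month, d_mm.
#' @export
water_balance <- function(table, pet = hargreaves_pet(table)) {
  if (nrow(pet) != nrow(table) ||
      any(pet$year != table$year) || any(pet$month != table$month))
    stop("climate table and PET are not aligned month-by-month")
  data.frame(year = table$year, month = table$month,
             d_mm = table$prcp_mm - pet$pet_mm)
}

# Unbiased probability-weighted moments b0, b1, b2 of a sample.
pwm_unbiased <- function(x) {
  x <- sort(x); n <- length(x); j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  c(b0, b1, b2)
}

# 3-parameter log-logistic fit by PWM (shape beta, scale alpha, location gam).
# CDF: F(x) = (1 + (alpha / (x - gam))^beta)^-1 for x > gam.
loglogistic_pwm <- function(x) {
  b <- pwm_unbiased(x)
  l2 <- 2 * b[2] - b[1]                 # second and third L-moments
  l3 <- 6 * b[3] - 6 * b[2] + b[1]
  beta <- l2 / l3
  if (!is.finite(beta) || beta <= 1.02)  # Gamma(1 - 1/beta) must exist
    stop("log-logistic PWM fit failed: shape <= 1")
  g1 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- l2 * beta / g1
  gam <- b[1] - alpha * g1
  list(beta = beta, alpha = alpha, gam = gam)
}

loglogistic_cdf <- function(x, fit) {
  p <- numeric(length(x))
  above <- x > fit$gam
  p[above] <- 1 / (1 + (fit$alpha / (x[above] - fit$gam))^fit$beta)
  p[!above] <- 0
  p
}

# Standard-normal quantile by the Abramowitz-Stegun rational approximation,
# the conventional standardization step for SPEI.
as_norm_quantile <- function(p) {
  c0 <- 2.515517; c1 <- 0.802853; c2 <- 0.010328
  d1 <- 1.432788; d2 <- 0.189269; d3 <- 0.001308
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lower <- p <= 0.5
  pp <- ifelse(lower, p, 1 - p)
  w <- sqrt(-2 * log(pp))
  z <- w - (c0 + c1 * w + c2 * w^2) / (1 + d1 * w + d2 * w^2 + d3 * w^3)
  ifelse(lower, -z, z)
}

# Aggregate monthly water balance into annual sums over a window of
# `window_months` months ending at `end_month` (window may reach into the
# previous calendar year).
window_sums <- function(D, window_months, end_month) {
  idx_end <- D$year * 12 + D$month
  years <- sort(unique(D$year))
  out <- data.frame(year = years, sum = NA_real_)
  for (k in seq_along(years)) {
    end_idx <- years[k] * 12 + end_month
    want <- (end_idx - window_months + 1):end_idx
    pos <- match(want, idx_end)
    if (any(is.na(pos))) next
    out$sum[k] <- sum(D$d_mm[pos])
  }
  out[!is.na(out$sum), ]
}

#' Standardized Precipitation-Evapotranspiration Index
#'
#' Sums the monthly climatic water balance over a window of
#' `window_months` months ending at `end_month` of each year (a 12-month
#' window ending in July covers previous-year August through current July),
#' fits a 3-parameter log-logistic distribution to the reference-period sums
#' by unbiased probability-weighted moments, and maps each year's sum through
#' the fitted CDF and the standard-normal quantile (Abramowitz-Stegun
#' approximation), giving one standardized value per year.
#'
#' If the fitted location exceeds the smallest reference sum the parametric
#' fit is rejected and the series falls back to empirical plotting-position
#' standardization, flagged in the result.
#'
#' @param D Monthly water balance (data.frame year, month, d_mm) as returned
#'   by [water_balance].
#' @param window_months Integration window length in months (6 or 12 in
#'   typical use).
#' @param end_month Calendar month the window ends in.
#' @param reference Year range c(from, to) used for fitting; default the
#'   full record.
#' @return A `spei_series`: data.frame year, value, plus attributes window,
#'   end_month, reference, method ("loglogistic" or "empirical").
#' @export
spei <- function(D, window_months, end_month, reference = NULL) {
  ws <- window_sums(D, window_months, end_month)
  if (is.null(reference)) reference <- range(ws$year)
  ref <- ws$sum[ws$year >= reference[1] & ws$year <= reference[2]]
  if (length(ref) < 25)
    stop("fewer than 25 complete windows in the reference period")
  if (stats::sd(ref) <= .Machine$double.eps)
    stop("zero variance in window sums; SPEI undefined")
  # Orient the fit along the sample skew: the log-logistic carries its heavy
  # tail on the right, so left-skewed balances (deep deficit years) are
  # fitted on the negated scale and the CDF reflected back.
  b <- pwm_unbiased(ref)
  orient <- if (6 * b[3] - 6 * b[2] + b[1] < 0) -1 else 1
  method <- if (orient == 1) "loglogistic" else "loglogistic-reflected"
  fit <- tryCatch(loglogistic_pwm(orient * ref), error = function(e) NULL)
  if (!is.null(fit) && fit$gam >= min(orient * ref)) fit <- NULL
  if (is.null(fit)) {
    method <- "empirical"
    # Gringorten plotting positions on the reference sample
    r <- rank(ws$sum)  # ranks of all sums against the pooled record
    p <- (r - 0.44) / (length(ws$sum) + 0.12)
    vals <- as_norm_quantile(p)
  } else {
    p <- loglogistic_cdf(orient * ws$sum, fit)
    if (orient == -1) p <- 1 - p
    vals <- as_norm_quantile(p)
  }
  out <- data.frame(year = ws$year, value = vals)
  attr(out, "window") <- window_months
  attr(out, "end_month") <- end_month
  attr(out, "reference") <- reference
  attr(out, "method") <- method
  class(out) <- c("spei_series", "data.frame")
  out
}

#' Years of extreme drought according to an SPEI threshold
#'
#' @param spei_series Output of [spei].
#' @param threshold Index value; years strictly below it are returned
#'   (default -2, the conventional extreme-drought cutoff).
#' @return Ascending integer years.
#' @export
identify_drought_years <- function(spei_series, threshold = -2) {
  sort(spei_series$year[spei_series$value < threshold])
}

#' Screen candidate SPEI windows against a growth chronology
#'
#' Computes each candidate (window, end_month) SPEI variant from the monthly
#' water balance and correlates it with the chronology index over the common
#' years; used to pick the integration window with the strongest
#' climate-growth association.
#'
#' @param chronology A `chronology` (see [build_chronology]).
#' @param D Monthly water balance.
#' @param candidates data.frame with columns window, end_month.
#' @param reference Optional reference period passed to [spei].
#' @return data.frame window, end_month, n, r — sorted by decreasing r.
#' @export
climate_growth_correlation <- function(chronology, D, candidates,
                                       reference = NULL) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    sp <- spei(D, candidates$window[i], candidates$end_month[i], reference)
    common <- intersect(chronology$years, sp$year)
    if (length(common) < 25)
      stop("fewer than 25 overlapping years between chronology and SPEI")
    r <- stats::cor(chronology$index[match(common, chronology$years)],
                    sp$value[match(common, sp$year)])
    data.frame(window = candidates$window[i],
               end_month = candidates$end_month[i],
               n = length(common), r = r)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r), ]
}
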