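mk_tree <- function(widths, first = 2000, id = "T1") {
  list(tree_id = id, years = seq(first, length.out = length(widths)),
       width_mm = widths)
}

test_that("to_bai matches hand arithmetic in both anchor modes", {
  # inside-out, single 5 mm ring: pi * 0.5^2
  b <- to_bai(mk_tree(5), mode = "inside-out")
  expect_equal(b$bai, pi * 0.25, tolerance = 1e-12)
  # previous radius 10 cm, ring 5 mm: pi (10.5^2 - 10^2)
  b2 <- to_bai(mk_tree(c(100, 5)), mode = "inside-out")
  expect_equal(b2$bai[2], pi * (10.5^2 - 10^2), tolerance = 1e-12)
  expect_equal(b2$bai[2], 32.2013, tolerance = 1e-4)
  # all-zero widths
  expect_equal(to_bai(mk_tree(rep(0, 5)), mode = "inside-out")$bai, rep(0, 5))
  # telescoping: sum of inside-out BAI equals pi r_final^2 exactly
  set.seed(1)
  w <- stats::runif(80, 0.1, 4)
  expect_equal(sum(to_bai(mk_tree(w), mode = "inside-out")$bai),
               pi * (sum(w) / 10)^2, tolerance = 1e-10)
})

test_that("outside-in anchoring pins the final radius to dbh/2", {
  w <- c(2, 3, 1.5, 2.5)
  b <- to_bai(mk_tree(w), dbh = 30, mode = "outside-in")
  # final-year BAI uses r = 15 cm
  expect_equal(b$bai[4], pi * (15^2 - 14.75^2), tolerance = 1e-10)
  expect_error(to_bai(mk_tree(c(100, 100)), dbh = 3, mode = "outside-in"),
               "negative interior radius")
})

test_that("spline detrending reproduces constants and smooth trends", {
  const <- detrend_spline(rep(2, 100))
  expect_equal(const$rwi, rep(1, 100), tolerance = 1e-9)
  lin <- detrend_spline(seq(5, 25, length.out = 200))
  core <- 30:170
  expect_true(all(abs(lin$rwi[core] - 1) < 0.02))
  expect_error(detrend_spline(rep(1, 10)), "short")
})

test_that("rwi series of realistic length keep mean near 1", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(40:200, 1)
    x <- pmax(stats::rlnorm(n, log(3), 0.3) * seq(1.5, 0.7,
                                                  length.out = n), 0.05)
    r <- detrend_spline(x)
    expect_gt(mean(r$rwi), 0.95)
    expect_lt(mean(r$rwi), 1.05)
    expect_true(all(r$rwi > 0))
  }
})

mk_rwi <- function(values, first = 2000, id = "r") {
  structure(list(tree_id = id, years = seq(first,
                                           length.out = length(values)),
                 rwi = values, fitted = rep(1, length(values))),
            class = "rwi_series")
}

test_that("chronology building is robust to outliers and exact on identical input", {
  base <- mk_rwi(c(1, 1.2, 0.8, 1.1, 0.9))
  same <- lapply(1:5, function(i) base)
  ch <- build_chronology(same)
  expect_equal(ch$index, base$rwi, tolerance = 1e-9)
  expect_equal(ch$sample_depth, rep(5L, 5))
  # single series is the identity
  expect_equal(build_chronology(list(base))$index, base$rwi)
  # one gross outlier among five values: biweight stays near 1
  sets <- c(lapply(1:4, function(i) mk_rwi(1)), list(mk_rwi(10)))
  idx <- build_chronology(sets)$index
  expect_lt(abs(idx - 1), 0.05)
  # arithmetic mean would be 2.8; biweight lies between median and mean
  set.seed(5)
  contaminated <- c(stats::rnorm(8, 1, 0.05), 3)
  tb <- droughtmix:::tukey_biweight(contaminated)
  expect_gte(tb, stats::median(contaminated) - 1e-12)
  expect_lte(tb, mean(contaminated))
  # below 4 series the arithmetic mean is used
  three <- list(mk_rwi(1), mk_rwi(1), mk_rwi(7))
  expect_equal(build_chronology(three)$index, 3)
})

test_that("rbar equals the mean of pairwise overlap correlations", {
  set.seed(7)
  series <- lapply(1:4, function(i)
    mk_rwi(stats::rnorm(60, 1, 0.2), first = 1990 + i, id = paste0("s", i)))
  got <- interseries_rbar(series, min_overlap = 20)
  # direct oracle: loop over pairs on their common years
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    common <- intersect(series[[i]]$years, series[[j]]$years)
    vals <- c(vals, stats::cor(
      series[[i]]$rwi[match(common, series[[i]]$years)],
      series[[j]]$rwi[match(common, series[[j]]$years)]))
  }
  expect_equal(got, mean(vals), tolerance = 1e-12)
  # identical series correlate perfectly
  expect_equal(interseries_rbar(list(series[[1]], series[[1]])), 1)
  # many long independent white-noise series: rbar near zero
  set.seed(8)
  noise <- lapply(1:12, function(i) mk_rwi(stats::rnorm(500, 1, 0.1)))
  expect_lt(abs(interseries_rbar(noise)), 0.05)
})

test_that("eps respects its limits and monotonicity", {
  expect_equal(eps(1, 30), 1)
  expect_equal(eps(0, 30), 0)
  expect_error(eps(-0.1, 30), "domain")
  rb <- seq(0.05, 0.95, 0.1)
  expect_true(all(diff(eps(rb, 30)) > 0))
  expect_true(all(eps(0.4, c(5, 10, 30, 100)) ==
                    cummax(eps(0.4, c(5, 10, 30, 100)))))
})

test_that("glk scores sign agreement with half weight for zero changes", {
  up <- mk_rwi(1:30 / 10)
  expect_equal(glk(list(up, up)), 1)
  down <- mk_rwi(rev(1:30) / 10)
  expect_equal(glk(list(up, down)), 0)
  # differences (+,+,0) vs (+,-,+): scores 1, 0, 0.5
  a <- mk_rwi(c(1, 2, 3, 3))
  b <- mk_rwi(c(1, 2, 1, 2))
  expect_equal(glk(list(a, b), min_overlap = 4), 0.5)
})

test_that("lag autocorrelation recovers a known AR(1) process", {
  set.seed(11)
  n <- 2000; phi <- 0.7
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  ac <- lag_autocorrelation(x, max_lag = 2)
  expect_equal(unname(ac[1]), phi, tolerance = 0.05)
  wn <- stats::rnorm(2000)
  expect_true(all(abs(lag_autocorrelation(wn, 2)) < 0.05))
  expect_error(lag_autocorrelation(stats::rnorm(7), max_lag = 5), "short")
  expect_error(lag_autocorrelation(rep(1, 100), 2), "constant")
})

test_that("chronology statistics table reports the expected columns", {
  set.seed(13)
  sets <- list(g1 = lapply(1:6, function(i)
    mk_rwi(stats::rnorm(50, 1, 0.15) + 0.3 * sin(1:50 / 3), id = paste0("t", i))))
  st <- chronology_stats(sets)
  expect_equal(st$n, 6)
  expect_equal(st$eps, eps(st$rbar, 6))
  expect_match(st$period, "^2000-2049$")
})
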