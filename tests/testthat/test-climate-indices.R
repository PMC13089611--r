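mk_climate <- function(years = 1980:2023, seed = 1, droughts = integer()) {
  simulate_climate(years, drought_years = droughts, seed = seed)
}

test_that("extraterrestrial radiation matches the published worked value", {
  # FAO-56 Example 8: 20 deg S, 3 September -> 32.2 MJ m-2 day-1
  expect_equal(droughtmix:::ra_day_mj(-20, 246), 32.2, tolerance = 0.02 * 32.2)
  # equatorial March/September symmetry
  expect_equal(extraterrestrial_radiation(0, 3),
               extraterrestrial_radiation(0, 9),
               tolerance = 0.02 * extraterrestrial_radiation(0, 3))
  # northern-hemisphere seasonality
  expect_gt(extraterrestrial_radiation(35, 6), extraterrestrial_radiation(35, 12))
  expect_error(extraterrestrial_radiation(70, 6), "polar")
})

test_that("Hargreaves PET follows the formula and floors at zero", {
  df <- data.frame(year = 2000, month = 6, prcp_mm = 50,
                   tmean_c = 20, tmin_c = 12, tmax_c = 28)
  tab <- climate_table(df, latitude = 48)
  pet <- hargreaves_pet(tab)
  ra <- extraterrestrial_radiation(48, 6)
  expect_equal(pet$pet_mm, 0.0023 * ra * (20 + 17.8) * sqrt(16) * 30,
               tolerance = 1e-10)
  # zero diurnal range gives zero PET
  df0 <- transform(df, tmin_c = 20, tmax_c = 20)
  expect_equal(hargreaves_pet(climate_table(df0, latitude = 48))$pet_mm, 0)
  # temperatures at -17.8 give zero after the floor
  dfn <- data.frame(year = 2000, month = 1, prcp_mm = 10,
                    tmean_c = -17.8, tmin_c = -20.8, tmax_c = -14.8)
  expect_equal(hargreaves_pet(climate_table(dfn, latitude = 48))$pet_mm, 0)
})

test_that("water balance is P - PET with strict alignment", {
  tab <- mk_climate()
  pet <- hargreaves_pet(tab)
  D <- water_balance(tab, pet)
  expect_equal(D$d_mm, tab$prcp_mm - pet$pet_mm)
  expect_error(water_balance(tab, pet[-1, ]), "aligned")
})

test_that("the 12-month July window covers previous-August through July", {
  # indicator bookkeeping: d = 1 exactly in Aug 1999..Jul 2000, noise elsewhere
  set.seed(2)
  grid <- expand.grid(month = 1:12, year = 1990:2020)
  d <- stats::rnorm(nrow(grid), 0, 0.01)
  inwin <- (grid$year == 1999 & grid$month >= 8) |
    (grid$year == 2000 & grid$month <= 7)
  d[inwin] <- 1
  D <- data.frame(year = grid$year, month = grid$month, d_mm = d)
  ws <- droughtmix:::window_sums(D, 12, 7)
  expect_equal(ws$sum[ws$year == 2000], 12, tolerance = 0.1)
  expect_lt(abs(ws$sum[ws$year == 1998]), 0.2)
  # the first year has no complete window and is dropped
  expect_false(1990 %in% ws$year)
})

test_that("SPEI standardization is calibrated on the reference period", {
  tab <- mk_climate(seed = 4)
  sp <- spei(water_balance(tab), 6, 8)
  expect_lt(abs(mean(sp$value)), 0.05)
  expect_gt(stats::sd(sp$value), 0.9)
  expect_lt(stats::sd(sp$value), 1.1)
  # a year at the fitted median maps to ~0: the middle rank is near zero
  mid <- sp$value[rank(sp$value) == ceiling(nrow(sp) / 2)]
  expect_lt(abs(mid), 0.35)
  short <- expand.grid(month = 1:12, year = 1998:2015)
  shortD <- data.frame(year = short$year, month = short$month,
                       d_mm = stats::rnorm(nrow(short)))
  expect_error(spei(shortD, 6, 8), "25")
})

test_that("SPEI is monotone in the window sum", {
  tab <- mk_climate(seed = 5)
  D <- water_balance(tab)
  sp0 <- spei(D, 6, 8)
  # raising one year's summer balance raises (weakly) that year's SPEI
  D2 <- D
  sel <- D2$year == 2000 & D2$month %in% 3:8
  D2$d_mm[sel] <- D2$d_mm[sel] + 50
  sp2 <- spei(D2, 6, 8, reference = attr(sp0, "reference"))
  expect_gt(sp2$value[sp2$year == 2000], sp0$value[sp0$year == 2000])
})

test_that("drought years are those strictly below the threshold", {
  sp <- structure(data.frame(year = c(2018, 2019, 2022),
                             value = c(-2.3, -0.5, -2.0)),
                  class = c("spei_series", "data.frame"))
  expect_equal(identify_drought_years(sp, -2), 2018)
  expect_equal(identify_drought_years(sp, -3), numeric(0))
})

test_that("window screening recovers a planted climate-growth signal", {
  set.seed(6)
  tab <- mk_climate(seed = 6)
  D <- water_balance(tab)
  sp6 <- spei(D, 6, 8)
  chron <- structure(list(site = "s", species = "oak", years = sp6$year,
                          index = 1 + 0.1 * sp6$value +
                            stats::rnorm(nrow(sp6), 0, 0.03),
                          sample_depth = rep(10L, nrow(sp6))),
                     class = "chronology")
  cands <- data.frame(window = c(6, 12, 3), end_month = c(8, 7, 8))
  out <- climate_growth_correlation(chron, D, cands)
  expect_equal(out$window[1], 6)
  expect_equal(out$end_month[1], 8)
  # identity chronology correlates perfectly
  chron2 <- chron; chron2$index <- sp6$value
  out2 <- climate_growth_correlation(chron2, D, data.frame(window = 6,
                                                           end_month = 8))
  expect_equal(out2$r, 1, tolerance = 1e-9)
  # white-noise chronology shows no strong correlation anywhere
  set.seed(7)
  chron3 <- chron; chron3$index <- stats::rnorm(length(chron$years))
  out3 <- climate_growth_correlation(chron3, D, cands)
  expect_true(all(abs(out3$r) < 0.35))
})
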