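mk_record <- function(target_dbh = 30, neighbors = NULL, species = "oak") {
  if (is.null(neighbors))
    neighbors <- data.frame(species = character(), dbh_cm = numeric(),
                            distance_m = numeric(), dead = logical())
  neighborhood_record("T1", species, target_dbh, neighbors)
}

two_nb <- function() mk_record(30, data.frame(
  species = c("pine", "oak"), dbh_cm = c(15, 45), distance_m = c(3, 5),
  dead = c(FALSE, FALSE)))

test_that("Hegyi CI matches hand-computed fixtures to 1e-10", {
  eq <- mk_record(30, data.frame(species = "oak", dbh_cm = 30,
                                 distance_m = 1, dead = FALSE))
  expect_equal(hegyi_ci(eq), 1.0, tolerance = 1e-12)
  expect_equal(hegyi_ci(two_nb()), 0.5 / 3 + 1.5 / 5, tolerance = 1e-10)
  expect_equal(hegyi_ci(mk_record()), 0)
  # interspecific filter keeps only the pine
  expect_equal(hegyi_ci(two_nb(), "interspecific"), 0.5 / 3,
               tolerance = 1e-10)
  # competitors below 1 cm dbh are ignored
  tiny <- mk_record(30, data.frame(species = "oak", dbh_cm = 0.5,
                                   distance_m = 1, dead = FALSE))
  expect_equal(hegyi_ci(tiny), 0)
  # dead neighbours never compete
  dead <- mk_record(30, data.frame(species = "oak", dbh_cm = 30,
                                   distance_m = 1, dead = TRUE))
  expect_equal(hegyi_ci(dead), 0)
})

test_that("CI is scale-invariant in dbh and monotone in geometry", {
  r1 <- two_nb()
  scaled <- mk_record(30 * 3.7, data.frame(
    species = c("pine", "oak"), dbh_cm = c(15, 45) * 3.7,
    distance_m = c(3, 5), dead = c(FALSE, FALSE)))
  expect_equal(hegyi_ci(r1), hegyi_ci(scaled), tolerance = 1e-10)
  # farther neighbour -> weakly smaller CI; larger neighbour -> larger CI
  set.seed(9)
  for (i in 1:20) {
    nb <- data.frame(species = sample(c("oak", "pine"), 5, TRUE),
                     dbh_cm = stats::runif(5, 2, 50),
                     distance_m = stats::runif(5, 0.5, 6.9),
                     dead = FALSE)
    base <- hegyi_ci(mk_record(30, nb))
    far <- nb; far$distance_m[1] <- min(far$distance_m[1] * 1.5, 7)
    expect_lte(hegyi_ci(mk_record(30, far)), base)
    big <- nb; big$dbh_cm[2] <- big$dbh_cm[2] * 1.5
    expect_gte(hegyi_ci(mk_record(30, big)), base)
  }
})

test_that("admixture is the interspecific share of competition", {
  expect_equal(admixture(two_nb()), 100 * (0.5 / 3) / (0.5 / 3 + 1.5 / 5),
               tolerance = 1e-10)
  expect_equal(admixture(two_nb()), 35.714, tolerance = 1e-3)
  allcon <- mk_record(30, data.frame(species = "oak", dbh_cm = 20,
                                     distance_m = 2, dead = FALSE))
  expect_equal(admixture(allcon), 0)
  allhet <- mk_record(30, data.frame(species = "pine", dbh_cm = 20,
                                     distance_m = 2, dead = FALSE))
  expect_equal(admixture(allhet), 100)
  expect_error(admixture(mk_record()), "isolated")
})

test_that("admixture agrees with its complement computed independently", {
  set.seed(10)
  for (i in 1:15) {
    nb <- data.frame(species = sample(c("oak", "pine", "fir"), 8, TRUE),
                     dbh_cm = stats::runif(8, 2, 50),
                     distance_m = stats::runif(8, 0.5, 6.9), dead = FALSE)
    rec <- mk_record(30, nb)
    direct <- admixture(rec)
    consp <- mk_record(30, nb[nb$species == "oak", , drop = FALSE])
    complement <- 100 * (1 - hegyi_ci(consp) / hegyi_ci(rec))
    expect_equal(direct, complement, tolerance = 1e-12)
  }
})

test_that("biogroup basal area scales from the exact 7-m circle", {
  solo <- mk_record(56.42)
  expect_equal(biogroup_basal_area(solo),
               pi * (56.42 / 200)^2 * 1e4 / (pi * 49), tolerance = 1e-10)
  expect_equal(biogroup_basal_area(solo), 16.24, tolerance = 0.01)
  # no dead trees -> zero deadwood basal area
  expect_equal(biogroup_basal_area(solo, include_dead = TRUE), 0)
  # doubling every dbh quadruples the live value
  big <- mk_record(2 * 56.42)
  expect_equal(biogroup_basal_area(big), 4 * biogroup_basal_area(solo),
               tolerance = 1e-10)
})

test_that("admixture categories close the middle interval", {
  expect_equal(as.character(admixture_category(c(0, 24.9, 25, 50, 75, 75.1, 80, 100))),
               c("<25%", "<25%", "25-75%", "25-75%", "25-75%", ">75%",
                 ">75%", ">75%"))
  expect_error(admixture_category(101))
})

test_that("neighbourhood CSVs round-trip through the summary table", {
  rec <- two_nb()
  f <- withr::local_tempfile(fileext = ".csv")
  nb <- rec$neighbors
  utils::write.csv(data.frame(
    target_id = "T1", target_species = "oak", target_dbh_cm = 30,
    neighbor_species = nb$species, neighbor_dbh_cm = nb$dbh_cm,
    distance_m = nb$distance_m, dead = nb$dead), f, row.names = FALSE)
  recs <- read_neighborhood_csv(f)
  cs <- competition_summary(recs)
  expect_equal(cs$ci_overall, hegyi_ci(rec), tolerance = 1e-12)
  expect_equal(cs$admixture_pct, admixture(rec), tolerance = 1e-12)
  expect_equal(cs$category, "25-75%")
})
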