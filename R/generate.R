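#' Full synthetic-dataset configuration
#'
#' The default bundle mirrors a two-site, two-species sampling design with
#' 30 target trees per species per site (10 per admixture category), growth
#' series 1975-2023, and recurrent droughts in 2018 and 2022 forced into
#' the climate and the growth responses.
#'
#' @param sites Site labels.
#' @param seed Master seed; all per-site and per-stage seeds derive from it.
#' @param years Growth-series year range.
#' @param climate_years Monthly climate record range.
#' @param events data.frame with drought `label` and `year`.
#' @param truth A [truth_record].
#' @param latitude Site latitude (deg).
#' @param stand Base [stand_config] (seed is overridden per site).
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(sites = c("siteA", "siteB"), seed = 1,
                           years = 1975:2023, climate_years = 1980:2023,
                           events = data.frame(
                             label = c("first", "second"),
                             year = c(2018L, 2022L)),
                           truth = truth_record(), latitude = 48,
                           stand = stand_config()) {
  stopifnot(nrow(events) == 2, all(events$year %in% years))
  structure(list(sites = sites, seed = as.integer(seed), years = years,
                 climate_years = climate_years, events = events,
                 truth = truth, latitude = latitude, stand = stand),
            class = "dataset_config")
}

# Convert a growth-index series into plausible ring widths: a declining
# linear age trend scaled so cumulative width matches 90% of dbh/2, with
# widths clamped below the 9.99 mm Tucson representability limit.
rwi_to_widths <- function(rwi_values, dbh_cm) {
  n <- length(rwi_values)
  trend <- 2 - seq_len(n) / n            # 2:1 early:late decline
  total_mm <- dbh_cm / 2 * 10 * 0.9
  w <- trend * rwi_values
  w <- w * total_mm / sum(w)
  pmin(pmax(round(w, 2), 0.01), 9.98)
}

write_truth_txt <- function(truth, path) {
  keys <- names(unclass(truth))
  writeLines(sprintf("%s=%.10g", keys,
                     vapply(keys, function(k) truth[[k]], numeric(1))),
             path)
}

#' Read a flat key=value truth record written by [generate_dataset]
#' @param path File path.
#' @export
read_truth_txt <- function(path) {
  kv <- strsplit(readLines(path), "=")
  vals <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                          vapply(kv, `[[`, "", 1))
  do.call(truth_record, vals)
}

#' Generate a complete on-disk synthetic dataset bundle
#'
#' Simulates stands, climate and growth for every configured site and
#' writes the same formats the analysis pipeline reads: one Tucson/RWL file
#' per site and species (two noisy cores per tree), one monthly climate CSV
#' per site, one stem-mapped neighbourhood CSV per site, the target-tree
#' table, the generative truth record and the exact per-tree drought
#' responses.
#'
#' @param config A [dataset_config].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (targets, records,
#'   rwi, truth_responses) and the file manifest.
#' @export
generate_dataset <- function(config = dataset_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_targets <- list(); all_truth <- list(); all_rwi <- list()
  all_records <- list()
  manifest <- character()
  for (si in seq_along(config$sites)) {
    site <- config$sites[si]
    st_cfg <- config$stand
    st_cfg$seed <- derive_seed(config$seed, 131, si)
    stand <- simulate_stand(st_cfg)
    tg <- stand$targets
    prefix <- toupper(substr(site, nchar(site), nchar(site)))  # A, B, ...
    tg$target_id <- paste0(prefix, tg$target_id)
    names(stand$records) <- tg$target_id
    for (k in seq_along(stand$records))
      stand$records[[k]]$target_id <- tg$target_id[k]
    tg$site <- site
    growth <- simulate_growth(tg, config$years, config$events,
                              truth = config$truth,
                              seed = derive_seed(config$seed, 977, si))
    clim <- simulate_climate(config$climate_years, config$events$year,
                             seed = derive_seed(config$seed, 389, si),
                             latitude = config$latitude, site = site)
    # ring-width cores: two noisy copies per tree
    set.seed(derive_seed(config$seed, 577, si))
    for (sp in unique(tg$species)) {
      ids <- tg$target_id[tg$species == sp]
      cores <- list()
      for (tid in ids) {
        w <- rwi_to_widths(growth$rwi[[tid]]$rwi,
                           tg$dbh[tg$target_id == tid])
        for (core in c("A", "B")) {
          noise <- pmax(1 + stats::rnorm(length(w), 0, 0.03), 0.2)
          cw <- pmin(pmax(round(w * noise, 2), 0.01), 9.98)
          cores[[paste0(tid, core)]] <- rw_series(
            paste0(tid, core), config$years[1], cw,
            metadata = list(tree_id = tid, site = site, species = sp))
        }
      }
      f <- file.path(dir, sprintf("%s_%s.rwl", site, sp))
      write_rwl(cores, f)
      manifest <- c(manifest, f)
    }
    f_clim <- file.path(dir, sprintf("climate_%s.csv", site))
    utils::write.csv(as.data.frame(clim), f_clim, row.names = FALSE)
    # long neighbourhood CSV
    nb_rows <- do.call(rbind, lapply(stand$records, function(r) {
      nb <- r$neighbors
      if (nrow(nb) == 0L)
        nb <- data.frame(species = "", dbh_cm = NA, distance_m = NA,
                         dead = NA)
      data.frame(target_id = r$target_id, target_species = r$target_species,
                 target_dbh_cm = r$target_dbh, neighbor_species = nb$species,
                 neighbor_dbh_cm = nb$dbh_cm, distance_m = nb$distance_m,
                 dead = nb$dead)
    }))
    f_nb <- file.path(dir, sprintf("neighborhood_%s.csv", site))
    utils::write.csv(nb_rows, f_nb, row.names = FALSE)
    manifest <- c(manifest, f_clim, f_nb)
    all_targets[[site]] <- tg
    all_truth[[site]] <- growth$truth_responses
    all_rwi <- c(all_rwi, growth$rwi)
    all_records <- c(all_records, stand$records)
  }
  targets <- do.call(rbind, all_targets); rownames(targets) <- NULL
  truth_responses <- do.call(rbind, all_truth)
  rownames(truth_responses) <- NULL
  utils::write.csv(targets, file.path(dir, "targets.csv"), row.names = FALSE)
  utils::write.csv(truth_responses, file.path(dir, "truth_responses.csv"),
                   row.names = FALSE)
  write_truth_txt(config$truth, file.path(dir, "truth.txt"))
  manifest <- c(manifest, file.path(dir, c("targets.csv",
                                           "truth_responses.csv",
                                           "truth.txt")))
  invisible(list(targets = targets, records = all_records, rwi = all_rwi,
                 truth_responses = truth_responses, manifest = manifest))
}

# Derive a sub-seed from a master seed without 32-bit overflow.
derive_seed <- function(seed, salt, k) {
  as.integer((as.numeric(seed) * salt + k) %% 2147483647)
}
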