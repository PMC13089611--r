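#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: SPEI integration
#' window and end month, the two drought events, the detrending cutoff, the
#' pre-drought window, biogroup geometry, sampler settings and the data
#' directory layout (as produced by [generate_dataset]).
#'
#' @param data_dir Directory holding the input bundle.
#' @param sites Site labels (file name stems).
#' @param species Species labels.
#' @param events data.frame: label ("first"/"second"), year.
#' @param spei_window,spei_end_month SPEI integration window (months) and
#'   end month.
#' @param drought_threshold SPEI cutoff for extreme drought.
#' @param cutoff_years Spline 50% frequency cutoff (years).
#' @param pre_window Pre-drought averaging window (years).
#' @param radius Biogroup radius (m).
#' @param min_dbh Minimum competitor dbh (cm).
#' @param latitude Site latitude for PET.
#' @param sampler A [sampler_config].
#' @param seed Seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, sites = c("siteA", "siteB"),
                            species = c("oak", "pine"),
                            events = data.frame(
                              label = c("first", "second"),
                              year = c(2018L, 2022L)),
                            spei_window = 6, spei_end_month = 8,
                            drought_threshold = -2, cutoff_years = 30,
                            pre_window = 2, radius = 7, min_dbh = 1,
                            latitude = 48,
                            sampler = sampler_config(), seed = 1) {
  stopifnot(nrow(events) == 2, cutoff_years > 0, pre_window > 0,
            radius > 0, min_dbh > 0)
  structure(list(data_dir = data_dir, sites = sites, species = species,
                 events = events, spei_window = spei_window,
                 spei_end_month = spei_end_month,
                 drought_threshold = drought_threshold,
                 cutoff_years = cutoff_years, pre_window = pre_window,
                 radius = radius, min_dbh = min_dbh, latitude = latitude,
                 sampler = sampler, seed = as.integer(seed)),
            class = "pipeline_config")
}

core_tree_id <- function(series_id) sub("[A-Za-z]$", "", series_id)

#' Run the full analysis pipeline
#'
#' Executes, in order: ring-width ingestion and per-tree BAI (cores
#' converted individually with the outside-in dbh anchor, then averaged),
#' spline detrending to growth indices, site chronologies with summary
#' statistics, SPEI and drought-year identification per site, competition
#' and admixture from the stem maps, drought-response extraction, and one
#' hierarchical model fit per species.  Stage outputs are written to
#' `outdir` as they complete, so a failing stage leaves earlier results on
#' disk.
#'
#' @param config A [pipeline_config].
#' @param outdir Output directory for stage CSVs (default: no writing).
#' @param fit_models Set `FALSE` to stop after the response table.
#' @return A results bundle: rwi, chronologies, chronology_stats, spei,
#'   drought_years, competition, responses, fits, log.
#' @export
run_pipeline <- function(config, outdir = NULL, fit_models = TRUE) {
  log <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log <<- c(log, line)
    message(line)
  }
  save_csv <- function(df, name) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
    }
  }
  note("stage=ingest seed=", config$seed)
  # --- neighbourhoods first (they carry the dbh anchors) ------------------
  competition <- list(); records <- list()
  for (site in config$sites) {
    f <- file.path(config$data_dir, sprintf("neighborhood_%s.csv", site))
    if (!file.exists(f)) stop("neighborhood stage: missing ", f)
    recs <- read_neighborhood_csv(f, radius = config$radius)
    cs <- competition_summary(recs, min_dbh = config$min_dbh)
    cs$site <- site
    competition[[site]] <- cs
    records <- c(records, recs)
  }
  competition <- do.call(rbind, competition)
  rownames(competition) <- NULL
  save_csv(competition, "competition.csv")
  dbh_of <- stats::setNames(competition$dbh, competition$target_id)
  # --- ring widths -> per-tree BAI -> rwi ---------------------------------
  rwi_by_group <- list(); bai_by_group <- list(); rwi_all <- list()
  for (site in config$sites) for (sp in config$species) {
    f <- file.path(config$data_dir, sprintf("%s_%s.rwl", site, sp))
    if (!file.exists(f)) stop("ingest stage: missing ", f)
    cores <- read_rwl(f)
    by_tree <- split(cores, vapply(cores, function(s)
      core_tree_id(s$series_id), character(1)))
    key <- paste(site, sp, sep = ".")
    rwi_by_group[[key]] <- list(); bai_by_group[[key]] <- list()
    for (tid in names(by_tree)) {
      if (is.na(dbh_of[tid]))
        stop("ingest stage: no dbh for tree ", tid)
      bais <- lapply(by_tree[[tid]], function(core) {
        tr <- list(tree_id = tid, years = years_of(core),
                   width_mm = core$widths)
        to_bai(tr, dbh = dbh_of[tid], mode = "outside-in")
      })
      bai_mat <- do.call(cbind, lapply(bais, `[[`, "bai"))
      bai_mean <- structure(
        list(tree_id = tid, years = bais[[1]]$years,
             bai = rowMeans(bai_mat)),
        class = "bai_series")
      r <- detrend_spline(bai_mean, cutoff_years = config$cutoff_years)
      bai_by_group[[key]][[tid]] <- bai_mean
      rwi_by_group[[key]][[tid]] <- r
      rwi_all[[tid]] <- r
    }
  }
  note("stage=detrend trees=", length(rwi_all))
  rwi_tab <- do.call(rbind, lapply(rwi_all, function(r)
    data.frame(tree_id = r$tree_id, year = r$years, rwi = r$rwi)))
  save_csv(rwi_tab, "rwi.csv")
  # --- chronologies + statistics ------------------------------------------
  chronologies <- lapply(names(rwi_by_group), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    build_chronology(rwi_by_group[[key]], site = parts[1], species = parts[2])
  })
  names(chronologies) <- names(rwi_by_group)
  stats_tab <- chronology_stats(rwi_by_group, bai_by_group)
  note("stage=chronology groups=", nrow(stats_tab))
  save_csv(stats_tab, "chronology_stats.csv")
  chron_tab <- do.call(rbind, lapply(chronologies, function(ch)
    data.frame(site = ch$site, species = ch$species, year = ch$years,
               index = ch$index, sample_depth = ch$sample_depth)))
  save_csv(chron_tab, "chronologies.csv")
  # --- climate / SPEI ------------------------------------------------------
  spei_list <- list(); drought_years <- list()
  for (site in config$sites) {
    f <- file.path(config$data_dir, sprintf("climate_%s.csv", site))
    if (!file.exists(f)) stop("climate stage: missing ", f)
    clim <- read_climate_csv(f, site = site, latitude = config$latitude)
    if (!all(config$events$year %in% clim$year))
      stop("climate stage: drought year(s) ",
           paste(setdiff(config$events$year, clim$year), collapse = ", "),
           " outside the climate record of ", site)
    D <- water_balance(clim)
    sp <- spei(D, config$spei_window, config$spei_end_month)
    spei_list[[site]] <- sp
    drought_years[[site]] <- identify_drought_years(sp,
                                                    config$drought_threshold)
  }
  note("stage=climate droughts=",
       paste(vapply(drought_years, paste, "", collapse = "/"),
             collapse = " "))
  spei_tab <- do.call(rbind, lapply(names(spei_list), function(s)
    data.frame(site = s, year = spei_list[[s]]$year,
               value = spei_list[[s]]$value,
               window = attr(spei_list[[s]], "window"),
               end_month = attr(spei_list[[s]], "end_month"))))
  save_csv(spei_tab, "spei.csv")
  # --- drought responses ---------------------------------------------------
  covar <- competition
  covar$species <- covar$species
  responses <- drought_response_table(rwi_all, config$events, covar,
                                      pre_window = config$pre_window)
  note("stage=respond rows=", nrow(responses))
  save_csv(responses, "responses.csv")
  fits <- NULL
  if (fit_models) {
    fits <- list()
    for (sp in config$species) {
      rs <- responses[responses$species == sp, ]
      fits[[sp]] <- fit_species_model(rs, config = config$sampler)
      note("stage=fit species=", sp, " max_rhat=",
           round(max(fits[[sp]]$rhat, na.rm = TRUE), 4))
      save_csv(fits[[sp]]$effects, sprintf("effects_%s.csv", sp))
    }
  }
  bundle <- list(rwi = rwi_all, chronologies = chronologies,
                 chronology_stats = stats_tab, spei = spei_list,
                 drought_years = drought_years, competition = competition,
                 responses = responses, fits = fits, config = config,
                 log = log)
  if (!is.null(outdir))
    writeLines(log, file.path(outdir, "run_log.txt"))
  bundle
}

#' Formatted report tables from a pipeline results bundle
#'
#' @param bundle Result of [run_pipeline].
#' @return List: `chronology` (site, species, n, period, mean BAI, rbar,
#'   glk, eps — the conventional chronology overview) and `effects` (per
#'   species posterior mean with 66% and 95% intervals), the latter `NULL`
#'   when models were not fitted.
#' @export
report_tables <- function(bundle) {
  st <- bundle$chronology_stats
  parts <- strsplit(st$label, ".", fixed = TRUE)
  chron <- data.frame(
    site = vapply(parts, `[[`, "", 1),
    species = vapply(parts, `[[`, "", 2),
    n = st$n, period = st$period,
    bai = sprintf("%.2f ± %.2f", st$bai_mean, st$bai_sd),
    rbar = round(st$rbar, 2), glk = round(st$glk, 2),
    eps = round(st$eps, 2))
  effects <- NULL
  if (!is.null(bundle$fits)) {
    effects <- do.call(rbind, lapply(names(bundle$fits), function(sp) {
      e <- bundle$fits[[sp]]$effects
      cbind(species = sp, e)
    }))
  }
  list(chronology = chron, effects = effects)
}
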