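#' Stem-mapped neighbourhood record
#'
#' One target tree plus all mapped neighbours within the 7-m biogroup
#' radius.  Competition uses only living neighbours with dbh >= `min_dbh`.
#'
#' @param target_id,target_species Target identifiers.
#' @param target_dbh Target dbh in cm (> 0).
#' @param neighbors data.frame with columns species, dbh_cm, distance_m and
#'   optionally dead (logical, default FALSE).  May have zero rows.
#' @param radius Biogroup radius in m (default 7).
#' @return A `neighborhood_record`.
#' @export
neighborhood_record <- function(target_id, target_species, target_dbh,
                                neighbors, radius = 7) {
  stopifnot(target_dbh > 0)
  if (nrow(neighbors) > 0) {
    if (is.null(neighbors$dead)) neighbors$dead <- FALSE
    if (any(neighbors$distance_m <= 0))
      stop("neighbour at non-positive distance in record ", target_id)
    if (any(neighbors$distance_m > radius + 1e-9))
      stop("neighbour outside the ", radius, " m biogroup in record ", target_id)
  } else {
    neighbors <- data.frame(species = character(), dbh_cm = numeric(),
                            distance_m = numeric(), dead = logical())
  }
  structure(
    list(target_id = target_id, target_species = target_species,
         target_dbh = target_dbh, neighbors = neighbors, radius = radius),
    class = "neighborhood_record")
}

competitors_of <- function(record, min_dbh = 1) {
  nb <- record$neighbors
  nb[!nb$dead & nb$dbh_cm >= min_dbh, , drop = FALSE]
}

#' Hegyi distance-dependent competition index
#'
#' CI_i = sum over living competitors j (dbh >= `min_dbh`, within the
#' biogroup) of (dbh_j / dbh_i) / dist_ij.  With
#' `species_filter = "interspecific"` only neighbours of species other than
#' the target contribute.
#'
#' @param record A [neighborhood_record].
#' @param species_filter `"all"` or `"interspecific"`.
#' @param min_dbh Minimum competitor dbh in cm (default 1).
#' @return Scalar CI (0 for an isolated tree).
#' @export
hegyi_ci <- function(record, species_filter = c("all", "interspecific"),
                     min_dbh = 1) {
  species_filter <- match.arg(species_filter)
  nb <- competitors_of(record, min_dbh)
  if (species_filter == "interspecific")
    nb <- nb[nb$species != record$target_species, , drop = FALSE]
  if (nrow(nb) == 0L) return(0)
  if (any(nb$distance_m <= 0)) stop("neighbour at distance 0")
  sum((nb$dbh_cm / record$target_dbh) / nb$distance_m)
}

#' Interspecific admixture percentage
#'
#' 100 * CI_interspecific / CI_overall: the share of a target tree's Hegyi
#' competition contributed by other species.
#'
#' @inheritParams hegyi_ci
#' @return Percent in [0, 100].
#' @export
admixture <- function(record, min_dbh = 1) {
  overall <- hegyi_ci(record, "all", min_dbh)
  if (overall <= 0)
    stop("isolated tree (CI_overall = 0): admixture undefined for ",
         record$target_id)
  # summation order can push the ratio past 1 by an ulp; clamp
  min(max(100 * hegyi_ci(record, "interspecific", min_dbh) / overall, 0), 100)
}

#' Biogroup basal area in m^2 per hectare
#'
#' Sum of pi * (dbh/200)^2 over the target tree and its neighbours
#' (living or dead according to `include_dead`), scaled from the exact
#' biogroup area pi * radius^2 to one hectare.
#'
#' @param record A [neighborhood_record].
#' @param include_dead If `FALSE` (default) only living trees count; if
#'   `TRUE`, only dead neighbours are summed (the deadwood column of a
#'   stand table).
#' @return Basal area in m^2 ha^-1.
#' @export
biogroup_basal_area <- function(record, include_dead = FALSE) {
  nb <- record$neighbors
  if (include_dead) {
    dbh <- nb$dbh_cm[nb$dead]
  } else {
    dbh <- c(record$target_dbh, nb$dbh_cm[!nb$dead])
  }
  if (length(dbh) == 0L) return(0)
  area_m2 <- pi * record$radius^2
  sum(pi * (dbh / 200)^2) * 1e4 / area_m2
}

#' Admixture gradient category
#'
#' Classifies an admixture percentage into the three-level gradient used for
#' stratified tree selection: below 25%, 25-75%, above 75% interspecific
#' share.  The boundaries 25 and 75 fall in the middle category.
#'
#' @param admixture_pct Percent in [0, 100].
#' @return Factor with levels `"<25%"`, `"25-75%"`, `">75%"`.
#' @export
admixture_category <- function(admixture_pct) {
  stopifnot(all(admixture_pct >= 0 & admixture_pct <= 100))
  lab <- ifelse(admixture_pct < 25, "<25%",
                ifelse(admixture_pct <= 75, "25-75%", ">75%"))
  factor(lab, levels = c("<25%", "25-75%", ">75%"))
}

#' Read stem-mapped neighbourhoods from a long CSV
#'
#' Expected columns: target_id, target_species, target_dbh_cm,
#' neighbor_species, neighbor_dbh_cm, distance_m, dead.  Rows with an empty
#' neighbor_species denote an isolated target.
#'
#' @param path CSV path.
#' @param radius Biogroup radius in m.
#' @return Named list of [neighborhood_record]s.
#' @export
read_neighborhood_csv <- function(path, radius = 7) {
  df <- utils::read.csv(path)
  split_rows <- split(df, df$target_id)
  out <- lapply(split_rows, function(d) {
    nb <- d[!is.na(d$neighbor_species) & nzchar(d$neighbor_species),
            c("neighbor_species", "neighbor_dbh_cm", "distance_m", "dead")]
    names(nb) <- c("species", "dbh_cm", "distance_m", "dead")
    nb$dead <- as.logical(nb$dead)
    neighborhood_record(d$target_id[1], d$target_species[1],
                        d$target_dbh_cm[1], nb, radius = radius)
  })
  out[order(names(out))]
}

#' Competition and admixture summary for a set of neighbourhoods
#'
#' @param records List of [neighborhood_record]s.
#' @param min_dbh Minimum competitor dbh (cm).
#' @return data.frame: target_id, species, dbh, ci_overall, ci_inter,
#'   admixture_pct, category, ba_live, ba_dead.
#' @export
competition_summary <- function(records, min_dbh = 1) {
  rows <- lapply(records, function(r) {
    ci_all <- hegyi_ci(r, "all", min_dbh)
    ci_int <- hegyi_ci(r, "interspecific", min_dbh)
    adm <- if (ci_all > 0) min(max(100 * ci_int / ci_all, 0), 100)
           else NA_real_
    data.frame(target_id = r$target_id, species = r$target_species,
               dbh = r$target_dbh, ci_overall = ci_all, ci_inter = ci_int,
               admixture_pct = adm,
               category = if (is.na(adm)) NA_character_
                          else as.character(admixture_category(adm)),
               ba_live = biogroup_basal_area(r, FALSE),
               ba_dead = biogroup_basal_area(r, TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
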