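#' Relative growth change of one tree for one drought event
#'
#' 100 * rwi(drought year) / mean(rwi over the `pre_window` years
#' immediately preceding).  The pre-drought window must be fully covered by
#' the series and must not contain another configured drought year.
#'
#' @param rwi An `rwi_series` (see [detrend_spline]).
#' @param drought_year Calendar year of the drought response.
#' @param pre_window Number of preceding years averaged (default 2).
#' @param other_droughts Other configured drought years; overlap with the
#'   pre-window is an error.
#' @return Response in percent (> 0).
#' @export
relative_growth_change <- function(rwi, drought_year, pre_window = 2,
                                   other_droughts = integer()) {
  pre_years <- (drought_year - pre_window):(drought_year - 1)
  need <- c(pre_years, drought_year)
  if (!all(need %in% rwi$years))
    stop("series ", rwi$tree_id, " does not cover years ",
         paste(setdiff(need, rwi$years), collapse = ", "))
  if (any(pre_years %in% setdiff(other_droughts, drought_year)))
    stop("pre-drought window overlaps another drought year for ",
         rwi$tree_id)
  dr <- rwi$rwi[match(drought_year, rwi$years)]
  pre <- mean(rwi$rwi[match(pre_years, rwi$years)])
  100 * dr / pre
}

#' Assemble the tree x drought response table
#'
#' Extracts the relative growth change of every tree for each labelled
#' drought event and joins the competition covariates.  Trees whose
#' pre-drought window is incomplete are dropped with a message rather than
#' computed on a shortened window.
#'
#' @param rwi_set Named list of `rwi_series` keyed by tree_id.
#' @param events data.frame with columns label (e.g. "first"/"second"),
#'   year, and optionally region.
#' @param covariates data.frame from [competition_summary] (plus columns
#'   site, species if available), keyed by target_id.
#' @param pre_window Pre-drought window length in years.
#' @return data.frame: tree_id, site, species, drought_label, drought_year,
#'   response_pct, dbh, ci_overall, admixture_pct.
#' @export
drought_response_table <- function(rwi_set, events, covariates,
                                   pre_window = 2) {
  all_years <- events$year
  rows <- list()
  for (tid in names(rwi_set)) {
    cv <- covariates[covariates$target_id == tid, , drop = FALSE]
    if (nrow(cv) == 0L) next
    for (k in seq_len(nrow(events))) {
      resp <- tryCatch(
        relative_growth_change(rwi_set[[tid]], events$year[k], pre_window,
                               other_droughts = all_years),
        error = function(e) {
          message("dropping ", tid, " / ", events$label[k], ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(resp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = tid,
        site = if ("site" %in% names(cv)) cv$site[1] else NA_character_,
        species = cv$species[1],
        drought_label = events$label[k],
        drought_year = events$year[k],
        response_pct = resp,
        dbh = cv$dbh[1],
        ci_overall = cv$ci_overall[1],
        admixture_pct = cv$admixture_pct[1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two-sided Wilcoxon rank-sum p-value: exact null when the combined sample
# is small and tie-free, tie-corrected normal approximation with continuity
# correction otherwise.
wilcoxon_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied; degenerate test, p = 1")
    return(1)
  }
  exact <- (length(x) + length(y) <= 20) && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Pairwise species comparison of drought responses
#'
#' Within each region x drought-event group, runs two-sided Wilcoxon
#' rank-sum tests between every species pair, multiplies the p-values by the
#' number of comparisons per group (Bonferroni, capped at 1), and assigns
#' compact letter displays at the given significance level: species that do
#' not share a letter differ significantly.
#'
#' @param responses Output of [drought_response_table], with a `region`
#'   column (defaults to a single region when absent).
#' @param alpha Significance level for the letter display (default 0.001).
#' @return data.frame: region, drought_label, species_a, species_b, n_a,
#'   n_b, p_raw, p_adj.  The attribute `letters` holds a data.frame of
#'   per-group species letters.
#' @export
compare_species <- function(responses, alpha = 0.001) {
  if (is.null(responses$region)) responses$region <- "all"
  groups <- split(responses,
                  list(responses$region, responses$drought_label),
                  drop = TRUE)
  rows <- list(); letter_rows <- list()
  for (g in groups) {
    spp <- sort(unique(g$species))
    if (length(spp) < 2L) next
    cmb <- utils::combn(spp, 2)
    m <- ncol(cmb)
    padj <- matrix(1, length(spp), length(spp),
                   dimnames = list(spp, spp))
    for (k in seq_len(m)) {
      a <- g$response_pct[g$species == cmb[1, k]]
      b <- g$response_pct[g$species == cmb[2, k]]
      if (length(a) < 3 || length(b) < 3)
        stop("group with fewer than 3 observations: ",
             cmb[1, k], "/", cmb[2, k])
      p <- wilcoxon_p(a, b)
      p_adj <- min(p * m, 1)
      padj[cmb[1, k], cmb[2, k]] <- padj[cmb[2, k], cmb[1, k]] <- p_adj
      rows[[length(rows) + 1L]] <- data.frame(
        region = g$region[1], drought_label = g$drought_label[1],
        species_a = cmb[1, k], species_b = cmb[2, k],
        n_a = length(a), n_b = length(b), p_raw = p, p_adj = p_adj)
    }
    letter_rows[[length(letter_rows) + 1L]] <- data.frame(
      region = g$region[1], drought_label = g$drought_label[1],
      species = spp, letters = letter_display(padj, alpha))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "letters") <- do.call(rbind, letter_rows)
  out
}

# Greedy compact letter display from a symmetric adjusted-p matrix:
# species sharing a letter are not significantly different at `alpha`.
letter_display <- function(padj, alpha) {
  spp <- rownames(padj)
  not_diff <- padj > alpha
  diag(not_diff) <- TRUE
  groups <- list()
  for (s in spp) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(not_diff[s, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], s); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- s
  }
  lab <- stats::setNames(rep("", length(spp)), spp)
  for (gi in seq_along(groups))
    for (s in groups[[gi]]) lab[s] <- paste0(lab[s], letters[gi])
  as.character(lab[spp])
}
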