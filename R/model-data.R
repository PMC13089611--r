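#' Standardize a predictor matrix
#'
#' Column-wise z-scores with the scaling (means, sds) retained for
#' back-transformation of effect sizes.
#'
#' @param x data.frame or matrix of numeric predictors.
#' @return list with `z` (matrix of z-scores), `center`, `scale`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl <= .Machine$double.eps))
    stop("zero-variance predictor: ",
         paste(colnames(x)[scl <= .Machine$double.eps], collapse = ", "))
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(z = z, center = ctr, scale = scl)
}

#' Back-transform standardized values to the raw scale
#' @param z Matrix of z-scores.
#' @param scaling List with `center` and `scale` from [standardize].
#' @export
unstandardize <- function(z, scaling) {
  sweep(sweep(as.matrix(z), 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) from the least-squares regression of predictor k
#' on all others (with intercept).  Perfect collinearity is reported as
#' `Inf` rather than raised.
#'
#' @param x data.frame or matrix with >= 2 predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(p >= 2, nrow(x) > p + 1)
  out <- numeric(p)
  for (k in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, k] - mean(x[, k]))^2)
    r2 <- 1 - ssr / sst
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(x))
}

#' Assemble model data for the drought-response regression
#'
#' Builds the design for the hierarchical log-normal model of relative
#' growth change: standardized CI, admixture and dbh, two drought-timing
#' indicator columns (no overall intercept), the admixture-by-second-drought
#' interaction, and tree-in-site grouping indices.
#'
#' @param responses data.frame as from [drought_response_table] for one
#'   species in one region: columns tree_id, site, drought_label,
#'   response_pct, dbh, ci_overall, admixture_pct.
#' @return A `model_data` list: y, X (columns ci, mix, dbh, first, second,
#'   mix_second), tree, site (integer indices), tree_site (site of each
#'   tree), scaling, labels.
#' @export
make_model_data <- function(responses) {
  stopifnot(all(c("tree_id", "site", "drought_label", "response_pct",
                  "dbh", "ci_overall", "admixture_pct") %in% names(responses)))
  if (any(responses$response_pct <= 0))
    stop("relative growth changes must be positive")
  if (!all(responses$drought_label %in% c("first", "second")))
    stop("drought_label must be 'first' or 'second'")
  per_tree <- table(responses$tree_id)
  if (any(per_tree > 2))
    stop("more than two rows for tree(s): ",
         paste(names(per_tree)[per_tree > 2], collapse = ", "))
  sc <- standardize(responses[, c("ci_overall", "admixture_pct", "dbh")])
  second <- as.numeric(responses$drought_label == "second")
  X <- cbind(ci = sc$z[, 1], mix = sc$z[, 2], dbh = sc$z[, 3],
             first = 1 - second, second = second,
             mix_second = sc$z[, 2] * second)
  tree_ids <- sort(unique(responses$tree_id))
  site_ids <- sort(unique(responses$site))
  tree <- match(responses$tree_id, tree_ids)
  site <- match(responses$site, site_ids)
  tree_site <- vapply(tree_ids, function(t)
    unique(site[tree == match(t, tree_ids)])[1], numeric(1))
  if (anyNA(tree_site) ||
      any(vapply(split(site, tree), function(s) length(unique(s)), 1L) > 1))
    stop("every tree must belong to exactly one site")
  structure(
    # responses are modelled on the ratio scale (1 = no change): with the
    # weakly informative normal(0,1) coefficient priors and no overall
    # intercept, the drought-level coefficients live near ln(ratio) ~ -0.3,
    # not ln(percent) ~ 4.3
    list(y = responses$response_pct / 100, X = X,
         tree = tree, site = site, tree_site = as.integer(tree_site),
         n_tree = length(tree_ids), n_site = length(site_ids),
         scaling = sc[c("center", "scale")],
         labels = list(tree = tree_ids, site = site_ids)),
    class = "model_data")
}
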