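#' Dated ring-width series
#'
#' Constructor for a single dated core measurement series: an identifier, the
#' calendar year of the first ring, and one width per consecutive year.
#' Widths are in millimetres at 0.01 mm measurement precision.
#'
#' @param series_id Character scalar, at most 8 characters for round-tripping
#'   through the Tucson format.
#' @param first_year Integer calendar year (CE) of the first ring.
#' @param widths Numeric vector of annual ring widths (mm), one per year.
#' @param metadata Optional named list (site, species, tree_id, ...).
#' @return An object of class `rw_series`.
#' @export
rw_series <- function(series_id, first_year, widths, metadata = list()) {
  stopifnot(is.character(series_id), length(series_id) == 1L,
            length(first_year) == 1L, length(widths) >= 1L)
  widths <- as.numeric(widths)
  if (any(!is.finite(widths)) || any(widths < 0))
    stop("ring widths must be finite and >= 0")
  structure(
    list(series_id = series_id, first_year = as.integer(first_year),
         widths = widths, metadata = metadata),
    class = "rw_series")
}

#' @export
print.rw_series <- function(x, ...) {
  cat(sprintf("<rw_series> %s: %d rings, %d-%d\n", x$series_id,
              length(x$widths), x$first_year,
              x$first_year + length(x$widths) - 1L))
  invisible(x)
}

years_of <- function(s) seq(s$first_year, length.out = length(s$widths))

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the decadal layout used by the ITRDB: series identifier in columns
#' 1-8, the first year of the line, then up to ten integer measurements.  The
#' end-of-series sentinel is consumed and determines the unit convention:
#' `999` marks 0.01 mm units and `-9999` marks 0.001 mm units.
#'
#' @param path Path to an existing RWL file.
#' @return A list of [rw_series] objects, named by series id.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  acc <- list()   # per id: list(years, vals, done, divisor)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    id <- trimws(substr(ln, 1L, 8L))
    rest <- trimws(substr(ln, 9L, nchar(ln)))
    toks <- strsplit(rest, "\\s+")[[1]]
    year <- suppressWarnings(as.integer(toks[1]))
    if (is.na(year) || !nzchar(id)) {
      if (is.null(acc[[id]]) || !nzchar(id)) next   # header/comment line
      stop(sprintf("malformed decade line %d: year field is not an integer", i))
    }
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (length(vals) == 0L || any(is.na(vals)))
      stop(sprintf("malformed decade line %d: bad or missing measurements", i))
    if (is.null(acc[[id]]))
      acc[[id]] <- list(years = integer(), vals = numeric(),
                        done = FALSE, divisor = 100)
    a <- acc[[id]]
    if (a$done)
      stop(sprintf("line %d: data after end sentinel for series %s", i, id))
    k <- 0L
    for (v in vals) {
      if (v == 999 || v == -9999) {
        a$done <- TRUE
        a$divisor <- if (v == -9999) 1000 else 100
        break
      }
      a$years <- c(a$years, year + k)
      a$vals <- c(a$vals, v)
      k <- k + 1L
    }
    acc[[id]] <- a
  }
  out <- list()
  for (id in names(acc)) {
    a <- acc[[id]]
    if (length(a$vals) == 0L) next
    if (any(diff(a$years) != 1L))
      stop("non-monotone or gapped years within series ", id)
    out[[id]] <- rw_series(id, a$years[1], a$vals / a$divisor)
  }
  out
}

#' Write a collection of ring-width series to a Tucson/RWL file
#'
#' Emits the decadal layout at 0.01 mm precision with the `999` end sentinel,
#' such that `read_rwl(write_rwl(x))` reproduces the values and years exactly.
#'
#' @param collection List of [rw_series] objects.
#' @param path Output file path.
#' @export
write_rwl <- function(collection, path) {
  out <- character()
  for (s in collection) {
    if (nchar(s$series_id) > 8L)
      stop("series_id exceeds the 8-character Tucson field: ", s$series_id)
    yrs <- years_of(s)
    ivals <- as.integer(round(s$widths * 100))
    if (any(abs(ivals / 100 - s$widths) > 1e-9))
      stop("widths not representable at 0.01 mm precision for ", s$series_id)
    if (any(ivals >= 999))
      stop("width >= 9.99 mm not representable with the 999 sentinel for ",
           s$series_id)
    tokens <- c(ivals, 999L)           # sentinel follows the last value
    tok_year <- c(yrs, yrs[length(yrs)] + 1L)
    i <- 1L
    while (i <= length(tokens)) {
      y <- tok_year[i]
      n_in_line <- min(10L - (y %% 10L), length(tokens) - i + 1L)
      sel <- i:(i + n_in_line - 1L)
      out <- c(out, sprintf("%-8s%4d%s", s$series_id, y,
                            paste0(sprintf("%6d", tokens[sel]), collapse = "")))
      i <- i + n_in_line
    }
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Average the cores of one tree into a single tree-level series
#'
#' Per year the value is the arithmetic mean of the cores measured in that
#' year; the span is the union of the core spans.  Interior gaps (years
#' covered by no core inside the union span) are an error because the
#' detrending downstream assumes consecutive years.
#'
#' @param cores List of [rw_series] for the same tree.
#' @param tree_id Tree identifier; defaults to the shared `metadata$tree_id`.
#' @param species,site Optional labels carried through.
#' @return A `tree_series` object: tree_id, species, site, years, width_mm,
#'   n_cores.
#' @export
merge_cores <- function(cores, tree_id = NULL, species = NA_character_,
                        site = NA_character_) {
  stopifnot(length(cores) >= 1L)
  ids <- vapply(cores, function(s)
    if (!is.null(s$metadata$tree_id)) s$metadata$tree_id else s$series_id,
    character(1))
  if (is.null(tree_id)) {
    if (length(unique(ids)) != 1L)
      stop("cores carry disjoint tree_ids: ", paste(unique(ids), collapse = ", "))
    tree_id <- ids[1]
  } else if (!all(ids == tree_id) && length(unique(ids)) != 1L) {
    stop("cores carry disjoint tree_ids")
  }
  yr_min <- min(vapply(cores, function(s) s$first_year, integer(1)))
  yr_max <- max(vapply(cores, function(s) s$first_year + length(s$widths) - 1L,
                       integer(1)))
  years <- yr_min:yr_max
  sums <- numeric(length(years)); n <- integer(length(years))
  for (s in cores) {
    idx <- match(years_of(s), years)
    sums[idx] <- sums[idx] + s$widths
    n[idx] <- n[idx] + 1L
  }
  if (any(n == 0L))
    stop("interior year(s) covered by no core: ",
         paste(years[n == 0L], collapse = ", "))
  structure(
    list(tree_id = tree_id, species = species, site = site, years = years,
         width_mm = sums / n, n_cores = n),
    class = "tree_series")
}

#' @export
print.tree_series <- function(x, ...) {
  cat(sprintf("<tree_series> %s (%s, %s): %d-%d\n", x$tree_id, x$species,
              x$site, x$years[1], x$years[length(x$years)]))
  invisible(x)
}

#' Export tree-level series as a long data frame
#'
#' @param trees List of `tree_series` objects.
#' @return data.frame with columns tree_id, year, width_mm, n_cores.
#' @export
tree_series_table <- function(trees) {
  do.call(rbind, lapply(trees, function(t)
    data.frame(tree_id = t$tree_id, year = t$years, width_mm = t$width_mm,
               n_cores = t$n_cores)))
}
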