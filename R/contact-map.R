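#' Binned Hi-C contact maps
#'
#' A `contact_map` holds a dense matrix of non-negative contact values over
#' a bin grid: square and symmetric when `row_region == col_region`
#' (intra-chromosomal view), rectangular otherwise (e.g. an off-diagonal
#' rectangle between two distant loci, or a cassette-vs-genome slice).
#' Masked bins — unmappable, filtered, or deleted loci — are carried as
#' `NA`, never as zeros, so they drop out of every downstream statistic
#' instead of dragging means down.
#'
#' @param values Numeric matrix, `NA` allowed; all present values must be
#'   `>= 0`.
#' @param row_region,col_region Regions covered by the rows / columns;
#'   anything [as_region()] accepts. Must be aligned to `bin_size`.
#' @param bin_size Bin width in bp.
#' @param normalization One of `"raw"`, `"rpm"`, `"balanced"`.
#' @param assembly Genome assembly label carried into file headers.
#' @return A `contact_map` object.
#' @export
contact_map <- function(values, row_region, col_region = row_region,
                        bin_size, normalization = "raw",
                        assembly = "unknown") {
  row_region <- as_region(row_region)
  col_region <- as_region(col_region)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  normalization <- match.arg(normalization, c("raw", "rpm", "balanced"))
  for (r in list(row_region, col_region)) {
    if (r$start %% bin_size != 0 || r$end %% bin_size != 0) {
      abort(sprintf("Region %s is not aligned to the %d bp bin grid.",
                    format(r), bin_size))
    }
  }
  n_r <- region_width(row_region) / bin_size
  n_c <- region_width(col_region) / bin_size
  if (nrow(values) != n_r || ncol(values) != n_c) {
    abort(sprintf("Matrix is %d x %d but regions span %d x %d bins.",
                  nrow(values), ncol(values), n_r, n_c))
  }
  if (any(values < 0, na.rm = TRUE)) abort("Contact values must be >= 0.")
  if (regions_equal(row_region, col_region)) {
    d <- abs(values - t(values))
    if (any(d > 1e-9, na.rm = TRUE)) {
      abort("Intra-chromosomal map must be symmetric where both entries are present.")
    }
  }
  structure(list(values = values, row_region = row_region,
                 col_region = col_region, bin_size = as.numeric(bin_size),
                 normalization = normalization, assembly = assembly),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s x %s @ %s bp [%s]%s\n",
              format(x$row_region), format(x$col_region),
              format(x$bin_size, scientific = FALSE),
              x$normalization,
              if (is_intra(x)) " (intra)" else ""))
  cat(sprintf("  %d x %d bins, %d masked entries\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$values)

is_intra <- function(map) regions_equal(map$row_region, map$col_region)

#' Bin table of a contact map axis
#'
#' @param map A [contact_map()].
#' @param axis `"row"` or `"col"`.
#' @return A tibble with `bin` (1-based index within the map), `chrom`,
#'   `start`, `end`.
#' @export
map_bins <- function(map, axis = c("row", "col")) {
  axis <- match.arg(axis)
  r <- if (axis == "row") map$row_region else map$col_region
  n <- region_width(r) / map$bin_size
  starts <- r$start + (seq_len(n) - 1) * map$bin_size
  tibble::tibble(bin = seq_len(n), chrom = r$chrom, start = starts,
                 end = starts + map$bin_size)
}

# Local (1-based) bin indices of a region along one axis; errors if the
# snapped region leaves the map extent.
local_bins <- function(map, x, axis = c("row", "col")) {
  axis <- match.arg(axis)
  r <- if (axis == "row") map$row_region else map$col_region
  x <- as_region(x)
  if (x$chrom != r$chrom || x$start < r$start || x$end > r$end) {
    abort(sprintf("Region %s is outside the map extent %s.",
                  format(x), format(r)))
  }
  region_bins(x, map$bin_size) - r$start / map$bin_size + 1L
}

#' Scale a raw map to reads per million (RPM)
#'
#' Multiplies every contact value by `1e6 / total_valid_pairs`, the
#' standard depth normalisation when comparing locus views across
#' libraries of different sequencing depth.
#'
#' @param map A raw [contact_map()].
#' @param total_valid_pairs Total valid read pairs of the library
#'   (positive).
#' @return The map with `normalization = "rpm"`.
#' @export
normalize_rpm <- function(map, total_valid_pairs) {
  stopifnot(inherits(map, "contact_map"))
  if (!is.numeric(total_valid_pairs) || total_valid_pairs <= 0) {
    abort("`total_valid_pairs` must be positive.")
  }
  if (map$normalization != "raw") {
    abort("RPM scaling applies to raw maps only.")
  }
  map$values <- map$values * (1e6 / total_valid_pairs)
  map$normalization <- "rpm"
  map
}

#' Iterative correction (matrix balancing)
#'
#' Iteratively divides rows and columns by their relative coverage until
#' the coefficient of variation of the unmasked row sums falls below
#' `tol`, equalising bin visibility across a square symmetric map. Bins
#' with zero coverage are masked before balancing.
#'
#' @param map Square intra-chromosomal [contact_map()].
#' @param max_iter Iteration cap.
#' @param tol Target coefficient of variation of row sums.
#' @return The balanced map (`normalization = "balanced"`).
#' @export
balance_ice <- function(map, max_iter = 100L, tol = 1e-5) {
  stopifnot(inherits(map, "contact_map"))
  if (!is_intra(map)) abort("Balancing needs a square intra-chromosomal map.")
  v <- map$values
  if (all(is.na(v) | v == 0)) abort("Cannot balance an all-zero matrix.")
  rs <- rowSums(v, na.rm = TRUE)
  dead <- rs == 0 | rowSums(!is.na(v)) == 0
  v[dead, ] <- NA_real_
  v[, dead] <- NA_real_
  live <- !dead
  for (iter in seq_len(max_iter)) {
    rs <- rowSums(v, na.rm = TRUE)[live]
    cv <- sd(rs) / mean(rs)
    if (is.na(cv) || cv < tol) break
    s <- rep(1, nrow(v))
    s[live] <- rs / mean(rs)
    v <- v / outer(s, s)
  }
  map$values <- v
  map$normalization <- "balanced"
  map
}

#' Extract a rectangular sub-view of a map
#'
#' Regions are snapped outward to the bin grid, so every overlapped bin is
#' covered; the sub-matrix is copied into a new map.
#'
#' @param map A [contact_map()].
#' @param rows,cols Regions for the row / column axes (default: keep the
#'   axis whole).
#' @return A [contact_map()] over the snapped regions.
#' @export
extract_submatrix <- function(map, rows = NULL, cols = NULL) {
  stopifnot(inherits(map, "contact_map"))
  rows <- if (is.null(rows)) map$row_region else snap_region(rows, map$bin_size)
  cols <- if (is.null(cols)) map$col_region else snap_region(cols, map$bin_size)
  ri <- local_bins(map, rows, "row")
  ci <- local_bins(map, cols, "col")
  contact_map(map$values[ri, ci, drop = FALSE], rows, cols,
              bin_size = map$bin_size, normalization = map$normalization,
              assembly = map$assembly)
}

#' Mask a locus out of an intra-chromosomal map
#'
#' Sets the rows and columns of every bin overlapping `locus` to `NA`,
#' modelling a deleted or unmappable locus while keeping the bin grid —
#' and hence wild-type/knockout comparability — intact.
#'
#' @param map Intra-chromosomal [contact_map()].
#' @param locus Region to mask.
#' @return The masked map.
#' @export
mask_locus <- function(map, locus) {
  stopifnot(inherits(map, "contact_map"))
  if (!is_intra(map)) abort("mask_locus() needs an intra-chromosomal map.")
  locus <- as_region(locus)
  if (!regions_overlap(locus, map$row_region)) return(map)
  clipped <- region(locus$chrom, max(locus$start, map$row_region$start),
                    min(locus$end, map$row_region$end))
  idx <- local_bins(map, clipped, "row")
  map$values[idx, ] <- NA_real_
  map$values[, idx] <- NA_real_
  map
}
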