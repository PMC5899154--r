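#' Genomic regions
#'
#' A genomic region is a 0-based, half-open interval `[start, end)` on a
#' named chromosome. All coordinates in the package follow this convention
#' (BED-compatible); bin `i` of a `bin_size` grid covers
#' `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start,end Integer-valued base-pair offsets, `0 <= start < end`.
#' @return A `genomic_region` object.
#' @examples
#' region("chrX", 47908463, 47990294)
#' as_region("chrX:47908463-47990294")
#' @export
region <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    abort("`chrom` must be a non-empty string.")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    abort("Region coordinates must satisfy 0 <= start < end.")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' @param x A `genomic_region`, a string like `"chrX:100-200"` (commas in
#'   numbers allowed), or a list/one-row data frame with `chrom`, `start`,
#'   `end`.
#' @rdname region
#' @export
as_region <- function(x) {
  if (inherits(x, "genomic_region")) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*([^:]+):([0-9,]+)-([0-9,]+)\\s*$", x))[[1]]
    if (length(m) != 4L) abort(sprintf("Cannot parse region string '%s'.", x))
    return(region(m[2],
                  as.numeric(gsub(",", "", m[3], fixed = TRUE)),
                  as.numeric(gsub(",", "", m[4], fixed = TRUE))))
  }
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(region(as.character(x$chrom[[1]]), x$start[[1]], x$end[[1]]))
  }
  abort("Cannot coerce to a genomic region.")
}

#' @export
format.genomic_region <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom,
          format(x$start, scientific = FALSE, trim = TRUE),
          format(x$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("<region>", format(x), "\n")
  invisible(x)
}

region_width <- function(x) x$end - x$start

regions_equal <- function(a, b) {
  a$chrom == b$chrom && a$start == b$start && a$end == b$end
}

regions_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

region_midpoint <- function(x) floor((x$start + x$end) / 2)

#' Snap a region outward to a bin grid
#'
#' Expands `x` so both ends lie on multiples of `bin_size`, covering every
#' bin the original region overlaps.
#'
#' @param x Region (anything [as_region()] accepts).
#' @param bin_size Grid bin size in bp.
#' @return A `genomic_region` on the grid.
#' @export
snap_region <- function(x, bin_size) {
  x <- as_region(x)
  region(x$chrom,
         floor(x$start / bin_size) * bin_size,
         ceiling(x$end / bin_size) * bin_size)
}

# Global (chromosome-wide, 0-based) bin indices overlapped by a region.
region_bins <- function(x, bin_size) {
  x <- as_region(x)
  seq(floor(x$start / bin_size), floor((x$end - 1) / bin_size))
}

# Global bin index containing a point.
point_bin <- function(pos, bin_size) floor(pos / bin_size)
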