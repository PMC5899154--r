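#' Specification of a synthetic Hi-C contact map
#'
#' Parameterizes a generative model for binned contact maps with the
#' structures the package's statistics are designed to measure: power-law
#' distance decay, TAD blocks separated by boundaries of tunable
#' insulation, point-like long-range loop windows, an optional locus
#' deletion, and Poisson sequencing-depth noise. The model for the
#' expected contact between bins `i` and `j` is
#' `diagonal_level * |i - j|^-decay_exponent`, multiplied by the
#' insulation factor of every boundary between them and by the fold
#' enrichment of any loop window covering the pair, then scaled so the
#' loop-free, deletion-free background sums to `depth`.
#'
#' @param extent Intra-chromosomal region modeled.
#' @param bin_size Bin width, bp.
#' @param decay_exponent Power-law decay exponent (> 0).
#' @param diagonal_level Expected contacts at a 1-bin separation before
#'   depth scaling; distance-0 (diagonal) entries use the same level.
#' @param tad_boundaries Boundary positions, bp (snapped to bin edges),
#'   strictly increasing within the extent.
#' @param boundary_insulation Per-boundary factor in `(0, 1]` multiplying
#'   contacts crossing it (smaller = stronger boundary); recycled.
#' @param loops List of loops, each a list with `anchor_row`,
#'   `anchor_col`, `fold` (>= 1) and optional `n_rows`, `n_cols`
#'   (default 6 x 7): the window centered on the anchor bin pair is
#'   enriched `fold`-fold (symmetrically).
#' @param deletion Optional region whose bins get zero expected signal
#'   (the bins are kept, so wild-type and knockout grids stay
#'   comparable).
#' @param depth Expected total contact count of the background model over
#'   the generated view.
#' @param view_rows,view_cols Optional sub-regions: generate only the
#'   (off-diagonal) rectangle `view_rows x view_cols` instead of the full
#'   square map. The two views must be equal or disjoint.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(extent, bin_size, decay_exponent = 1,
                           diagonal_level = 1, tad_boundaries = numeric(),
                           boundary_insulation = numeric(), loops = list(),
                           deletion = NULL, depth = 1e6,
                           view_rows = NULL, view_cols = NULL) {
  extent <- snap_region(extent, bin_size)
  stopifnot(decay_exponent > 0, diagonal_level > 0, depth > 0)
  if (length(tad_boundaries) > 0) {
    tad_boundaries <- round(tad_boundaries / bin_size) * bin_size
    if (any(diff(tad_boundaries) <= 0)) {
      abort("Boundary positions must be strictly increasing.")
    }
    if (any(tad_boundaries <= extent$start | tad_boundaries >= extent$end)) {
      abort("Boundary positions must lie inside the extent.")
    }
    if (length(boundary_insulation) == 0) boundary_insulation <- 0.5
    boundary_insulation <- rep_len(boundary_insulation, length(tad_boundaries))
    if (any(boundary_insulation <= 0 | boundary_insulation > 1)) {
      abort("Insulation factors must lie in (0, 1].")
    }
  }
  loops <- lapply(loops, function(l) {
    stopifnot(!is.null(l$anchor_row), !is.null(l$anchor_col))
    l$anchor_row <- as_region(l$anchor_row)
    l$anchor_col <- as_region(l$anchor_col)
    l$fold <- l$fold %||% 5
    if (l$fold < 1) abort("Loop fold enrichment must be >= 1.")
    l$n_rows <- as.integer(l$n_rows %||% 6L)
    l$n_cols <- as.integer(l$n_cols %||% 7L)
    l
  })
  if (!is.null(deletion)) deletion <- as_region(deletion)
  view_rows <- if (is.null(view_rows)) extent else snap_region(view_rows, bin_size)
  view_cols <- if (is.null(view_cols)) extent else snap_region(view_cols, bin_size)
  if (!regions_equal(view_rows, view_cols) &&
      regions_overlap(view_rows, view_cols)) {
    abort("View rectangles must be equal or disjoint.")
  }
  structure(list(extent = extent, bin_size = bin_size,
                 decay_exponent = decay_exponent,
                 diagonal_level = diagonal_level,
                 tad_boundaries = tad_boundaries,
                 boundary_insulation = boundary_insulation,
                 loops = loops, deletion = deletion, depth = depth,
                 view_rows = view_rows, view_cols = view_cols),
            class = "synthetic_spec")
}

#' Expected (noise-free) contact map of a synthetic spec
#'
#' Deterministic: the Poisson means that [sample_map()] draws from.
#'
#' @param spec A [synthetic_spec()].
#' @return A real-valued [contact_map()] of expectations.
#' @export
expected_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bs <- spec$bin_size
  rb <- region_bins(spec$view_rows, bs)   # global bin indices
  cb <- region_bins(spec$view_cols, bs)
  d <- abs(outer(rb, cb, `-`))
  base <- spec$diagonal_level * ifelse(d == 0, 1, d^(-spec$decay_exponent))

  scale <- spec$depth / sum(base)
  e <- base * scale

  # boundary at edge k separates global bins k-1 and k; a pair (i, j)
  # crosses it iff min < k <= max
  lo <- outer(rb, cb, pmin)
  hi <- outer(rb, cb, pmax)
  for (b in seq_along(spec$tad_boundaries)) {
    k <- spec$tad_boundaries[b] / bs
    crossed <- lo < k & hi >= k
    e[crossed] <- e[crossed] * spec$boundary_insulation[b]
  }
  for (l in spec$loops) {
    ra <- loop_window_bins(l$anchor_row, l$n_rows, bs)
    ca <- loop_window_bins(l$anchor_col, l$n_cols, bs)
    hit <- (outer(rb %in% ra, cb %in% ca, `&`)) |
      (outer(rb %in% ca, cb %in% ra, `&`))
    e[hit] <- e[hit] * l$fold
  }
  if (!is.null(spec$deletion)) {
    db <- region_bins(snap_region(spec$deletion, bs), bs)
    e[rb %in% db, ] <- 0
    e[, cb %in% db] <- 0
  }
  intra <- regions_equal(spec$view_rows, spec$view_cols)
  if (intra) e <- (e + t(e)) / 2
  contact_map(e, spec$view_rows, spec$view_cols, bin_size = bs,
              assembly = "synthetic")
}

# global bin indices of a loop window centered on the anchor midpoint
loop_window_bins <- function(anchor, n, bin_size) {
  center <- point_bin(region_midpoint(anchor), bin_size)
  (center - floor((n - 1) / 2)):(center + ceiling((n - 1) / 2))
}

#' Sample a contact map with Poisson depth noise
#'
#' Draws each upper-triangle entry (or each entry, for a disjoint
#' off-diagonal view) independently from a Poisson with the
#' [expected_map()] mean, mirroring across the diagonal for intra views.
#' Deterministic for a given `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return An integer-count [contact_map()].
#' @export
sample_map <- function(spec, seed) {
  e <- expected_map(spec)
  v <- withr::with_seed(as.integer(seed), {
    if (is_intra(e)) {
      n <- nrow(e$values)
      ut <- upper.tri(e$values, diag = TRUE)
      draws <- rpois(sum(ut), e$values[ut])
      m <- matrix(0, n, n)
      m[ut] <- draws
      m <- m + t(m) - diag(diag(m))
      m
    } else {
      matrix(rpois(length(e$values), e$values), nrow(e$values))
    }
  })
  e$values <- v
  e
}

#' Derive a knockout spec from a wild-type spec
#'
#' Sets a deletion and, optionally, removes every loop with an anchor
#' overlapping the deleted locus — the in-silico analogue of deleting a
#' loop-anchoring locus while leaving the TAD partition untouched.
#'
#' @param spec A [synthetic_spec()].
#' @param locus Region deleted in the knockout.
#' @param remove_loops_touching Drop loops anchored in `locus`.
#' @return A modified `synthetic_spec`.
#' @export
ko_spec <- function(spec, locus, remove_loops_touching = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  locus <- as_region(locus)
  if (!regions_overlap(locus, spec$extent)) {
    abort("Deleted locus must lie within the extent.")
  }
  spec$deletion <- locus
  if (remove_loops_touching) {
    spec$loops <- purrr::keep(spec$loops, function(l) {
      !regions_overlap(l$anchor_row, locus) &&
        !regions_overlap(l$anchor_col, locus)
    })
  }
  spec
}

#' Sample a cassette-to-genome contact profile
#'
#' Simulates the per-bin inter-chromosomal contact counts between a
#' transgene cassette contig and genomic bins: Poisson background
#' everywhere, plus a Poisson pileup at each insertion's bin and a
#' half-mean pileup at its two neighbours (proximity-ligation signal
#' spreads into adjacent bins).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths, bp.
#' @param bin_size Bin width, bp.
#' @param insertions Data frame with `chrom`, `pos`, `pileup_mean` (may
#'   have zero rows).
#' @param background_mean Background Poisson mean per bin.
#' @param seed Integer seed.
#' @param condition Condition label stored on the profile.
#' @return A cassette-profile tibble: `condition`, `chrom`, `bin`,
#'   `start`, `end`, `count`.
#' @export
sample_cassette_profile <- function(chrom_lengths, bin_size, insertions,
                                    background_mean, seed,
                                    condition = "cond") {
  stopifnot(!is.null(names(chrom_lengths)), background_mean >= 0)
  withr::with_seed(as.integer(seed), {
    prof <- purrr::map_dfr(names(chrom_lengths), function(ch) {
      n <- ceiling(chrom_lengths[[ch]] / bin_size)
      starts <- (seq_len(n) - 1) * bin_size
      counts <- rpois(n, background_mean)
      ins <- insertions[insertions$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(ins))) {
        if (ins$pos[k] < 0 || ins$pos[k] >= chrom_lengths[[ch]]) {
          abort("Insertion position outside its chromosome.")
        }
        b <- point_bin(ins$pos[k], bin_size) + 1L
        counts[b] <- counts[b] + rpois(1, ins$pileup_mean[k])
        for (nb in c(b - 1L, b + 1L)) {
          if (nb >= 1L && nb <= n) {
            counts[nb] <- counts[nb] + rpois(1, ins$pileup_mean[k] / 2)
          }
        }
      }
      tibble::tibble(condition = condition, chrom = ch, bin = seq_len(n),
                     start = starts,
                     end = pmin(starts + bin_size, chrom_lengths[[ch]]),
                     count = counts)
    })
    prof
  })
}

#' Sample a synthetic peak track
#'
#' Homogeneous Poisson-process background peaks over an extent plus a
#' fixed number of extra peaks uniform within a hotspot region, all of a
#' fixed 200 bp width — emulating a chromosome-wide binding-site track
#' with one locus of exceptional density.
#'
#' @param extent Region covered.
#' @param background_rate Background intensity, peaks per Mb.
#' @param hotspot Optional hotspot region within the extent.
#' @param hotspot_count Number of hotspot peaks.
#' @param seed Integer seed.
#' @param width Peak width, bp.
#' @return A peak tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`), sorted by start.
#' @export
sample_peaks <- function(extent, background_rate, hotspot = NULL,
                         hotspot_count = 0, seed, width = 200) {
  extent <- as_region(extent)
  stopifnot(background_rate >= 0, hotspot_count >= 0)
  if (!is.null(hotspot)) {
    hotspot <- as_region(hotspot)
    if (!(hotspot$start >= extent$start && hotspot$end <= extent$end)) {
      abort("Hotspot must lie within the extent.")
    }
  }
  withr::with_seed(as.integer(seed), {
    n_bg <- rpois(1, background_rate * region_width(extent) / 1e6)
    mids <- floor(runif(n_bg, extent$start, extent$end))
    if (hotspot_count > 0) {
      if (is.null(hotspot)) abort("`hotspot` required when hotspot_count > 0.")
      mids <- c(mids, floor(runif(hotspot_count, hotspot$start, hotspot$end)))
    }
    mids <- sort(mids)
    start <- pmax(extent$start, mids - width %/% 2)
    tibble::tibble(chrom = extent$chrom, start = start,
                   end = pmin(extent$end, start + width),
                   name = sprintf("peak_%d", seq_along(mids)),
                   score = 0, strand = "*")
  })
}
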