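#' Insulation parameters
#'
#' Parameter bundle for the insulation-square method of TAD boundary
#' detection. The defaults reproduce the canonical option set of the
#' cworld `matrix2insulation` script as used for mouse 40 kb matrices:
#' a 480 kb insulation square, 320 kb delta span, `iqrMean` aggregation,
#' zero noise threshold, 160 kb smoothing, and a boundary-margin of 0
#' bins.
#'
#' @param square_size Side of the insulation square, bp. For each bin the
#'   aggregate is taken over the square of contacts linking the
#'   `square_size` of sequence upstream to the `square_size` downstream.
#' @param delta_span Flank span of the delta vector, bp.
#' @param aggregation How values inside the square are aggregated:
#'   `"iqrMean"` (mean of values lying within `[Q1, Q3]`, inclusive —
#'   robust to single outlier pixels), `"mean"`, or `"median"`.
#' @param noise_threshold Bins whose unmasked row sum is `<=` this value
#'   are masked before scoring (0 masks only zero-coverage bins).
#' @param smooth_span Span of the centered running mean applied to the raw
#'   insulation vector before log-normalisation, bp; `0` disables
#'   smoothing.
#' @param boundary_margin Boundaries within this many bins of a masked bin
#'   are discarded.
#' @param strength_cutoff Minimum delta excursion for a reported boundary;
#'   suppresses numerical-noise zero crossings on flat profiles.
#' @return An `insulation_params` list.
#' @export
insulation_params <- function(square_size = 480e3, delta_span = 320e3,
                              aggregation = c("iqrMean", "mean", "median"),
                              noise_threshold = 0, smooth_span = 160e3,
                              boundary_margin = 0L, strength_cutoff = 0.1) {
  aggregation <- match.arg(aggregation)
  stopifnot(square_size > 0, delta_span > 0, smooth_span >= 0,
            boundary_margin >= 0, strength_cutoff >= 0)
  structure(list(square_size = square_size, delta_span = delta_span,
                 aggregation = aggregation, noise_threshold = noise_threshold,
                 smooth_span = smooth_span,
                 boundary_margin = as.integer(boundary_margin),
                 strength_cutoff = strength_cutoff),
            class = "insulation_params")
}

# bp span -> whole bins, snapped to the nearest positive multiple
span_bins <- function(span, bin_size) max(1L, as.integer(round(span / bin_size)))

aggregate_square <- function(x, mode) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  switch(mode,
         mean = mean(x),
         median = median(x),
         iqrMean = {
           q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
           mean(x[x >= q[1] & x <= q[2]])
         })
}

#' Insulation score of an intra-chromosomal map
#'
#' For each bin the contacts crossing it are aggregated over a
#' `square_size` x `square_size` square sliding along the diagonal
#' (rows `i-w..i-1` by columns `i+1..i+w`, `w = square_size / bin_size`),
#' optionally smoothed, and log2-normalised to the mean over unmasked
#' bins, so that a bin with score 0 is averagely insulating and local
#' minima mark candidate TAD boundaries. The score is invariant under
#' global rescaling of the matrix.
#'
#' Bins are masked when the square is truncated by a matrix edge, when
#' more than half of its entries are missing, when the bin's coverage is
#' at or below `noise_threshold`, or when the (smoothed) aggregate is
#' exactly zero (log undefined).
#'
#' @param map Square intra-chromosomal [contact_map()] spanning at least
#'   twice `square_size`.
#' @param params An [insulation_params()].
#' @return An `insulation_profile` tibble with one row per bin: `bin`,
#'   `chrom`, `start`, `end`, `raw` (aggregate after smoothing), `score`,
#'   `delta` (`NA` until [delta_vector()] is applied), `valid`.
#' @export
insulation_score <- function(map, params = insulation_params()) {
  stopifnot(inherits(map, "contact_map"))
  if (!is_intra(map)) abort("Insulation needs a square intra-chromosomal map.")
  v <- map$values
  n <- nrow(v)
  w <- span_bins(params$square_size, map$bin_size)
  if (region_width(map$row_region) < 2 * params$square_size) {
    abort("Map extent must be at least twice the insulation square size.")
  }

  coverage <- rowSums(v, na.rm = TRUE)
  row_dead <- coverage <= params$noise_threshold | rowSums(!is.na(v)) == 0
  v[row_dead, ] <- NA_real_
  v[, row_dead] <- NA_real_

  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (row_dead[i] || i - w < 1L || i + w > n) next
    sq <- v[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
    if (mean(is.na(sq)) > 0.5) next
    raw[i] <- aggregate_square(sq, params$aggregation)
  }

  if (params$smooth_span > 0) {
    half <- max(0L, as.integer(round(params$smooth_span / (2 * map$bin_size))))
    if (half > 0L) raw <- running_mean(raw, half)
  }
  raw[!is.na(raw) & raw == 0] <- NA_real_

  valid <- !is.na(raw)
  score <- rep(NA_real_, n)
  if (any(valid)) score[valid] <- log2(raw[valid] / mean(raw[valid]))

  prof <- map_bins(map, "row")
  prof$raw <- raw
  prof$score <- score
  prof$delta <- NA_real_
  prof$valid <- valid
  new_insulation_profile(prof, map$bin_size, params)
}

new_insulation_profile <- function(df, bin_size, params) {
  structure(df, class = c("insulation_profile", class(tibble::as_tibble(df))),
            bin_size = bin_size, params = params)
}

# centered running mean of half-width `half`, NA-aware
running_mean <- function(x, half) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    win <- x[max(1L, i - half):min(n, i + half)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

#' Delta vector of an insulation profile
#'
#' `delta(i)` is the mean score over the `delta_span` of bins downstream
#' of `i` minus the mean over the span upstream; it crosses zero from
#' negative to positive at insulation minima, and the amplitude of the
#' excursion around the crossing is the boundary strength. Positions whose
#' flank is truncated by the profile edge, or holds no valid score at all,
#' are left `NA`; isolated masked bins inside a flank (e.g. a deleted
#' locus) are simply skipped, so a boundary remains detectable across a
#' small deletion.
#'
#' @param profile An [insulation_score()] result.
#' @param params The [insulation_params()] used (defaults to those stored
#'   on the profile).
#' @return The profile with the `delta` column filled.
#' @export
delta_vector <- function(profile, params = attr(profile, "params")) {
  stopifnot(inherits(profile, "insulation_profile"))
  bin_size <- attr(profile, "bin_size")
  s <- span_bins(params$delta_span, bin_size)
  score <- profile$score
  n <- length(score)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - s < 1L || i + s > n) next
    left <- score[(i - s):(i - 1L)]
    right <- score[(i + 1L):(i + s)]
    if (all(is.na(left)) || all(is.na(right))) next
    delta[i] <- mean(right, na.rm = TRUE) - mean(left, na.rm = TRUE)
  }
  profile$delta <- delta
  profile
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries sit where the delta vector crosses zero upward (bracketing a
#' local minimum of the insulation score). The boundary bin is the
#' lower-scoring bin of the crossing pair; its strength is the delta
#' excursion across the crossing — the nearest local maximum of delta on
#' the rising side minus the nearest local minimum on the falling side.
#' Crossings weaker than `strength_cutoff`, or within `boundary_margin`
#' bins of a masked bin, are discarded.
#'
#' @param profile A profile with `delta` computed (computed on the fly
#'   otherwise).
#' @param params The [insulation_params()].
#' @return A tibble of boundaries: `bin`, `chrom`, `start`, `end`,
#'   `strength`, sorted by position.
#' @export
call_boundaries <- function(profile, params = attr(profile, "params")) {
  stopifnot(inherits(profile, "insulation_profile"))
  if (all(is.na(profile$delta))) profile <- delta_vector(profile, params)
  delta <- profile$delta
  score <- profile$score
  n <- length(delta)
  out <- list()
  for (i in seq_len(n - 1L)) {
    if (is.na(delta[i]) || is.na(delta[i + 1L])) next
    if (!(delta[i] < 0 && delta[i + 1L] >= 0)) next
    # boundary bin: lowest-scoring valid bin around the crossing, so a
    # masked (e.g. deleted) crossing bin resolves to its nearest valid
    # neighbour
    cand <- max(1L, i - 2L):min(n, i + 3L)
    cand <- cand[profile$valid[cand]]
    if (length(cand) == 0L) next
    b <- cand[which.min(score[cand])]
    lo <- i
    while (lo - 1L >= 1L && !is.na(delta[lo - 1L]) && delta[lo - 1L] <= delta[lo]) {
      lo <- lo - 1L
    }
    hi <- i + 1L
    while (hi + 1L <= n && !is.na(delta[hi + 1L]) && delta[hi + 1L] >= delta[hi]) {
      hi <- hi + 1L
    }
    strength <- delta[hi] - delta[lo]
    if (strength < params$strength_cutoff) next
    m <- params$boundary_margin
    near <- max(1L, b - m):min(n, b + m)
    if (any(!profile$valid[near])) next
    out[[length(out) + 1L]] <- tibble::tibble(
      bin = b, chrom = profile$chrom[b], start = profile$start[b],
      end = profile$end[b], strength = strength)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(bin = integer(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strength = numeric()))
  }
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$bin) |>                # two crossings can resolve
    dplyr::slice_max(.data$strength, n = 1,      # to the same valid bin
                     with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$start)
}

#' Boundary strength nearest a region
#'
#' Convenience lookup for dot-plot style comparisons of one boundary
#' across conditions: the strength of the called boundary whose bin lies
#' nearest the region midpoint, searching within `pad` bp.
#'
#' @param profile An insulation profile (delta computed on the fly if
#'   needed).
#' @param locus Region of interest.
#' @param params The [insulation_params()].
#' @param pad Search radius around the region midpoint, bp (default: one
#'   insulation square).
#' @return The strength, or `NA_real_` when no boundary lies within `pad`.
#' @export
boundary_strength_at <- function(profile, locus, params = attr(profile, "params"),
                                 pad = NULL) {
  locus <- as_region(locus)
  pad <- pad %||% params$square_size
  b <- call_boundaries(profile, params)
  if (nrow(b) == 0L) return(NA_real_)
  mid <- region_midpoint(locus)
  d <- abs((b$start + b$end) / 2 - mid)
  if (min(d) > pad) return(NA_real_)
  b$strength[which.min(d)]
}

#' Tile an extent into TADs between called boundaries
#'
#' @param boundaries A [call_boundaries()] tibble.
#' @param extent Analyzed region.
#' @return A tibble of `n_boundaries + 1` contiguous domains covering
#'   `extent` in genomic order.
#' @export
tads_from_boundaries <- function(boundaries, extent) {
  extent <- as_region(extent)
  cuts <- sort(unique(pmin(pmax(
    (boundaries$start + boundaries$end) / 2, extent$start), extent$end)))
  edges <- c(extent$start, cuts, extent$end)
  edges <- unique(edges)
  tibble::tibble(chrom = extent$chrom,
                 start = edges[-length(edges)],
                 end = edges[-1])
}
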