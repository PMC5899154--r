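new_pair_comparison <- function(test, statistic, p_value, n_a, n_b,
                                degenerate = FALSE, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n_a = n_a, n_b = n_b,
                 degenerate = degenerate, ...),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s: statistic = %.4g, p = %.4g (n = %d vs %d)%s\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Inter-TAD contact values between two domains
#'
#' Flattens the rectangular block of the contact map linking two disjoint
#' TADs, row-major, dropping masked entries — the per-bin-pair sample used
#' to compare cross-boundary interaction frequency between conditions.
#'
#' @param map Intra-chromosomal [contact_map()].
#' @param tad_a,tad_b Disjoint domains within the map extent.
#' @return Numeric vector of unmasked contact values.
#' @export
inter_tad_values <- function(map, tad_a, tad_b) {
  stopifnot(inherits(map, "contact_map"))
  tad_a <- as_region(tad_a)
  tad_b <- as_region(tad_b)
  if (regions_overlap(tad_a, tad_b)) abort("TADs must be disjoint.")
  ri <- local_bins(map, snap_region(tad_a, map$bin_size), "row")
  ci <- local_bins(map, snap_region(tad_b, map$bin_size), "col")
  vals <- as.vector(t(map$values[ri, ci, drop = FALSE]))
  vals[!is.na(vals)]
}

#' Compare inter-TAD interaction frequency between conditions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on the per-bin-pair
#' contact values of the same domain pair in two conditions — e.g.
#' wild-type versus knockout — sensitive to a boundary-weakening shift in
#' cross-boundary contact frequency.
#'
#' @param a,b Numeric value vectors (e.g. from [inter_tad_values()]).
#' @return A `pair_comparison`; `degenerate = TRUE` with `p = 1` when all
#'   pooled values are identical.
#' @export
compare_inter_tad <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) abort("Both samples must be non-empty.")
  pooled <- c(a, b)
  if (all(pooled == pooled[1])) {
    return(new_pair_comparison("Wilcoxon rank-sum", NA_real_, 1,
                               length(a), length(b), degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  new_pair_comparison("Wilcoxon rank-sum", wt$statistic, wt$p.value,
                      length(a), length(b))
}

#' Peak counts in sliding windows
#'
#' Counts peaks per window slid across an extent, assigning each peak to
#' windows by its midpoint — with the default non-overlapping tiling
#' (`step = window_size`) every in-extent peak is counted exactly once.
#' This is the windowed CTCF-density statistic used to rank a locus
#' against the rest of a chromosome.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`; see [read_peaks()]).
#' @param extent Region to tile.
#' @param window_size Window width, bp.
#' @param step Step between window starts, bp (default `window_size`).
#' @return A `window_density` tibble: `window`, `chrom`, `start`, `end`,
#'   `count`.
#' @export
peak_density_windows <- function(peaks, extent, window_size,
                                 step = window_size) {
  extent <- as_region(extent)
  stopifnot(step > 0, window_size > 0)
  if (window_size > region_width(extent)) {
    abort("`window_size` exceeds the extent.")
  }
  n_win <- floor((region_width(extent) - window_size) / step) + 1
  starts <- extent$start + (seq_len(n_win) - 1) * step
  mids <- with(peaks[peaks$chrom == extent$chrom, , drop = FALSE],
               floor((start + end) / 2))
  mids <- mids[mids >= extent$start & mids < extent$end]
  count <- vapply(starts, function(s) {
    sum(mids >= s & mids < s + window_size)
  }, numeric(1))
  structure(tibble::tibble(window = seq_len(n_win), chrom = extent$chrom,
                           start = starts, end = starts + window_size,
                           count = count),
            class = c("window_density", class(tibble::tibble())),
            window_size = window_size, step = step, extent = extent)
}

#' Rank of the window containing a locus
#'
#' Descending rank (1 = densest) and empirical quantile of the window
#' containing the locus midpoint, with mid-rank averaging over ties; the
#' quantile is `(n - rank + 1) / n`, so a unique maximum scores 1.
#'
#' @param track A [peak_density_windows()] result.
#' @param locus Region of interest within the track extent.
#' @return A one-row tibble: `window`, `count`, `rank`, `quantile`.
#' @export
window_rank <- function(track, locus) {
  locus <- as_region(locus)
  mid <- region_midpoint(locus)
  hit <- which(track$start <= mid & mid < track$end)
  if (length(hit) == 0L) abort("Locus midpoint is outside every window.")
  # overlapping windows: take the window whose center is nearest
  hit <- hit[which.min(abs((track$start[hit] + track$end[hit]) / 2 - mid))]
  ranks <- rank(-track$count, ties.method = "average")
  n <- nrow(track)
  tibble::tibble(window = track$window[hit], count = track$count[hit],
                 rank = ranks[hit], quantile = (n - ranks[hit] + 1) / n)
}

#' Chi-square test of colocalization proportions
#'
#' Pearson chi-square test (no continuity correction unless requested) on
#' the 2x2 table of colocalized versus non-colocalized nuclei in two
#' conditions.
#'
#' @param k_a,n_a Colocalized count and total nuclei in condition A.
#' @param k_b,n_b Same for condition B.
#' @param correct Apply the Yates continuity correction.
#' @return A `pair_comparison` carrying the proportions; degenerate (with
#'   statistic 0, p 1) when an outcome is absent from both groups.
#' @export
colocalization_test <- function(k_a, n_a, k_b, n_b, correct = FALSE) {
  if (n_a <= 0 || n_b <= 0) abort("Group totals must be positive.")
  if (k_a < 0 || k_a > n_a || k_b < 0 || k_b > n_b) {
    abort("Counts must satisfy 0 <= k <= n.")
  }
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    return(new_pair_comparison("Pearson chi-square", 0, 1, n_a, n_b,
                               degenerate = TRUE,
                               prop_a = k_a / n_a, prop_b = k_b / n_b))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  new_pair_comparison("Pearson chi-square", ct$statistic, ct$p.value,
                      n_a, n_b, prop_a = k_a / n_a, prop_b = k_b / n_b)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control sample.
#' @return Fold change `2^-((dCt_case) - (dCt_ctrl))`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}

#' Span of a loxP-style deletion from its two cut sites
#'
#' Distance from the downstream edge of the 5' cut point to the upstream
#' edge of the 3' cut point, i.e. the sequence removed by recombination
#' between two inserted cassettes, with kb rounded half-up.
#'
#' @param cut5,cut3 Cut-site regions (5' first).
#' @return A one-row tibble: `span_bp`, `span_kb`.
#' @export
deletion_span <- function(cut5, cut3) {
  cut5 <- as_region(cut5)
  cut3 <- as_region(cut3)
  if (cut5$chrom != cut3$chrom) abort("Cut sites must share a chromosome.")
  if (cut3$start < cut5$end) abort("5' cut site must precede the 3' cut site.")
  bp <- cut3$start - cut5$end
  tibble::tibble(span_bp = bp, span_kb = floor(bp / 1000 + 0.5))
}
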