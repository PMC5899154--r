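#' Call enriched genomic bins from a cassette contact profile
#'
#' Detects transgene insertion sites as bins whose contact count with the
#' cassette contig exceeds the inter-chromosomal background. The
#' background rate per chromosome is the median bin count (robust to the
#' pileups themselves); each bin gets an upper-tail Poisson probability,
#' Benjamini-Hochberg adjusted across all bins of the profile, and bins
#' below `alpha` are merged into sites when separated by at most one
#' non-enriched bin.
#'
#' @param profile A cassette contact profile tibble — `condition`,
#'   `chrom`, `bin`, `start`, `end`, `count` (see
#'   [sample_cassette_profile()]), one row per genomic bin.
#' @param alpha Adjusted-p call threshold.
#' @return An `insertion_calls` tibble: `condition`, `chrom`, `start`,
#'   `end`, `n_bins`, `max_count`, `score` (-log10 adjusted tail
#'   probability of the site's maximal bin).
#' @export
call_enriched_bins <- function(profile, alpha = 1e-6) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(profile)))
  if (nrow(profile) < 100L) {
    abort("Need at least 100 bins to estimate the background.")
  }
  if (all(profile$count == 0)) return(empty_insertion_calls())
  prof <- dplyr::group_by(profile, .data$chrom) |>
    dplyr::mutate(lambda = median(.data$count)) |>
    dplyr::ungroup()
  # P(X >= count | lambda); lambda 0 handled as: any positive count is a hit
  pr <- ifelse(prof$lambda == 0,
               ifelse(prof$count > 0, 0, 1),
               ppois(prof$count - 1, prof$lambda, lower.tail = FALSE))
  prof$p_adj <- p.adjust(pr, method = "BH")
  prof$enriched <- prof$p_adj < alpha
  if (!any(prof$enriched)) return(empty_insertion_calls())
  cond <- if ("condition" %in% names(prof)) prof$condition[1] else NA_character_

  calls <- prof |>
    dplyr::filter(.data$enriched) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    # join runs separated by <= 1 non-enriched bin (gap <= 2 bins of coords)
    dplyr::mutate(gap = .data$start - dplyr::lag(.data$end, default = -Inf),
                  site = cumsum(.data$gap > (.data$end - .data$start) + 1e-9)) |>
    dplyr::group_by(.data$chrom, .data$site) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_bins = dplyr::n(), max_count = max(.data$count),
                     score = -log10(pmax(.data$p_adj[which.max(.data$count)],
                                         1e-300)),
                     .groups = "drop") |>
    dplyr::select(-"site") |>
    dplyr::arrange(.data$chrom, .data$start)
  calls <- dplyr::bind_cols(tibble::tibble(condition = rep(cond, nrow(calls))),
                            calls)
  structure(calls, class = c("insertion_calls", class(tibble::tibble())),
            alpha = alpha)
}

empty_insertion_calls <- function() {
  structure(tibble::tibble(condition = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           n_bins = integer(), max_count = numeric(),
                           score = numeric()),
            class = c("insertion_calls", class(tibble::tibble())))
}

#' Insertion sites consistent between two conditions
#'
#' Keeps the calls of condition A that overlap (by at least 1 bp) a call
#' in condition B — the cross-condition consistency filter that separates
#' genuine cassette insertion sites from condition-specific noise. The
#' reported score is the smaller of the two supporting scores.
#'
#' @param calls_a,calls_b [call_enriched_bins()] results for the two
#'   conditions (same genome and bin size).
#' @return An `insertion_calls` tibble with `support_a`/`support_b` flags.
#' @export
consistent_insertions <- function(calls_a, calls_b) {
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) {
    out <- empty_insertion_calls()
    out$support_a <- logical()
    out$support_b <- logical()
    return(out)
  }
  rows <- purrr::map_dfr(seq_len(nrow(calls_a)), function(k) {
    hits <- which(calls_b$chrom == calls_a$chrom[k] &
                    calls_b$start < calls_a$end[k] &
                    calls_a$start[k] < calls_b$end)
    if (length(hits) == 0L) return(NULL)
    best <- hits[which.max(calls_b$score[hits])]
    dplyr::mutate(calls_a[k, ],
                  score = min(calls_a$score[k], calls_b$score[best]),
                  support_a = TRUE, support_b = TRUE)
  })
  if (nrow(rows) == 0L) {
    rows <- empty_insertion_calls()
    rows$support_a <- logical()
    rows$support_b <- logical()
  }
  structure(rows, class = c("insertion_calls", class(tibble::tibble())))
}

#' Per-chromosome insertion-site summary
#'
#' @param calls An `insertion_calls` tibble.
#' @return A tibble `chrom`, `n_sites` with one row per chromosome
#'   carrying at least one site; the number of rows is the number of
#'   chromosomes with insertions.
#' @export
insertion_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(chrom = character(), n_sites = integer()))
  }
  dplyr::count(tibble::as_tibble(calls), .data$chrom, name = "n_sites") |>
    dplyr::arrange(.data$chrom)
}
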