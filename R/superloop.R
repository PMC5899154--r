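#' Sliding-window specification
#'
#' Geometry of the rectangular bin window used for long-range interaction
#' testing: a block of `n_rows` x `n_cols` bins centered on an anchor
#' locus pair. The default 6 x 7 window at 40 kb bins covers 42 bin
#' pairs, the size used for testing a focal interaction between two loci
#' tens of Mb apart against the surrounding background.
#'
#' @param anchor_row,anchor_col Anchor regions on the row / column axis;
#'   the window is centered on the bins containing their midpoints, with
#'   the extra row/column on the downstream side when a dimension is
#'   even.
#' @param n_rows,n_cols Window dimensions in bins (`n_rows * n_cols >= 2`
#'   so a t-test is possible).
#' @return A `window_spec` object.
#' @export
window_spec <- function(anchor_row, anchor_col, n_rows = 6L, n_cols = 7L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_rows * n_cols >= 2L)
  structure(list(anchor_row = as_region(anchor_row),
                 anchor_col = as_region(anchor_col),
                 n_rows = n_rows, n_cols = n_cols),
            class = "window_spec")
}

# local 1-based index span of a window of n bins centered on bin `center`
# (extra bin downstream for even n)
window_span <- function(center, n) {
  (center - floor((n - 1) / 2)):(center + ceiling((n - 1) / 2))
}

#' Extract the target-window values around an anchor pair
#'
#' Returns the `n_rows * n_cols` contact values of the window centered on
#' the anchor bin pair, flattened row-major; masked entries are `NA`.
#'
#' @param map A [contact_map()] containing the window.
#' @param spec A [window_spec()].
#' @return Numeric vector of length `n_rows * n_cols`.
#' @export
extract_target_window <- function(map, spec) {
  stopifnot(inherits(map, "contact_map"), inherits(spec, "window_spec"))
  cr <- anchor_bin(map, spec$anchor_row, "row")
  cc <- anchor_bin(map, spec$anchor_col, "col")
  ri <- window_span(cr, spec$n_rows)
  ci <- window_span(cc, spec$n_cols)
  if (min(ri) < 1L || max(ri) > nrow(map$values) ||
      min(ci) < 1L || max(ci) > ncol(map$values)) {
    abort("Anchored window exceeds the map extent.")
  }
  as.vector(t(map$values[ri, ci, drop = FALSE]))
}

anchor_bin <- function(map, anchor, axis) {
  r <- if (axis == "row") map$row_region else map$col_region
  anchor <- as_region(anchor)
  mid <- region_midpoint(anchor)
  if (anchor$chrom != r$chrom || mid < r$start || mid >= r$end) {
    abort(sprintf("Anchor %s is outside the map %s extent.",
                  format(anchor), axis))
  }
  as.integer(point_bin(mid, map$bin_size) - r$start / map$bin_size + 1L)
}

# Welch two-sample t-test with explicit degenerate-input rules:
# both samples constant -> p = 1 if equal, p = 0 otherwise; a single
# constant sample falls through to Welch with an epsilon variance guard.
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) return(c(t = NA_real_, p = NA_real_))
  vx <- var(x)
  vy <- var(y)
  mx <- mean(x)
  my <- mean(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(c(t = 0, p = 1))
    return(c(t = sign(mx - my) * Inf, p = 0))
  }
  eps <- .Machine$double.eps * max(1, abs(mx), abs(my))^2
  vx <- max(vx, eps)
  vy <- max(vy, eps)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(t = tt, p = 2 * pt(-abs(tt), df))
}

#' Slide a window across a heatmap, t-testing against a target
#'
#' Slides the window bin-by-bin over every top-left position of the
#' heatmap and Welch-t-tests each window's unmasked values against the
#' target values (e.g. the window over a candidate long-range loop).
#' A position is flagged invalid when more than half of its entries are
#' masked, or — on an intra-chromosomal map — when the window touches the
#' diagonal, where distance decay rather than focal looping would drive
#' the test.
#'
#' @param map A [contact_map()].
#' @param spec A [window_spec()] (its anchors locate the target position;
#'   the slide covers the whole map regardless).
#' @param target Target values, length `n_rows * n_cols`; defaults to the
#'   window extracted at the spec's anchors.
#' @return A `sliding_window_result` tibble with one row per top-left
#'   position: `row`, `col` (1-based bin indices), `row_start`,
#'   `col_start` (bp), `t`, `p`, `valid`.
#' @export
slide_window_test <- function(map, spec, target = NULL) {
  stopifnot(inherits(map, "contact_map"), inherits(spec, "window_spec"))
  target <- target %||% extract_target_window(map, spec)
  if (length(target) != spec$n_rows * spec$n_cols) {
    abort("`target` length must equal n_rows * n_cols.")
  }
  tgt <- target[!is.na(target)]
  v <- map$values
  nr <- spec$n_rows
  nc <- spec$n_cols
  R <- nrow(v) - nr + 1L
  C <- ncol(v) - nc + 1L
  if (R < 1L || C < 1L) abort("Map extent is smaller than the window.")
  intra <- is_intra(map)
  pos <- expand.grid(row = seq_len(R), col = seq_len(C))
  n_pos <- nrow(pos)
  tstat <- rep(NA_real_, n_pos)
  pval <- rep(NA_real_, n_pos)
  valid <- rep(FALSE, n_pos)
  for (k in seq_len(n_pos)) {
    i <- pos$row[k]
    j <- pos$col[k]
    win <- v[i:(i + nr - 1L), j:(j + nc - 1L)]
    if (mean(is.na(win)) > 0.5) next
    if (intra && i <= j + nc - 1L && j <= i + nr - 1L) next  # touches diagonal
    res <- welch_t(as.vector(win), tgt)
    tstat[k] <- res[["t"]]
    pval[k] <- res[["p"]]
    valid[k] <- !is.na(res[["p"]])
  }
  rb <- map_bins(map, "row")
  cb <- map_bins(map, "col")
  out <- tibble::tibble(row = pos$row, col = pos$col,
                        row_start = rb$start[pos$row],
                        col_start = cb$start[pos$col],
                        t = tstat, p = pval, valid = valid)
  structure(out, class = c("sliding_window_result", class(tibble::tibble())),
            spec = spec, bin_size = map$bin_size,
            row_region = map$row_region, col_region = map$col_region,
            target = target)
}

#' Compare sliding-window p-value distributions across conditions
#'
#' One-way ANOVA on the per-position p-values of two or more
#' [slide_window_test()] results: a condition in which the target window
#' is genuinely enriched yields a p-value density piled near zero, and
#' the ANOVA asks whether the conditions' p-value distributions differ.
#' Per-condition kernel density summaries are returned for plotting.
#'
#' @param results List of `sliding_window_result` objects.
#' @param labels Condition labels (defaults to list names).
#' @param valid_only Use only positions flagged valid (default) or all
#'   positions with a p-value.
#' @return A `pvalue_density_comparison`: list with `f_statistic`, `p_value`,
#'   `df`, a `samples` tibble (`label`, `p`) and a `densities` tibble
#'   (`label`, `x`, `y`).
#' @export
compare_pvalue_densities <- function(results, labels = NULL,
                                     valid_only = TRUE) {
  if (length(results) < 2L) abort("Need at least two conditions.")
  labels <- labels %||% names(results) %||% paste0("condition_", seq_along(results))
  samples <- purrr::map2_dfr(results, labels, function(r, lab) {
    p <- if (valid_only) r$p[r$valid] else r$p[!is.na(r$p)]
    if (length(p) < 2L) {
      abort(sprintf("Condition '%s' has fewer than 2 valid positions.", lab))
    }
    tibble::tibble(label = lab, p = p)
  })
  samples$label <- factor(samples$label, levels = labels)
  fit <- anova(lm(p ~ label, data = samples))
  densities <- dplyr::group_by(samples, .data$label) |>
    dplyr::reframe({
      d <- density(.data$p, from = 0, to = 1)
      tibble::tibble(x = d$x, y = d$y)
    }) |>
    dplyr::ungroup()
  structure(list(f_statistic = fit$`F value`[1],
                 p_value = fit$`Pr(>F)`[1],
                 df = c(fit$Df[1], fit$Df[2]),
                 samples = samples, densities = densities),
            class = "pvalue_density_comparison")
}

#' @export
print.pvalue_density_comparison <- function(x, ...) {
  cat(sprintf("<pvalue_density_comparison> one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("  conditions: %s\n",
              paste(levels(x$samples$label), collapse = ", ")))
  invisible(x)
}

#' Pairwise super-loop quantification
#'
#' For each unordered pair of labeled anchor loci (classically Firre,
#' DXZ4, x75 and ICCE on the inactive X), flattens the contact values of
#' the rectangle spanned by the two padded regions — the per-bin-pair
#' sample whose size is the product of the padded bin spans (e.g. 4 x 3
#' bins = n 12 at 100 kb bins with a 100 kb pad).
#'
#' @param map A [contact_map()] (typically 100 kb bins).
#' @param regions Named list of anchor regions.
#' @param pad Symmetric pad added to each region before snapping, bp.
#' @return A `superloop_quant` tibble: `pair`, `region_a`, `region_b`,
#'   `n`, `mean`, `values` (list column; masked entries kept as `NA`).
#' @export
superloop_quant <- function(map, regions, pad = 100e3) {
  stopifnot(inherits(map, "contact_map"), pad >= 0)
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    abort("`regions` must be a named list.")
  }
  regions <- lapply(regions, as_region)
  padded <- lapply(regions, function(r) {
    snap_region(region(r$chrom, max(0, r$start - pad), r$end + pad),
                map$bin_size)
  })
  labs <- names(regions)
  combs <- utils::combn(seq_along(regions), 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]
    b <- combs[2, k]
    if (regions_overlap(padded[[a]], padded[[b]])) {
      abort(sprintf("Padded regions %s and %s overlap.", labs[a], labs[b]))
    }
    ri <- local_bins(map, padded[[a]], "row")
    ci <- local_bins(map, padded[[b]], "col")
    vals <- as.vector(t(map$values[ri, ci, drop = FALSE]))
    tibble::tibble(pair = paste(labs[a], labs[b], sep = "-"),
                   region_a = format(padded[[a]]),
                   region_b = format(padded[[b]]),
                   n = length(vals), mean = mean(vals, na.rm = TRUE),
                   values = list(vals))
  })
  structure(dplyr::bind_rows(rows),
            class = c("superloop_quant", class(tibble::tibble())),
            pad = pad, bin_size = map$bin_size)
}

#' Compare super-loop quantifications between two conditions
#'
#' Welch two-sided t-test per region pair on the bin-pair contact values
#' of two [superloop_quant()] results (e.g. wild-type vs knockout), plus
#' the condition-B / condition-A mean ratio.
#'
#' @param a,b `superloop_quant` tibbles over the same region pairs.
#' @return A tibble: `pair`, `n`, `mean_a`, `mean_b`, `ratio` (`b`/`a`),
#'   `t`, `p_value`, `degenerate`.
#' @export
compare_superloop <- function(a, b) {
  stopifnot(inherits(a, "superloop_quant"), inherits(b, "superloop_quant"))
  if (!identical(a$pair, b$pair)) abort("Quantifications cover different pairs.")
  purrr::map_dfr(seq_len(nrow(a)), function(k) {
    va <- a$values[[k]]
    vb <- b$values[[k]]
    if (length(va) != length(vb)) {
      abort(sprintf("Pair %s has different n in the two conditions.", a$pair[k]))
    }
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    res <- welch_t(vb, va)
    degen <- length(unique(c(va, vb))) == 1L
    tibble::tibble(pair = a$pair[k], n = a$n[k],
                   mean_a = mean(va), mean_b = mean(vb),
                   ratio = mean(vb) / mean(va),
                   t = res[["t"]], p_value = res[["p"]],
                   degenerate = degen)
  })
}
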