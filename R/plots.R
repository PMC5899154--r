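#' Heatmap of a contact map
#'
#' @param object A [contact_map()].
#' @param trans Fill transformation (`"log10"` with a pseudocount, or
#'   `"identity"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, trans = c("log10", "identity"), ...) {
  trans <- match.arg(trans)
  rb <- map_bins(object, "row")
  cb <- map_bins(object, "col")
  df <- tidyr::expand_grid(row = rb$bin, col = cb$bin)
  df$row_start <- rb$start[df$row]
  df$col_start <- cb$start[df$col]
  df$value <- as.vector(t(object$values))[
    (df$row - 1L) * ncol(object$values) + df$col]
  if (trans == "log10") df$value <- log10(df$value + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_start, y = .data$row_start,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (trans == "log10") "log10(contacts + 1)" else "contacts",
      na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = format(object$col_region), y = format(object$row_region)) +
    ggplot2::theme_minimal()
}

#' Insulation profile with called boundaries
#'
#' @param object An [insulation_score()] profile.
#' @param boundaries Optional [call_boundaries()] tibble to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insulation_profile <- function(object, boundaries = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[df$valid, ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "insulation score (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    p <- p + ggplot2::geom_vline(
      data = boundaries,
      ggplot2::aes(xintercept = (.data$start + .data$end) / 2),
      colour = "red", linetype = 3)
  }
  p
}

#' Grid of sliding-window significance
#'
#' @param object A [slide_window_test()] result.
#' @param ... Unused.
#' @return A ggplot object showing `-log10(p)` per window position.
#' @export
autoplot.sliding_window_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglog_p <- ifelse(df$valid, -log10(pmax(df$p, 1e-300)), NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_start, y = .data$row_start,
                                   fill = .data$neglog_p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p", na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "window column start (bp)", y = "window row start (bp)") +
    ggplot2::theme_minimal()
}

#' Per-condition p-value density curves
#'
#' @param x A [compare_pvalue_densities()] result.
#' @return A ggplot object of the kernel densities, annotated with the
#'   ANOVA p-value.
#' @export
plot_pvalue_densities <- function(x) {
  stopifnot(inherits(x, "pvalue_density_comparison"))
  ggplot2::ggplot(x$densities, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sliding-window t-test p-value", y = "density",
                  colour = NULL,
                  subtitle = sprintf("one-way ANOVA p = %.3g", x$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplot of windowed peak counts with a highlighted locus
#'
#' @param track A [peak_density_windows()] result.
#' @param locus Optional region whose window is marked as a red point.
#' @return A ggplot object.
#' @export
plot_window_density <- function(track, locus = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(track),
                       ggplot2::aes(x = "", y = .data$count)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "peaks per window") +
    ggplot2::theme_minimal()
  if (!is.null(locus)) {
    wr <- window_rank(track, locus)
    p <- p + ggplot2::geom_point(data = wr,
                                 ggplot2::aes(x = "", y = .data$count),
                                 colour = "red", size = 2)
  }
  p
}
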