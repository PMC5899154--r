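#' Tidy a pairwise comparison
#'
#' @param x A `pair_comparison` (from [compare_inter_tad()],
#'   [colocalization_test()], ...).
#' @param ... Unused.
#' @return A one-row tibble with `test`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `degenerate`, plus any test-specific extras (e.g.
#'   proportions).
#' @export
tidy.pair_comparison <- function(x, ...) {
  extras <- x[setdiff(names(x),
                      c("test", "statistic", "p_value", "n_a", "n_b",
                        "degenerate"))]
  out <- tibble::tibble(test = x$test, statistic = x$statistic,
                        p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
                        degenerate = x$degenerate)
  if (length(extras)) out <- dplyr::bind_cols(out, tibble::as_tibble(extras))
  out
}

#' @rdname tidy.pair_comparison
#' @export
glance.pair_comparison <- function(x, ...) tidy(x, ...)

#' Tidy a p-value density comparison
#'
#' @param x A [compare_pvalue_densities()] result.
#' @param ... Unused.
#' @return `tidy()`: per-condition summary (`label`, `n`, `mean_p`,
#'   `frac_below_05`). `glance()`: one row with the ANOVA `f_statistic`,
#'   `df1`, `df2`, `p_value`.
#' @export
tidy.pvalue_density_comparison <- function(x, ...) {
  dplyr::group_by(x$samples, .data$label) |>
    dplyr::summarise(n = dplyr::n(), mean_p = mean(.data$p),
                     frac_below_05 = mean(.data$p < 0.05), .groups = "drop")
}

#' @rdname tidy.pvalue_density_comparison
#' @export
glance.pvalue_density_comparison <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 p_value = x$p_value)
}
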