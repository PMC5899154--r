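test_that("target-window extraction has the right geometry and values", {
  spec <- synthetic_spec(region("chrX", 0, 4e6), 40e3, depth = 2e5)
  cm <- sample_map(spec, 21)
  ws <- window_spec(region("chrX", 1e6, 1.04e6), region("chrX", 3e6, 3.04e6))
  expect_length(extract_target_window(cm, ws), 42L)
  # 1x2 window on known entries: center bin contains the anchor midpoint,
  # the extra column goes downstream
  ws12 <- window_spec(region("chrX", 1e6, 1.04e6), region("chrX", 3e6, 3.04e6),
                      n_rows = 1, n_cols = 2)
  expect_equal(extract_target_window(cm, ws12), cm$values[26, 76:77])
  # constant matrix -> 42 copies of the constant
  cc <- contact_map(matrix(7, 100, 100), region("chrX", 0, 4e6),
                    bin_size = 40e3)
  expect_equal(extract_target_window(cc, ws), rep(7, 42))
  # window pushed over the edge errors
  expect_error(
    extract_target_window(cm, window_spec(region("chrX", 0, 40e3),
                                          region("chrX", 3e6, 3.04e6))),
    "exceeds")
})

test_that("sliding grid covers every bin-by-bin position", {
  s <- loop_test_specs(depth = 2e5)
  cm <- sample_map(s$male, 31)
  expect_equal(dim(cm), c(50L, 50L))
  res <- slide_window_test(cm, s$window)
  expect_equal(nrow(res), (50 - 6 + 1) * (50 - 7 + 1))  # 45 * 44 = 1980
  expect_true(all(res$p[res$valid] >= 0 & res$p[res$valid] <= 1))
  # self-comparison at the target's own position gives p = 1 exactly
  expect_true(any(res$p == 1 & res$t == 0, na.rm = TRUE))
})

test_that("degenerate windows follow the zero-variance rules", {
  cc <- contact_map(matrix(5, 20, 30), region("chrX", 0, 0.8e6),
                    region("chrX", 2e6, 3.2e6), bin_size = 40e3)
  ws <- window_spec(region("chrX", 0.4e6, 0.44e6), region("chrX", 2.4e6, 2.5e6))
  res <- slide_window_test(cc, ws)
  expect_true(all(res$p[res$valid] == 1))
  # constant but unequal -> p = 0
  cc2 <- cc
  res2 <- slide_window_test(cc2, ws, target = rep(9, 42))
  expect_true(all(res2$p[res2$valid] == 0))
})

test_that("intra-map positions touching the diagonal are invalid", {
  spec <- synthetic_spec(region("chrX", 0, 1.2e6), 40e3, depth = 1e5)
  cm <- sample_map(spec, 77)
  ws <- window_spec(region("chrX", 0.1e6, 0.14e6), region("chrX", 1e6, 1.04e6),
                    n_rows = 2, n_cols = 2)
  res <- slide_window_test(cm, ws)
  bad <- res[!res$valid, ]
  expect_true(all(abs(bad$row - bad$col) <= 2))
  expect_true(all(res$valid[abs(res$row - res$col) > 2]))
})

test_that("enriched target shifts the p-value density (ANOVA detects it)", {
  s <- loop_test_specs(depth = 5e5, fold = 5)
  wt <- slide_window_test(sample_map(s$wt, 101), s$window)
  ko <- slide_window_test(sample_map(s$ko, 102), s$window)
  male <- slide_window_test(sample_map(s$male, 103), s$window)
  # planted enrichment: more significant positions in WT than in male
  expect_gt(mean(wt$p[wt$valid] < 0.05), mean(male$p[male$valid] < 0.05))
  cmp <- compare_pvalue_densities(list(WT = wt, KO = ko, male = male))
  expect_lt(cmp$p_value, 0.05)
  expect_equal(levels(cmp$samples$label), c("WT", "KO", "male"))
  # identical grids across conditions -> F ~ 0, p ~ 1
  same <- compare_pvalue_densities(list(a = male, b = male, c = male))
  expect_lt(abs(same$f_statistic), 1e-9)
  expect_gt(same$p_value, 0.999)
})

test_that("two-condition ANOVA equals the squared pooled t-test", {
  s <- loop_test_specs(depth = 2e5)
  a <- slide_window_test(sample_map(s$male, 7), s$window)
  b <- slide_window_test(sample_map(s$male, 8), s$window)
  cmp <- compare_pvalue_densities(list(a = a, b = b))
  tt <- t.test(a$p[a$valid], b$p[b$valid], var.equal = TRUE)
  expect_equal(cmp$f_statistic, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("super-loop pair quantification yields the documented n", {
  spec <- synthetic_spec(region("chrX", 0, 80e6), 100e3, depth = 2e6)
  cm <- sample_map(spec, 55)
  regions <- list(
    Firre = region("chrX", 47.88e6, 47.97e6),  # crosses a bin edge: 2 bins
    DXZ4  = region("chrX", 72.9e6, 72.99e6),
    x75   = region("chrX", 60.0e6, 60.09e6),
    ICCE  = region("chrX", 30.0e6, 30.09e6))
  q <- superloop_quant(cm, regions, pad = 100e3)
  expect_equal(nrow(q), 6L)
  ns <- setNames(q$n, q$pair)
  # Firre spans 2 bins + 1 pad bin each side = 4; the others span 1 + 2 = 3
  expect_equal(unname(ns["Firre-DXZ4"]), 12L)
  expect_equal(unname(ns["DXZ4-x75"]), 9L)
  expect_equal(unname(ns["Firre-x75"]), 12L)
  expect_true(all(q$n == vapply(q$values, length, 1L)))
  # constant matrix -> every pair sees the same value
  cc <- contact_map(matrix(2, 800, 800), region("chrX", 0, 80e6),
                    bin_size = 100e3)
  qc <- superloop_quant(cc, regions, pad = 100e3)
  expect_true(all(vapply(qc$values, function(v) all(v == 2), logical(1))))
  # overlapping padded regions are rejected
  expect_error(superloop_quant(cm, list(a = region("chrX", 1e6, 1.1e6),
                                        b = region("chrX", 1.25e6, 1.35e6)),
                               pad = 100e3),
               "overlap")
})

test_that("super-loop comparison reports ratio and symmetric p", {
  regions <- list(A = region("chrX", 10e6, 10.1e6),
                  B = region("chrX", 40e6, 40.1e6),
                  C = region("chrX", 60e6, 60.1e6))
  base <- synthetic_spec(region("chrX", 0, 80e6), 100e3, depth = 5e7)
  loop <- synthetic_spec(region("chrX", 0, 80e6), 100e3, depth = 5e7,
                         loops = list(list(anchor_row = regions$A,
                                           anchor_col = regions$B, fold = 5,
                                           n_rows = 3, n_cols = 3)))
  wt <- superloop_quant(sample_map(loop, 61), regions)
  ko <- superloop_quant(sample_map(base, 62), regions)
  cmp <- compare_superloop(wt, ko)
  ab <- cmp[cmp$pair == "A-B", ]
  expect_lt(ab$ratio, 1)
  expect_lt(ab$p_value, 0.05)
  # pairs without the loop keep ratios near 1
  expect_true(all(abs(cmp$ratio[cmp$pair != "A-B"] - 1) < 0.35))
  # swapping conditions inverts the ratio and keeps p
  rev <- compare_superloop(ko, wt)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
  expect_equal(rev$ratio, 1 / cmp$ratio, tolerance = 1e-12)
  # identical quantifications are degenerate with ratio 1... (constant map)
  cc <- contact_map(matrix(2, 800, 800), region("chrX", 0, 80e6),
                    bin_size = 100e3)
  qc <- superloop_quant(cc, regions)
  same <- compare_superloop(qc, qc)
  expect_true(all(same$degenerate))
  expect_true(all(same$p_value == 1))
  expect_true(all(same$ratio == 1))
})
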