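params_40k <- insulation_params()  # 480 kb square, 320 kb delta, iqrMean

test_that("constant matrix scores zero everywhere and yields no boundary", {
  cm <- block_map(40, within = 4, between = 4)
  prof <- delta_vector(insulation_score(cm, params_40k))
  expect_true(all(abs(prof$score[prof$valid]) < 1e-12))
  expect_true(all(abs(prof$delta[!is.na(prof$delta)]) < 1e-12))
  expect_equal(nrow(call_boundaries(prof)), 0L)
})

test_that("two-TAD matrix has its score minimum at the junction", {
  cm <- block_map(c(20, 20), within = 10, between = 0)
  # plain mean aggregation: on an idealised all-or-nothing fixture the
  # iqrMean aggregator discards the minority within-TAD pixels entirely
  p <- insulation_params(aggregation = "mean")
  prof <- insulation_score(cm, p)
  # junction between bins 20 and 21
  expect_true(all(which(prof$score == min(prof$score, na.rm = TRUE))
                  %in% 20:21))
  b <- call_boundaries(delta_vector(prof), p)
  expect_equal(nrow(b), 1L)
  expect_true(b$bin %in% 20:21)
})

test_that("score normalisation and scale invariance hold", {
  cm <- random_map(60, seed = 41)
  prof <- insulation_score(cm, params_40k)
  expect_equal(mean(2^prof$score[prof$valid]), 1, tolerance = 1e-6)
  cm10 <- cm
  cm10$values <- cm$values * 10
  expect_equal(insulation_score(cm10, params_40k)$score, prof$score,
               tolerance = 1e-9)
})

test_that("iqrMean ignores a single outlier pixel where mean does not", {
  cm <- block_map(40, within = 5, between = 5)
  cm_out <- cm
  cm_out$values[10, 25] <- 500  # inside bin 18's square (rows 6..17 x cols 19..30)
  cm_out$values[25, 10] <- 500
  p <- insulation_params(aggregation = "iqrMean", smooth_span = 0)
  pm <- insulation_params(aggregation = "mean", smooth_span = 0)
  expect_equal(insulation_score(cm_out, p)$raw[18],
               insulation_score(cm, p)$raw[18])
  expect_gt(insulation_score(cm_out, pm)$raw[18],
            insulation_score(cm, pm)$raw[18])
})

test_that("delta vector tracks score shape", {
  cm <- random_map(60, seed = 13)
  prof <- insulation_score(cm, params_40k)
  # strictly increasing score -> positive delta wherever defined
  inc <- prof
  inc$score <- seq_len(60) / 10
  inc$valid <- rep(TRUE, 60)
  d <- delta_vector(inc)$delta
  expect_true(all(d[!is.na(d)] > 0))
  # V-shaped score -> delta sign change within 1 bin of the minimum
  v <- prof
  v$score <- abs(seq_len(60) - 30) / 10
  v$valid <- rep(TRUE, 60)
  dv <- delta_vector(v)$delta
  cross <- which(dv[-60] < 0 & dv[-1] >= 0)
  expect_true(any(abs(cross - 30) <= 1))
})

test_that("boundary strength orders junction weakness correctly", {
  p <- params_40k
  strong_weak <- block_map(c(20, 20, 20), within = 10, between = c(1, 6))
  b <- call_boundaries(delta_vector(insulation_score(strong_weak, p)))
  expect_equal(nrow(b), 2L)
  expect_true(all(abs(b$bin - c(20, 40)) <= 1))
  expect_gt(b$strength[1], b$strength[2])
  # raising inter-TAD contacts weakens the boundary
  wt <- block_map(c(20, 20), within = 10, between = 0.5)
  ko <- block_map(c(20, 20), within = 10, between = 5)
  locus <- region("chrX", 19 * 40e3, 21 * 40e3)
  s_wt <- boundary_strength_at(delta_vector(insulation_score(wt, p)), locus, p)
  s_ko <- boundary_strength_at(delta_vector(insulation_score(ko, p)), locus, p)
  expect_lt(s_ko, s_wt)
  # a TAD interior has no boundary within the search pad
  prof <- delta_vector(insulation_score(wt, p))
  expect_true(is.na(boundary_strength_at(prof, region("chrX", 0.3e6, 0.4e6),
                                         p, pad = 200e3)))
})

test_that("production insulation equals the brute-force oracle", {
  w <- 12L
  for (seed in 1:5) {
    cm <- random_map(60, seed = seed)
    for (mode in c("mean", "median", "iqrMean")) {
      p <- insulation_params(aggregation = mode, smooth_span = 0)
      got <- insulation_score(cm, p)$score
      want <- oracle_insulation(cm$values, w, mode)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("masking a locus only invalidates squares touching the mask", {
  cm <- random_map(60, seed = 8)
  p <- insulation_params(smooth_span = 0)
  before <- insulation_score(cm, p)
  masked <- mask_locus(cm, region("chrX", 30 * 40e3, 31 * 40e3))  # bin 31
  after <- insulation_score(masked, p)
  lost <- which(before$valid & !after$valid)
  # every lost bin's square (i-12..i-1 x i+1..i+12) or the bin itself
  # intersects masked bin 31
  expect_true(all(vapply(lost, function(i) {
    i == 31 || (31 >= i - 12 && 31 <= i + 12)
  }, logical(1))))
  # scores far from the mask are unchanged
  far <- which(after$valid & abs(seq_len(60) - 31) > 13)
  expect_equal(after$raw[far], before$raw[far], tolerance = 1e-9)
})

test_that("TAD tiling between boundaries conserves the extent", {
  ext <- region("chrX", 0, 2.4e6)
  b <- tibble::tibble(bin = c(20L, 40L), chrom = "chrX",
                      start = c(0.8e6, 1.6e6), end = c(0.84e6, 1.64e6))
  tads <- tads_from_boundaries(b, ext)
  expect_equal(nrow(tads), 3L)
  expect_equal(tads$start[1], ext$start)
  expect_equal(tads$end[3], ext$end)
  expect_equal(tads$start[-1], tads$end[-3])
  expect_equal(nrow(tads_from_boundaries(b[0, ], ext)), 1L)
})
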