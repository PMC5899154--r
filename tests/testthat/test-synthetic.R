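test_that("expected map follows the closed-form decay model", {
  spec <- synthetic_spec(region("chrX", 0, 2e6), 100e3, decay_exponent = 1,
                         depth = 1e5)
  e <- expected_map(spec)$values
  # alpha = 1: E[i,j] / E[i,k] = |i-k| / |i-j| exactly
  expect_equal(e[1, 5] / e[1, 11], 10 / 4, tolerance = 1e-12)
  expect_equal(e[3, 9] / e[3, 5], 2 / 6, tolerance = 1e-12)
  # deterministic and symmetric
  expect_equal(e, t(e))
  expect_equal(expected_map(spec)$values, e)
})

test_that("boundaries, loops and deletions edit the expectation locally", {
  ext <- region("chrX", 0, 4e6)
  base <- synthetic_spec(ext, 100e3, depth = 2e5)
  bnd <- synthetic_spec(ext, 100e3, depth = 2e5, tad_boundaries = 2e6,
                        boundary_insulation = 0.5)
  e0 <- expected_map(base)$values
  e1 <- expected_map(bnd)$values
  cross <- outer(seq_len(40) <= 20, seq_len(40) > 20, `&`)
  cross <- cross | t(cross)
  expect_equal(e1[cross], e0[cross] / 2, tolerance = 1e-12)
  expect_equal(e1[!cross], e0[!cross], tolerance = 1e-12)

  loopspec <- synthetic_spec(ext, 100e3, depth = 2e5,
                             loops = list(list(
                               anchor_row = region("chrX", 0.5e6, 0.6e6),
                               anchor_col = region("chrX", 3.5e6, 3.6e6),
                               fold = 10, n_rows = 2, n_cols = 2)))
  e2 <- expected_map(loopspec)$values
  changed <- which(abs(e2 - e0) > 1e-12, arr.ind = TRUE)
  expect_equal(sum(abs(e2 / e0 - 10) < 1e-9), 2 * 4)  # window + mirror
  expect_true(all(e2[changed] > e0[changed]))

  ko <- ko_spec(loopspec, region("chrX", 0.5e6, 0.6e6))
  expect_length(ko$loops, 0L)
  e3 <- expected_map(ko)$values
  del <- 6  # bin containing 0.5-0.6 Mb
  expect_true(all(e3[del, ] == 0))
  expect_true(all(e3[, del] == 0))
  # WT and KO expectations differ only at the deletion and loop windows
  diff_bins <- which(abs(e3 - e2) > 1e-12, arr.ind = TRUE)
  expect_true(all(diff_bins[, 1] == del | diff_bins[, 2] == del |
                    (abs(e2 / pmax(e3, 1e-300) - 10) < 1e-6)[diff_bins]))
  # boundary-preserving KO keeps the TAD partition
  expect_equal(ko_spec(bnd, region("chrX", 1.95e6, 2.05e6))$tad_boundaries,
               bnd$tad_boundaries)
})

test_that("sampling is seed-deterministic with Poisson marginals", {
  spec <- synthetic_spec(region("chrX", 0, 2e6), 100e3, depth = 1e5,
                         deletion = region("chrX", 1.0e6, 1.1e6))
  m1 <- sample_map(spec, 17)
  m2 <- sample_map(spec, 17)
  expect_identical(m1$values, m2$values)
  expect_false(identical(sample_map(spec, 18)$values, m1$values))
  expect_true(all(m1$values == round(m1$values)))
  expect_equal(m1$values, t(m1$values))
  expect_true(all(m1$values[11, ] == 0))  # deleted bin
  # Monte-Carlo mean of one entry within 3 s.e. of its expectation
  e <- expected_map(spec)$values[2, 9]
  draws <- vapply(1:200, function(s) sample_map(spec, 100 + s)$values[2, 9],
                  numeric(1))
  expect_lt(abs(mean(draws) - e), 3 * sqrt(e / 200))
})

test_that("cassette profiles and peak tracks are reproducible and shaped", {
  chroms <- c(chrA = 10e6, chrB = 8e6)
  ins <- tibble::tibble(chrom = "chrA", pos = 5e6, pileup_mean = 50)
  p1 <- sample_cassette_profile(chroms, 100e3, ins, background_mean = 2,
                                seed = 9)
  expect_identical(p1, sample_cassette_profile(chroms, 100e3, ins,
                                               background_mean = 2, seed = 9))
  expect_equal(nrow(p1), 100 + 80)
  # the insertion bin dominates its neighbours on average over seeds
  bins <- vapply(1:100, function(s) {
    p <- sample_cassette_profile(chroms, 100e3, ins, background_mean = 2,
                                 seed = s)
    p$count[p$chrom == "chrA"][50:52]
  }, numeric(3))
  expect_gt(mean(bins[2, ]), mean(bins[1, ]) + 10)
  expect_gt(mean(bins[2, ]), mean(bins[3, ]) + 10)
  expect_gt(mean(bins[1, ]), 20)  # half-weight neighbours
  # no insertions -> pure background
  p0 <- sample_cassette_profile(chroms, 100e3, ins[0, ], background_mean = 2,
                                seed = 9)
  expect_lt(max(p0$count), 15)

  ext <- region("chrX", 0, 10e6)
  hot <- region("chrX", 4e6, 4.08e6)
  pk <- sample_peaks(ext, background_rate = 0, hotspot = hot,
                     hotspot_count = 15, seed = 2)
  expect_equal(nrow(pk), 15L)
  expect_true(all(pk$start >= hot$start - 100 & pk$end <= hot$end + 100))
  expect_true(all(pk$end - pk$start == 200))
  expect_identical(pk, sample_peaks(ext, background_rate = 0, hotspot = hot,
                                    hotspot_count = 15, seed = 2))
})

test_that("planted structures are recovered end-to-end", {
  # boundary of factor 0.3 at depth 5e5 -> called within 1 bin
  spec <- synthetic_spec(region("chrX", 0, 4e6), 40e3, tad_boundaries = 2e6,
                         boundary_insulation = 0.3, depth = 5e5)
  hits <- vapply(1:5, function(s) {
    b <- call_boundaries(delta_vector(insulation_score(sample_map(spec, s))))
    nrow(b) >= 1 && min(abs(b$bin - 50.5)) <= 1.5
  }, logical(1))
  expect_true(all(hits))
  # no boundary inside a homogeneous TAD away from the planted junction
  falsepos <- vapply(1:5, function(s) {
    b <- call_boundaries(delta_vector(insulation_score(sample_map(spec, s))))
    any(abs(b$bin - 50.5) > 3.5)
  }, logical(1))
  expect_false(any(falsepos))
  # boundary strength decreases as the planted insulation factor rises
  strengths <- vapply(c(0.2, 0.5, 0.8), function(f) {
    sp <- synthetic_spec(region("chrX", 0, 4e6), 40e3, tad_boundaries = 2e6,
                         boundary_insulation = f, depth = 5e5)
    mean(vapply(1:5, function(s) {
      prof <- delta_vector(insulation_score(sample_map(sp, s)))
      boundary_strength_at(prof, region("chrX", 1.9e6, 2.1e6))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(strengths) < 0))
})
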