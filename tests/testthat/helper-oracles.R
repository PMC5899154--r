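# Independent brute-force oracles and small fixture builders.

# Direct evaluation of the insulation definition: for each bin, aggregate
# the square (i-w..i-1) x (i+1..i+w) with explicit loops, no smoothing,
# then log2-normalise to the mean over valid bins. Kept deliberately
# separate from the package implementation.
oracle_insulation <- function(values, w, mode = "mean") {
  n <- nrow(values)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    if (sum(values[i, ], na.rm = TRUE) == 0) next
    vals <- c()
    n_na <- 0
    for (r in (i - w):(i - 1)) {
      for (cc in (i + 1):(i + w)) {
        x <- values[r, cc]
        if (is.na(x)) n_na <- n_na + 1 else vals <- c(vals, x)
      }
    }
    if (n_na > w * w / 2) next
    if (length(vals) == 0) next
    raw[i] <- if (mode == "mean") {
      mean(vals)
    } else if (mode == "median") {
      median(vals)
    } else {
      q <- quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
      mean(vals[vals >= q[1] & vals <= q[2]])
    }
  }
  raw[!is.na(raw) & raw == 0] <- NA_real_
  ok <- !is.na(raw)
  score <- rep(NA_real_, n)
  score[ok] <- log2(raw[ok] / mean(raw[ok]))
  score
}

# Closed-form Pearson chi-square on a 2x2 table, sum((O - E)^2 / E).
oracle_chisq_2x2 <- function(k1, n1, k2, n2) {
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  rs <- rowSums(obs)
  cs <- colSums(obs)
  ex <- outer(rs, cs) / sum(obs)
  stat <- sum((obs - ex)^2 / ex)
  c(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Block matrix with constant within/between values: TAD sizes in bins,
# `within` on diagonal blocks, `between[k]` between blocks k and k+1
# (and beyond, taking products is not needed for these fixtures: the
# between value for any cross pair is the value of the strongest
# separating junction list entry passed explicitly).
block_matrix <- function(sizes, within, between) {
  n <- sum(sizes)
  m <- matrix(0, n, n)
  starts <- cumsum(c(0, sizes))
  nb <- length(sizes)
  for (a in seq_len(nb)) {
    ia <- (starts[a] + 1):starts[a + 1]
    m[ia, ia] <- within
    if (a < nb) {
      for (b in (a + 1):nb) {
        ib <- (starts[b] + 1):starts[b + 1]
        val <- min(between[a:(b - 1)])
        m[ia, ib] <- val
        m[ib, ia] <- val
      }
    }
  }
  m
}

block_map <- function(sizes, within, between, bin_size = 40e3,
                      chrom = "chrX") {
  m <- block_matrix(sizes, within, between)
  contact_map(m, region(chrom, 0, nrow(m) * bin_size), bin_size = bin_size)
}

# Symmetric random positive matrix for oracle-equivalence sweeps.
random_map <- function(n, bin_size = 40e3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n, 0.5, 10), n, n)
    m <- (m + t(m)) / 2
    contact_map(m, region("chrX", 0, n * bin_size), bin_size = bin_size)
  })
}

# Off-diagonal WT/KO/no-loop specs mirroring the long-range loop design:
# two anchors ~25 Mb apart, 2 Mb x 2 Mb view at 40 kb bins.
loop_test_specs <- function(depth = 5e5, fold = 5) {
  ext <- region("chrX", 0, 80e6)
  anchor_a <- region("chrX", 47.90e6, 47.99e6)
  anchor_b <- region("chrX", 72.90e6, 72.99e6)
  wt <- synthetic_spec(ext, 40e3, depth = depth,
                       loops = list(list(anchor_row = anchor_a,
                                         anchor_col = anchor_b,
                                         fold = fold)),
                       view_rows = region("chrX", 46.96e6, 48.96e6),
                       view_cols = region("chrX", 71.96e6, 73.96e6))
  list(wt = wt,
       ko = ko_spec(wt, anchor_a),
       male = synthetic_spec(ext, 40e3, depth = depth,
                             view_rows = wt$view_rows,
                             view_cols = wt$view_cols),
       window = window_spec(anchor_a, anchor_b))
}
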