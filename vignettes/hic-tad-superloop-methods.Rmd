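---
title: "Insulation, super-loops and insertion mapping: models and methods"
author: "tadloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insulation, super-loops and insertion mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadloop)
```

tadloop analyses binned Hi-C contact matrices at the scale of a single
locus and its chromosomal neighbourhood. It answers four questions that
recur when a regulatory locus — for instance a CTCF-dense lncRNA locus
sitting on a TAD boundary of the X chromosome — is deleted or moved:

1. Where are the TAD boundaries, and how strong are they? (insulation
   module)
2. Do contacts across a boundary, or between two distant anchor loci,
   change between conditions? (interaction statistics and super-loop
   modules)
3. Is a focal long-range interaction statistically exceptional relative
   to its surrounding heatmap? (sliding-window test)
4. Where did a transgene cassette integrate, given contacts between a
   cassette contig and the genome? (insertion finder)

Every statistic is backed by a synthetic contact-map generator that
plants known structure, so each stage can be validated against ground
truth.

## The contact-map data model

A `contact_map` is a dense matrix of non-negative contact values over a
0-based, half-open bin grid (`bin i` covers `[i*binsize, (i+1)*binsize)`;
BED-compatible). Intra-chromosomal views are square and symmetric;
rectangular views represent off-diagonal windows between distant loci or
cassette-versus-genome slices. Two conventions matter throughout:

* **Masked means missing, never zero.** Unmappable, filtered or deleted
  bins are carried as `NA` and excluded from every aggregate. A deleted
  locus written as zeros would drag window means down and distort
  insulation scores; written as `NA` it simply drops out.
* **Region-to-bin snapping is outward.** Any requested region is expanded
  to cover all overlapped bins, so views are deterministic and loss-free.

I/O covers the classic dense heatmap dialect (header row/column of
`name|assembly|chrom:start-end` labels) and the sparse
"triplet + bin BED" dialect, with upper-triangle counts mirrored on
densification. Depth normalisation to reads per million and an iterative
row/column balancing (coefficient of variation of row sums below a
tolerance) are provided as plumbing; all downstream statistics accept any
normalisation state and record it, since ratio-based scores are invariant
to global scaling anyway.

## Insulation score and boundary calling

For each bin $i$, the raw insulation is the aggregate of the square of
contacts linking the `square_size` of sequence upstream of $i$ to the
`square_size` downstream — rows $i-w..i-1$ by columns $i+1..i+w$, with
$w = \mathrm{square\_size}/\mathrm{bin\_size}$. The aggregate is then
(optionally) smoothed by a centered running mean over `smooth_span` and
normalised as

$$\mathrm{score}(i) = \log_2 \frac{\mathrm{raw}(i)}{\overline{\mathrm{raw}}}$$

so the mean of $2^{\mathrm{score}}$ over unmasked bins is exactly 1 and
the score is invariant under global rescaling. Local minima are candidate
boundaries. The delta vector
$\Delta(i) = \overline{\mathrm{score}}_{(i, i+s]} -
\overline{\mathrm{score}}_{[i-s, i)}$ (with
$s = \mathrm{delta\_span}/\mathrm{bin\_size}$) crosses zero upward at a
minimum; the **boundary strength** is the delta excursion across the
crossing — nearest local maximum on the rising side minus nearest local
minimum on the falling side.

Defaults follow the canonical option set for 40 kb mouse matrices: 480 kb
square, 320 kb delta span, `iqrMean` aggregation, zero noise threshold,
160 kb smoothing, boundary margin 0 bins.

Choices a user should know about:

* **`iqrMean`** is the mean of the square's values lying within
  `[Q1, Q3]` (inclusive). It is robust to isolated outlier pixels, but on
  *idealised* all-or-nothing fixtures (e.g. within-TAD 10, between-TAD 0)
  it can discard the minority class entirely; plain `mean` is the right
  aggregation for such synthetic block matrices.
* **Normalisation reference** is the mean over the supplied matrix (the
  analysed view), not a whole chromosome: operations act on region views,
  and this keeps the scale-invariance property intact.
* **Edges and masks.** Squares truncated by the matrix edge are masked
  rather than partially aggregated (edge-biased scores are worse than no
  score); squares more than half missing are masked; bins whose row
  coverage is at or below `noise_threshold` are masked; a (smoothed) raw
  insulation of exactly zero is masked because its log is undefined.
* **Deletions and the delta vector.** Flank means of the delta vector
  skip interior masked bins (`na.rm`) and are only masked when a flank is
  edge-truncated or entirely data-free; the boundary bin at a crossing
  resolves to the lowest-scoring *valid* bin near the crossing. This is
  what lets a boundary remain detectable when a small deleted locus sits
  directly on it — the scenario the knockout analyses care about. The
  cost is that delta values adjacent to a mask average over slightly
  fewer bins.
* **`strength_cutoff`** (default 0.1) suppresses floating-point zero
  crossings on flat profiles. The canonical option set exposes no such
  cutoff; planted boundaries in the validation suite have strengths well
  above 1, so the cutoff does not interact with recovery.
* The `-yb`-style parameter of the original script is a plot axis bound,
  not a computation parameter, and is not reproduced. Both "boundary
  score" and "boundary strength" styles of comparison are served by the
  same delta-excursion statistic.

```{r, eval = FALSE}
spec <- synthetic_spec(region("chrX", 0, 4e6), 40e3,
                       tad_boundaries = 2e6, boundary_insulation = 0.3,
                       depth = 5e5)
prof <- sample_map(spec, 1) |> insulation_score() |> delta_vector()
call_boundaries(prof)
autoplot(prof, boundaries = call_boundaries(prof))
```

## Inter-TAD comparison and locus statistics

`inter_tad_values()` flattens the rectangular block linking two disjoint
domains; `compare_inter_tad()` applies a two-sided Wilcoxon rank-sum test
between conditions (normal approximation with continuity correction;
all-identical pooled values return a degenerate `p = 1`). The rank-sum
test assumes the values within each arm are identically distributed;
within a block spanning a wide range of genomic distances the
distance-decay gradient violates this, so the test is best read as a
shift test on matched blocks, and its calibration is verified on compact,
distant domain pairs where decay variation is negligible against Poisson
noise.

Peak-density windows count peaks per sliding window by **midpoint
assignment**, with the default step equal to the window size
(non-overlapping tiling) so counts are conserved — one count per
in-extent peak. The window step of the original chromosome-wide CTCF
analysis is not recorded; both tiled and overlapping windows are
supported. `window_rank()` reports descending mid-rank and the quantile
`(n - rank + 1)/n`, so a unique maximum scores exactly 1.

`colocalization_test()` is a plain Pearson chi-square on the 2x2 table
(no continuity correction by default — the correction is exposed as a
flag), `ddct_fold_change()` the closed-form $2^{-\Delta\Delta C_t}$, and
`deletion_span()` the distance between the downstream edge of a 5' cut
site and the upstream edge of a 3' cut site, with kb rounded half-up.

## The sliding-window significance test for long-range loops

To ask whether a focal interaction between two loci tens of Mb apart is
exceptional, a window of `n_rows x n_cols` bins (default 6 x 7 = 42 bins
at 40 kb) is centered on the anchor bin pair (bin of each anchor
midpoint; the extra row/column of an even dimension goes downstream) and
slid **bin-by-bin** over every top-left position of the surrounding
heatmap — 45 x 44 = 1980 positions on a 2 Mb x 2 Mb, 50 x 50-bin
rectangle. Each position is compared with the target window by a Welch
two-sided t-test.

* **Welch, not Student:** distance decay makes window variances unequal;
  the original analysis states only "t-test".
* **Zero-variance rules:** both samples constant and equal gives `p = 1`,
  constant and unequal gives `p = 0`; a single constant sample falls
  through to Welch with an epsilon variance guard. The target's own
  position therefore returns `p = 1` exactly — a useful positional sanity
  anchor.
* **Validity flags:** positions more than half masked, and positions
  whose window touches the diagonal of an intra-chromosomal map (where
  decay, not looping, would drive the test), are flagged invalid. The
  target position itself is included in the grid (exclusion is a flag).
  For the anchor pair geometry used here — loci ~25 Mb apart with a
  +/- 1 Mb view — the rectangle never approaches the diagonal.

`compare_pvalue_densities()` then runs a classic one-way ANOVA across
conditions on the per-position p-value samples (for two conditions it
reduces to the squared pooled t-test, `F = t^2`), and returns kernel
density summaries for plotting. Note that within one map the positions
share a single target sample, so per-position p-values are positively
dependent; the per-map p-value *distribution* is a descriptive density,
and calibration statements are made over independent replicate maps.

`superloop_quant()` quantifies all unordered pairs of a set of labeled
anchors (classically Firre, DXZ4, x75, ICCE) as the flattened bin-pair
values of the padded-region rectangle at 100 kb bins with a 100 kb pad —
a 4-bin by 3-bin pair yields n = 12 values, 3 x 3 yields n = 9.
`compare_superloop()` reports the Welch t-test and the condition-B /
condition-A mean ratio per pair.

## Insertion-site detection

Contacts between a cassette contig and genomic bins are Poisson-like
background plus focal pileups at integration sites. The background rate
is estimated **per chromosome by the median** bin count (robust to the
pileups themselves); each bin receives an upper-tail Poisson probability,
Benjamini-Hochberg adjusted across all bins, and bins below `alpha`
(default 1e-6) are merged into sites, joining runs separated by at most
one non-enriched bin (pileups spread into neighbouring bins). The site
score is $-\log_{10}$ of the adjusted tail probability of its maximal
bin. The original analysis determined "consistent" interactions by
inspection; here consistency is formalised as a >= 1 bp overlap between
calls in the two conditions (e.g. DOX- and DOX+), with the smaller of
the two scores reported. That formalisation — enrichment rule, alpha,
and merge gap — is a package decision, exposed as parameters.

## The synthetic generator

`synthetic_spec()` fixes the study conditions for validation:

* expected contacts
  $E_{ij} \propto |i-j|^{-\alpha}$ with $\alpha = 1$ by default (the
  generic mammalian intra-chromosomal scaling regime); diagonal entries
  use the distance-1 level;
* each TAD boundary multiplies crossing contacts by an insulation factor
  in $(0, 1]$; each loop multiplies its 6 x 7-bin window (and its mirror)
  by a fold $\geq 1$;
* a deletion zeroes the expected signal of its bins but keeps the bins,
  so wild-type and knockout grids stay comparable (an empty stripe, as in
  a real knockout map);
* `depth` scales the **loop-free, deletion-free decay background** to the
  requested total. Scaling the structured expectation instead would make
  a planted boundary or loop perturb every entry through the
  normalisation constant; anchoring the scale to the background keeps
  structural edits exactly local (a factor-0.5 boundary halves crossing
  entries exactly), at the cost that the realised total deviates from
  `depth` by the small structural mass;
* `sample_map()` draws independent Poisson counts per upper-triangle
  entry (or per entry of a disjoint off-diagonal view rectangle) and is
  deterministic given its seed.

Validation problem sizes are chosen to keep the full suite around a
minute: 2 Mb x 2 Mb views at 40 kb bins (50 x 50) at depth 5e5 for the
loop analyses, 4-4.8 Mb maps at 40 kb for boundary recovery (20 seeds),
1000 replicate map pairs for null calibration, and 100 replicate
10,000-bin profiles for the insertion false-positive sweep.

What the generator does **not** emulate — and what passing tests
therefore do not certify on real data: ICE-style coverage biases and
their correction artefacts, restriction-fragment and mappability
structure, nested/hierarchical TADs, loop-extrusion stripes and corner
peaks, trans-chromosomal background gradients, and overdispersion beyond
Poisson. The statistics are rank- and ratio-based precisely so that the
first-order biases cancel, but calibration claims are claims about the
generative model.

## Known limitations

* Boundary calling reports the single strongest crossing per bin
  neighbourhood; closely spaced (< delta span) boundaries can merge.
* The sliding-window test's per-map p-value field is dependent through
  the shared target; single-map uniformity should not be expected even
  under the null, and cross-condition comparison is the supported use.
* The insertion finder reports merged bin regions, not base-pair
  breakpoints, and does not estimate cassette copy number.
* No `.hic`/`.cool` binary I/O; matrices enter as dense or triplet text
  at the locus scale.
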