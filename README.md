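# tadloop

Locus-scale statistics for binned Hi-C contact matrices: TAD-boundary
insulation, long-range (super-loop) interaction significance, and
transgene insertion mapping — with a synthetic contact-map generator
providing ground truth for every stage.

The package is aimed at analyses of the kind that follow a locus
perturbation: a CTCF-dense locus sitting on a TAD boundary is deleted,
and one asks whether the boundary survives, whether contacts now leak
across it, whether a very-long-range loop anchored at the locus (such as
the inactive-X interactions among Firre, DXZ4, x75 and ICCE) is lost,
and — for a rescue transgene — where the cassette integrated.

## What it computes

**Insulation and boundaries.** For each bin `i` of a square map, the
contacts crossing it are aggregated over a `square_size` x `square_size`
square sliding along the diagonal, and log2-normalised:

    score(i) = log2( raw(i) / mean(raw) ),

so the score is invariant under global rescaling and local minima mark
boundaries. The delta vector `delta(i) = mean(score over (i, i+s]) -
mean(score over [i-s, i))` crosses zero upward at a minimum, and the
amplitude of its excursion across the crossing is the **boundary
strength**. Defaults are the canonical 40 kb option set: 480 kb square,
320 kb delta span, `iqrMean` aggregation, 160 kb smoothing.

**Comparative statistics.** Inter-TAD contact values are compared
between conditions with a two-sided Wilcoxon rank-sum test; CTCF peak
density is counted in sliding windows (midpoint assignment, tiled by
default) and ranked; colocalization proportions get a Pearson chi-square;
qPCR fold changes use `2^(-ddCt)`; `deletion_span()` does loxP cut-site
interval arithmetic.

**Super-loop significance.** A 6 x 7-bin target window (42 bins at
40 kb) centered on an anchor pair is slid bin-by-bin across a
2 Mb x 2 Mb off-diagonal heatmap (1980 positions) and each position is
Welch-t-tested against the target; p-value densities are compared across
conditions by one-way ANOVA. Pairwise super-loop quantification flattens
padded-region rectangles at 100 kb bins (n = 12 or 9 bin pairs for the
classic anchor set) and t-tests them between conditions.

**Insertion finder.** Bins of a cassette-versus-genome contact profile
are tested against a per-chromosome median Poisson background
(Benjamini-Hochberg adjusted, default alpha 1e-6), merged into sites,
and filtered for cross-condition (DOX-/DOX+) consistency.

**Synthetic maps.** `synthetic_spec()` + `sample_map()` generate
contact maps with power-law distance decay, TAD boundaries of tunable
insulation, fold-enriched loop windows, locus deletions and Poisson
depth noise; `ko_spec()` derives the matched knockout.

## Worked example

Plant a strong boundary (insulation factor 0.3) at chrX:48 Mb, delete an
80 kb locus sitting on it, and ask what survives:

```r
library(tadloop)

wt <- synthetic_spec(region("chrX", 44e6, 52e6), bin_size = 40e3,
                     tad_boundaries = 48e6, boundary_insulation = 0.3,
                     depth = 2e6)
firre <- region("chrX", 47.96e6, 48.04e6)
ko <- ko_spec(wt, firre)

prof_wt <- sample_map(wt, seed = 1) |> insulation_score() |> delta_vector()
prof_ko <- mask_locus(sample_map(ko, seed = 2), firre) |>
  insulation_score() |> delta_vector()

call_boundaries(prof_wt)
#> # A tibble: 1 × 5
#>     bin chrom    start      end strength
#>   <int> <chr>    <dbl>    <dbl>    <dbl>
#> 1   100 chrX  47960000 48000000     2.59
call_boundaries(prof_ko)
#> # A tibble: 1 × 5
#>     bin chrom    start      end strength
#>   <int> <chr>    <dbl>    <dbl>    <dbl>
#> 1    99 chrX  47920000 47960000     3.04
```

The boundary is still called in the knockout, one bin from the masked
locus. A genuinely weakened boundary (factor 0.3 raised to 0.6) drops its
strength from ~2.6 to ~1.1:

```r
weakened <- wt
weakened$boundary_insulation <- 0.6
sample_map(weakened, seed = 3) |> insulation_score() |> delta_vector() |>
  boundary_strength_at(firre)
#> [1] 1.118692
```

Now the long-range loop: a 5-fold 6 x 7-bin interaction between a
Firre-like and a DXZ4-like anchor ~25 Mb apart, tested against matched
conditions without it:

```r
ext   <- region("chrX", 0, 80e6)
firre <- region("chrX", 47.90e6, 47.99e6)
dxz4  <- region("chrX", 72.90e6, 72.99e6)
wt <- synthetic_spec(ext, 40e3, depth = 5e5,
                     loops = list(list(anchor_row = firre,
                                       anchor_col = dxz4, fold = 5)),
                     view_rows = region("chrX", 46.96e6, 48.96e6),
                     view_cols = region("chrX", 71.96e6, 73.96e6))
ko   <- ko_spec(wt, firre)
male <- synthetic_spec(ext, 40e3, depth = 5e5,
                       view_rows = wt$view_rows, view_cols = wt$view_cols)

w <- window_spec(firre, dxz4)   # 6 x 7 bins = 42 values at 40 kb
cmp <- compare_pvalue_densities(list(
  female_wt = slide_window_test(sample_map(wt, 11), w),
  female_ko = slide_window_test(sample_map(ko, 12), w),
  male_wt   = slide_window_test(sample_map(male, 13), w)))
cmp
#> <pvalue_density_comparison> one-way ANOVA: F(2, 5937) = 443.4, p = 3.507e-180
#>   conditions: female_wt, female_ko, male_wt
tidy(cmp)
#> # A tibble: 3 × 4
#>   label         n   mean_p frac_below_05
#>   <fct>     <int>    <dbl>         <dbl>
#> 1 female_wt  1980 0.000527         0.999
#> 2 female_ko  1980 0.0851           0.867
#> 3 male_wt    1980 0.207            0.467
```

The loop-carrying condition piles its sliding-window p-values at zero
(mean p ~ 5e-4; the target is enriched against essentially every other
position), the matched deletion and no-loop conditions do not, and the
ANOVA separates the three densities decisively. `autoplot()` methods
exist for contact maps, insulation profiles and sliding-window grids;
`plot_pvalue_densities()` draws the per-condition density curves.

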