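# microdyn

Quantitative analysis of microglial population dynamics across the human
cortical lifespan.

During human brain development the microglial population does not grow
monotonically: it expands and contracts in waves, driven by a balance of
proliferation, apoptosis and migration. Quantifying this from histology
means turning marked point patterns of immunostained cells (IBA1 for
microglia/macrophages, Ki67 for proliferation, cleaved caspase-3 for
apoptosis, TMEM119 for homeostatic microglia) on layered cortical columns
into lifespan trajectories, and then asking a statistical question that is
rarely posed explicitly: *does the distribution of a measurement across the
cohort have more than one mode?*

`microdyn` implements that pipeline for R users working with per-cell
tables exported from image analysis:

- **Histological quantification** — cell density `N_D = cells / area
  (mm^2)`, proliferative index `I = 100 * (IBA1+Ki67+) / IBA1+`, apoptotic
  index (same with cleaved caspase-3), TMEM119/IBA1 density ratios,
  per-layer densities on annotated transient zones (MZ, CP, SP, IZ, SVZ,
  VZ; 450-um-wide columns), and correction of densities for brain growth
  by cumulative fold change of wall thickness or brain weight.
- **Morphometric phenotyping** — circularity `4*pi*A/P^2` with the strict
  `< 0.3` migratory cutoff, axial folding of major-axis orientations, and
  the `< 45 degrees = tangential / > 45 degrees = radial` rule, summarised
  per layer.
- **Spatial heatmaps** — disk-kernel counts on a 10-um grid with a 150-um
  sampling radius, a display cap of 4, and proportional extrapolation to
  cells/mm^2 (`count / (pi r^2)`).
- **Wave statistics** — the excess-mass multimodality test: statistic
  `Delta_{n,k+1} = max_lambda [E_{n,k+1}(lambda) - E_{n,k}(lambda)]`
  (equal to twice the Hartigan dip for k = 1), calibrated by a
  critical-bandwidth smoothed bootstrap (B = 100 by default), with modes
  and antimodes estimated from the KDE at the critical bandwidth; temporal
  windows (embryonic ... adult) on a canonical days-post-conception axis;
  Kruskal-Wallis with tie-corrected Dunn pairwise tests and two-stage
  Benjamini-Krieger-Yekutieli FDR; Loess (10-nearest-neighbour) followed
  by a 6-8-knot smoothing spline for trend curves.
- **Expression rules** — On/Off/Other constitutive-expression
  classification (TPM > 2 in > 80% of samples at every timepoint), DE
  summarisation over a signature gene list, TPM normalisation, unscaled
  3xMAD single-cell QC, and cycling fractions per age with the >= 50-cell
  rule.
- **Synthetic data** — generators for cortical-column point patterns,
  lifespan cohorts with planted proliferation/density waves, and TPM
  matrices with known gene classes, so every stage can be tested against
  ground truth.

## Worked example

```r
library(microdyn)

# a synthetic lifespan cohort with proliferation waves at 9 and 18 pcw
g <- generate_cohort(wave_spec(), seed = 11)

# is the pooled density distribution multimodal?
r <- test_multimodality(g$cohort$density_per_mm2, B = 100, seed = 99)
print(r)
#> Excess-mass multimodality test
#>   Delta_{n,2} = 0.1848, bootstrap p = 0 (B = 100, n = 55)
#>   decision: multimodal
#>   modes: 95.16, 341.9
#>   antimodes: 238.8

# where do the density waves peak?
tf <- fit_trend(g$cohort[g$cohort$canonical_age_days <= 210, ], "density")
print(tf)
#> trend_fit of density on 42 cases; peaks at day(s): 35.2, 72.7, 138.1, 187.5
round(days_to_pcw(tf$peaks), 2)
#> [1]  5.03 10.39 19.73 26.78
```

The test rejects unimodality (p = 0 over 100 bootstrap replicas) and places
the two value-distribution modes near the baseline (~95 cells/mm^2) and the
wave regime (~342 cells/mm^2).  The fitted trend localizes the planted
density peaks (truth: 10.5 and 19.5 pcw) to within half a week; the two
outer maxima at 5 and 26.8 pcw are small boundary wiggles of the spline at
the ends of the observed age span, not waves.

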