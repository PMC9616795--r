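---
title: "Quantifying microglial population waves across the human cortical lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial population waves across the human cortical lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The problem

Microglia colonise the human telencephalon early in embryonic life and their
population then fluctuates in waves: phases of proliferative expansion are
followed by density peaks and apoptotic refinement, tracking major
neurodevelopmental milestones. Quantifying this from immunohistochemistry
means working with *marked point patterns*: each detected cell carries a
position in a cortical column (depth from the pial surface), shape
descriptors from a fitted outline, and binary marker flags — IBA1
(microglia/macrophages), Ki67 (cycling), cleaved caspase-3 (apoptotic),
TMEM119 (homeostatic microglia). `microdyn` turns such tables into per-case
summaries, lifespan trajectories, and formal tests of the wave structure.

All ages live on one canonical axis, days post-conception, with term fixed
at 266 days (38 postconceptional weeks): prenatal ages map as `7 * pcw`,
postnatal ages as `266 + days`, a year counted as 365.25 days and a month
as 30.44. This keeps the axis continuous at birth and strictly monotone
from embryo to adult, which the trend fits and window assignment rely on.

## Histological quantification

Density is cells per analysed area, `N_D = n / area(mm^2)`. The
proliferative index is the percentage of IBA1-positive cells co-labelled
for Ki67, `I = 100 * n(IBA1+Ki67+) / n(IBA1+)`, and the apoptotic index is
the analogue with cleaved caspase-3. Indices with a zero denominator are
errors, never silently zero — a cohort mean computed over silently-zero
indices would be biased toward zero exactly where data are thinnest.

Layer assignment uses half-open depth intervals `[top, bottom)`: a cell
exactly on a boundary belongs to the deeper layer, which resolves boundary
cells deterministically. Layer areas are thickness times the 450-micrometre
column width. Cells outside all annotated layers are counted in an explicit
`unassigned` bucket so that per-layer counts always conserve the total.

Because the cortical wall grows severalfold while the population changes,
raw densities confound population size with dilution. The growth correction
multiplies each raw density by the cumulative size fold-change relative to
a reference age, `corrected(t) = raw(t) * size(t) / size(ref)`, with the
size series (wall thickness prenatally, brain weight postnatally)
interpolated piecewise-linearly in canonical age. Multiplication is the
default direction — growth dilutes density, so recovering population change
requires scaling back up — but `direction = "divide"` is exposed for users
who want the opposite reading, and the fold-change chain rule guarantees
that correcting stepwise between subsequent ages or directly against the
reference gives the same factor. The proliferative index, a ratio of
counts, needs no correction. Whether a brain-weight correction should enter
through a volumetric exponent (weight^(2/3) for an areal measure) is not
determinable from first principles here; the fold change is applied
directly and documented as such.

## Morphometric phenotyping

Migratory microglia are elongated and polarised; differentiated microglia
are ramified and round-ish in outline. The classifier uses the standard
shape descriptor circularity `= 4 pi A / P^2` (1 for a circle, clamped at 1
against discretisation artefacts) with the strict rule: circularity below
0.3 is the migratory phenotype. The defining inequalities are strict on
both sides, so the measure-zero tie at exactly 0.3 is assigned to the
non-migratory side, and 45 degrees to the radial side, as documented,
configurable tie rules. Orientations are axial data: the angle between the
cell's major axis and the layer plane is folded to [0, 90] via
`min(d, 180 - d)`, making the folding idempotent. Angles below 45 degrees
are tangential migration, above radial. A caveat carried in the naming:
these are *phenotype* labels inferred from static morphology, not measured
displacement.

A note on a subtlety the test suite pins down: a smooth 4:1 ellipse has
circularity about 0.54 (perimeter by numerical quadrature of the arc-length
integral), far above the 0.3 cutoff. Real migratory cells pass the cutoff
because their perimeters are convoluted, not merely because they are
elongated. The synthetic generator therefore draws a target circularity for
migratory cells (0.08-0.28) and sets the perimeter from it
(`P = sqrt(4 pi A / C)`), rather than using the smooth-ellipse perimeter of
the drawn aspect ratio.

## Spatial heatmaps

The heatmap reproduces a disk-counting workflow: at every point of a
10-micrometre grid, count the cells within a 150-micrometre radius. The
display layer is capped at 4 — a saturated pixel means at least 4 cells in
a `pi * 0.15^2` mm^2 disk — but the cap is display-only; the raw count
layer is preserved, because proportional extrapolation to density,
`count / (pi r^2)` with r in mm, would be biased if computed from capped
values. One cell at a grid point therefore extrapolates to
`1 / (pi 0.15^2) = 14.147` cells/mm^2. The uniform disk kernel is the
default and the only one the extrapolation accepts; a quartic kernel is
available for visual parity with GIS-style maps but is refused by the
density step. The 10-micrometre spacing keeps the discretisation error of
the disk-area identity `sum(count) * spacing^2 = N * pi * r^2` (for cells
whose disks lie inside the grid) under the 2% the tests assert. No
boundary correction is applied, matching the source workflow; conservation
checks restrict to interior cells.

## The excess-mass wave test

The statistical core asks: does the distribution of a cohort measurement
(pooled density, pooled proliferative index) have more than one mode? Two
regimes — a baseline and a wave — show up as two modes in the *value*
distribution.

The empirical excess mass at level `lambda` over `m` disjoint intervals is
`E_{n,m}(lambda) = max over intervals of sum_j [P_n(I_j) - lambda |I_j|]`,
and the test statistic is
`Delta_{n,k+1} = max_lambda [E_{n,k+1}(lambda) - E_{n,k}(lambda)]`.
The implementation (compiled) evaluates, for each candidate level, the best
interval systems by dynamic programming over the sorted sample, with the
candidate levels taken as the slopes `(j - i) / (n (x_j - x_i))` between
order statistics — the breakpoints where optimal systems change. For
`k = 1` the statistic is exactly twice the Hartigan dip (the sup-norm
distance from the empirical CDF to the nearest unimodal CDF), and the
package also ships an independent dip implementation computed from that
definition directly: bisection on the distance with an exact feasibility
certificate for "a convex-then-concave monotone function exists within
these bands", allowing an atom at the mode only. The identity
`Delta_{n,2} = 2 dip` holds to machine precision across the test battery,
including tied samples — a strong cross-check, since the two routes share
no code. The brute-force oracle in the tests solves the same minimax as a
small linear program over piecewise-linear unimodal CDFs.

Calibration follows the critical-bandwidth smoothed bootstrap: the critical
bandwidth `h_k` is the smallest Gaussian KDE bandwidth with at most `k`
modes (mode counts are monotone in the bandwidth for the Gaussian kernel,
so bisection applies); replicas are drawn by resampling the data,
perturbing with `h_k`-scaled Gaussian noise and rescaling so the replica
variance matches the sample variance; the p-value is the fraction of `B`
replicas (default 100) whose statistic reaches the observed one. Small p
rejects unimodality. This package states the standard convention
explicitly — H0 is "k modes", small p favours more — and always reports
both the p-value and the decision, because the verbal conventions around
"excess tests" in the applied literature are easy to invert. Modes and
antimodes are reported from the KDE at the critical bandwidth of the
accepted mode count; at that bandwidth a merging mode/antimode pair can
linger numerically, so the `k` tallest maxima are kept and antimodes are
the density minima between consecutive kept modes.

At the cohort sizes in play (n around 95), the simulated type-I rate at
alpha = 0.05 sits near 0.05-0.07 and the power against a 6-sigma-separated
half-and-half normal mixture is essentially 1, with mean mode estimates
within a few hundredths of the truth; single-replicate mode estimates
scatter with sd around 0.3-0.5, which is sampling noise of the KDE mode at
n = 95, not estimator bias.

## Windows, comparisons and trends

Temporal windows follow the standard staging: embryonic (3-8 pcw), early
fetal (9-15), mid-late fetal (16-25), preterm (26-35), term (36 pcw-birth),
neonatal (0-1 month), infant (1-12 months), child (1-2 years), adult
(over 18 years). The 2-18-year range maps to an explicit `unclassified`
label: paediatric tissue in that range is essentially unobtainable, and
hiding the gap inside a neighbouring window would misdate it. Intervals
are half-open on the canonical day axis.

Window comparisons run Kruskal-Wallis followed by Dunn pairwise z-tests
(tie-corrected), adjusted either by Bonferroni or, by default, the
two-stage Benjamini-Krieger-Yekutieli step-up: stage one estimates the
number of true nulls at level `alpha / (1 + alpha)`, stage two reruns the
step-up with that estimate. The reported adjusted p-values are BH values
scaled by `m0 / m`, monotonised, so thresholding them at alpha reproduces
the two-stage discovery set. Both pieces are implemented in the package
(no installed package provides them); the omnibus test and the classical
two-sample tests (Kolmogorov-Smirnov, Mann-Whitney, paired Wilcoxon,
Friedman, Spearman) are the base R implementations behind a uniform
front end, all two-sided.

Trend curves are fitted in two passes: a local linear (tricube) smoother
with a 10-nearest-neighbour window — "10 points" is read as a neighbourhood
size and converted to a span of `10/n` — followed by a cubic smoothing
spline with 6-8 knots fitted to the smoothed values. The curve is reported
on a grid spanning the observed ages only; extrapolation is refused. Peaks
are the curve's interior local maxima; with dense fetal sampling the
planted density peaks are localised to within 2-3 days, while the span ends
can carry small boundary wiggles that callers should not read as waves.
Two smoothing passes are not exactly idempotent on curved input — refitting
the fitted curve re-smooths it by a few percent (bias of order `h^2 f''`) —
so idempotence holds exactly only for data the pipeline reproduces exactly
(straight lines), and the tests assert exact linear reproduction plus
peak-location stability under refitting.

## Expression rules

A gene is constitutively expressed ("On") when, at *every* timepoint,
strictly more than 80% of that timepoint's samples exceed TPM 2 (both
inequalities strict: TPM exactly 2.0 never counts). "Off" is defined as the
symmetric complement — a pass fraction at or below 20% at every timepoint —
because the source rule only names "unexpressed"; everything else is
"Other" (sporadic). The three classes partition the gene universe by
construction, pass fractions are computed per timepoint (with a warning
when a timepoint has fewer than 5 samples, where fractions are coarse), and
gene symbols are matched case-insensitively with unmatched symbols reported
rather than erroring.

Differential-expression *computation* is out of scope — those calls come
from dedicated tools upstream — but the package summarises DE tables over a
signature list (n tested, up, down, percent DE per transition, with a
validation error if a gene is flagged both up and down in one transition)
and ships a clearly-labelled rank-sum + BH stand-in for exercising the
summary on synthetic matrices.

Single-cell QC uses the unscaled median absolute deviation: keep a cell iff
every available metric lies within `median ± 3 MAD`. The 1.4826 consistency
factor is off by default to match the single-cell convention, and a
constant metric (MAD 0) excludes nobody — the degenerate alternative would
discard every cell that deviates at all. The cycling-fraction summary drops
ages with fewer than 50 annotated cells before reporting per-age fractions.

## What the synthetic generators emulate — and what they do not

The generators provide ground truth for every stage without any external
download.

*Columns* are homogeneous Poisson point patterns per layer with Bernoulli
marker flags, planted migratory fractions, and shapes drawn as described
above (target circularity for migratory cells, near-circular amoeboid
cells, radial/tangential orientations with 8-degree angular noise). They
emulate counts, fractions and classifications; they do not emulate
clustered spatial structure (vascular association, layer-boundary
accumulation), so the heatmap tests check conservation and unbiasedness,
not realistic spatial texture.

*Cohorts* place Gaussian proliferation bumps `A_j exp(-(t - tau_j)^2 /
(2 sigma_j^2))` on a baseline, with density bumps lagged by `L_j` and an
apoptotic index proportional to the relative density *loss* rate,
`a(t) = 100 gamma max(0, -D'(t)) / D(t)` — apoptosis appears in refinement
phases, after each density peak. The defaults are the study conditions:
waves at 9 and 18 pcw (the first at the embryonic-fetal transition, the
second matching a subplate-expansion-era wave with its density peak near
20 pcw), lag 1.5 pcw, width 10.5 days, baseline 90 cells/mm^2 and 2%
proliferation rising to peaks near 490 and 340 cells/mm^2 and about 22%.
Density noise is lognormal with sigma 0.12 (about the 13% CV implied by an
adult mean of 85 with SEM 4.4 at typical adult n); index noise is
beta-binomial on counts so indices stay in [0, 100] by construction, with
overdispersion 0 meaning noise-free. The gain `gamma` defaults to 1 and is
deliberately uncalibrated: the histology does not pin down an
apoptosis-to-density-loss budget. The default age design oversamples the
two wave windows and carries a thin lifespan baseline tail, emulating how
such cohorts are actually assembled (fetal ages are heavily represented);
this matters because a sparse uniform age grid cannot produce a bimodal
pooled-value distribution — too few cases sit near the peaks — whereas the
realistic design yields detection of bimodality in the large majority of
seeded replicates. What the cohort generator does not emulate: regional
heterogeneity, case-level covariates (sex effects), or measurement error
in age itself.

*Expression matrices* plant exact On/Off/Other structure (On genes exceed
the cutoff everywhere by construction; Other genes are expressed at a
random proper nonempty subset of timepoints) and a DE spike that multiplies
the above-cutoff excess at one timepoint — so spiked genes remain
constitutive and class recovery stays exact. Constitutive log-TPM spread is
sdlog 0.3, a realistic within-condition spread for constitutive genes that
also makes a 4-fold spike rank-separable at 6 samples per timepoint. *QC
metrics* are uniform (compact support) with planted outliers displaced to
exactly ±8 unscaled MAD — heavy-tailed clean metrics would make "exactly
the planted cells removed" an ill-posed target at a 3-MAD fence, which is a
property of the fence, not of the generator. These generators test the
rules, not transcriptome biology: there are no gene-gene correlations, no
library-size artefacts, no batch structure.

## Numerical choices and degenerate inputs

Sorted-sample dynamic programming for the excess mass is exact at its
candidate levels; the bisections (dip distance, critical bandwidth) run to
relative tolerances of 1e-12 and 1e-3 respectively. Degenerate samples —
one point, all values tied — have dip 0 and excess mass 0 with a warning.
The bootstrap refuses to run without a seed: a calibration that silently
depends on the RNG state is not reproducible. Zero-denominator indices and
ratios are errors; the TMEM119/IBA1 ratio may exceed 100% (a warning), as
sampling noise can invert densities. Problem sizes in the tests — cohorts
of about 100 cases, columns of about 2000 cells, 200-replicate calibration
studies at B = 100 — were chosen so the full suite completes in a few
minutes while keeping Monte Carlo error well inside the asserted bands.

## Design notes

The package is organised as a toolbox of analysis stages rather than around
a single fitted-model object: the pipeline has several entry points
(histology, morphometry, heatmaps, cohort statistics, expression rules)
with no one estimator at its centre. Where a stage does produce a
model-like result, it returns a classed object with the conventional
methods (`mode_test` with `print`; `trend_fit` with `print`, `predict`,
`residuals`, `plot`; `heat_grid` with `print`, `plot`). Exported functions
plus `scripts/acceptance.R` are the interface; there is no shell
executable, as the intended users work from R.

## Known limitations

Columns are treated as 2-D projections; no Abercrombie-type 3-D count
correction is attempted (none is defined for this workflow). Migration
labels are morphometric phenotypes, and nothing distinguishes
periphery-derived from within-brain migration. The bootstrap p-value at
B = 100 has granularity 0.01, which is faithful to the published procedure
but coarse; raise `B` for finer p-values. The excess-mass test is run per
variable (density, proliferation separately); no joint test is offered.
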