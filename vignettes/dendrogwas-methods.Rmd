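---
title: "Methods: from tree rings and climate to marker-trait associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tree rings and climate to marker-trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`dendrogwas` implements a complete dendro-genomic analysis chain for conifer
provenance trials: station climate is interpolated to the trial site, drought
events are detected with the standardized precipitation index (SPI), per-tree
drought response indicators are derived from ring-width series, their
repeatability is estimated by REML variance components, and biallelic SNPs
are scanned against the resulting trait table with an exact per-marker mixed
linear model including admixture covariates and a genomic kinship effect
(MLM+Q+K). A deterministic generator produces synthetic datasets with known
ground truth so every stage can be validated in closed loop.

# Climate and drought detection

**Interpolation.** Site climate is an inverse-distance-weighted mean of the
`n_nearest = 4` closest stations with exponent 2 (great-circle distances).
The station count follows the emulated trial's practice; the exponent is the
conventional IDW default, as no value is stated for it in the source
analysis.

**SPI.** For a timescale of k months the right-aligned k-month precipitation
sums of each calendar month are modelled as H(x) = q + (1 - q) G(x), where q
is the relative frequency of zero sums and G a gamma CDF fitted by maximum
likelihood to the nonzero sums over a reference period (default: the full
record; the emulated analysis used 1961-2011). The SPI is the standard
normal quantile of H. The gamma MLE is a Nelder-Mead optimization
initialized from Thom's approximation, which is stable on the ~50
observations available per calendar month; months with fewer than 10
nonzero reference values raise an error naming the month.

**Classification and events.** SPI values are classified on the McKee
scale (mild > -1, moderate > -1.5, severe > -2, extreme <= -2; non-negative
values are "none"), which partitions the real line. A calendar year is a
drought event when the minimum of the 1- or 3-month SPI over the growing
season (default April-July) is at or below -2 ("extreme"); this threshold
reproduces the three retained events of the emulated record (SPI -2.41,
-2.37, -2.00). Sub-threshold excursions outside the growing season are
reported but flagged and excluded from defaults, because late-season
deficits occur after earlywood formation has largely finished and leave
little imprint on ring width. Whether event identification should use SPI-1,
SPI-3 or both is not specified in the source; both are computed and the
union rule is the default.

# Drought response indicators

From raw, untransformed ring widths (dimensional transformations would
distort variance components): with Dr the drought-year width and preDr /
postDr the mean widths of the two years before/after (closed windows,
configurable width),

- resistance Rt = Dr / preDr,
- recovery Rc = postDr / Dr,
- resilience Rs = postDr / preDr,
- relative resilience rRs = (postDr - Dr) / preDr.

The identities Rs = Rt * Rc and rRs = Rs - Rt hold exactly and are enforced
to 1e-12 in tests; all four are invariant to rescaling the series. A tree
missing any required year yields a missing response with a recorded reason
rather than an error.

# Trait table

The association trait table always has 51 columns: 4 drought scenario
traits, 12 drought indicators (4 indices x 3 events, suffixed with the
two-digit event year), 8 climate-growth correlations and 27 wood-property
traits (9 annual means with binomial `b` and categorical `t` transforms).
Notes on the open choices:

- **Climate-growth traits.** The two-step screen (correlate the mean
  chronology with each of 18 months x {temperature, precipitation} from
  April of the previous year to September of the current year; keep p <
  0.05; then per-tree Pearson r with each kept variable, Fisher
  z-transformed with |r| clipped at 1 - 1e-12) is implemented in
  `climate_growth_traits()`. Because the screen's outcome varies with the
  data, the *table builder* pins the eight canonical columns (CorFebP,
  CorMayP, CorJunP, CorJanT, CorMarT, CorMayT, CorJunT, CorAugT) so the
  table is always 51 wide; the screen remains available for exploratory
  use. Per-tree correlations use raw ring width (not a per-tree index),
  matching the source's description of correlating "annual increment" of
  each tree.
- **Transforms.** Binomial = median split, categorical = tertiles; quantiles
  use linear interpolation between order statistics, values exactly on a
  cutpoint go to the lower class, missing propagates.
- **Scenario traits.** The original cutoffs are published only in a figure
  and are not recoverable, so scenarios are a configurable rule registry
  with documented defaults built on per-event medians of Rt for the first
  two events (the third event is excluded: its pre-window overlaps the
  second event's recovery years, a carry-over): Scen1 = above both medians,
  Scen2 = above either, Scen3 = count above (0/1/2), Scen4 = tertiles of
  the mean per-event z-score.

# Repeatability

Indicators are log-transformed (Rt, Rc, Rs; strictly positive ratios) and
z-scored within each drought event; rRs can be non-positive and is z-scored
only. This order ("log then standardize") is an assumption; the source
states both operations without an order.

Variance components come from a dense-covariance REML fit with
non-negativity constraints (L-BFGS-B on the restricted likelihood; dense
Cholesky is adequate at <= 1,000 records). Repeatability is
r = sigma2_ind / (sigma2_ind + sigma2_res) per provenance; the
across-provenance model adds a provenance random effect whose variance
enters the denominator (this is the convention that reproduces the published
overall row: 0.182 / (0.022 + 0.182 + 0.798) = 0.182). Standard errors use
the delta method on the inverse observed-information matrix (central finite
differences); components estimated on the boundary report SE 0, matching the
"0.000 +/- 0.000" convention, and r is not estimable when the model is
degenerate. Significance is a likelihood-ratio test of sigma2_ind = 0
against the 50:50 chi0:chi1 mixture at alpha = 0.05 — the source never
states its rule, and the published bold pattern is inconsistent with a
simple r/SE cutoff (one provenance is flagged significant at r = 0.131 +/-
0.131), so the standard boundary LRT was chosen. SubsetQD is the set of
provenances whose Rt repeatability is significant.

Equivalence with the original ASReml fits cannot be asserted bit-for-bit
(the exact parameterization is unpublished); instead the engine is checked
against the balanced-design closed form (sigma2_ind = (MSB - MSW) / k to
1e-6), against `lme4`, and by parameter recovery on synthetic data.

# Population genetics

- **QC:** markers with MAF < 5% or missingness > 10% are removed before
  association.
- **Neutral panel:** markers outside exons (intron / intergenic / upstream /
  downstream), 100% call rate, MAF strictly > 0.15.
- **Kinship:** genotype columns centered by twice the allele frequency,
  missing imputed to the column mean; the default normalizer is VanRaden
  method 1 (sum of 2pq). The original analysis used TASSEL's centered IBS,
  whose scaling constant differs but is not recoverable; a `tassel` option
  (divide by m/2) is provided and all mixed-model results are proven
  invariant to the choice (the scale is absorbed into the genetic
  variance). The kinship grand sum is 0 by the centering identity and the
  matrix is PSD.
- **HWE:** two-sided exact test by enumeration of heterozygote
  configurations conditional on allele counts.
- **Fst:** Weir-Cockerham 1984 theta, combined across loci as a ratio of
  sums. The original estimator is unstated; the published values 0.015 /
  0.045 are therefore interpreted through this estimator, not asserted.

# Association model

Per trait and marker: y = mu + Q* v + x beta + u + e with u ~ N(0, s2g K),
e ~ N(0, s2e I), where Q* drops the last admixture column (full rank with
the intercept; with K = 2 clusters one covariate remains). No compression is
applied and the variance ratio delta = s2e / s2g is re-estimated for every
marker, as in the original analysis. The fit profiles the restricted
likelihood over delta on the eigenbasis of K (computed once per trait);
the optimization is three nested, fully vectorized grids over log delta in
[-10, 10] (anchored at the mean eigenvalue so the fit is exactly invariant
to a constant rescaling of K) followed by a parabolic refinement, verified
against a brute-force dense grid oracle to 1e-6 in p. Markers with missing
calls drop those individuals, which changes the eigenbasis; the multi-trait
scanner processes such markers marker-outer so each decomposition is shared
across all 51 traits. beta is tested with an F statistic at denominator df
n - rank(fixed effects). Binomial and categorical traits are analyzed on
their numeric codes with the same Gaussian model, mirroring the original
TASSEL usage.

Marker R2 is computed on the whitened scale at the marker's optimum:
(RSS without marker - RSS with marker) / total corrected SS. The original
Rsq_Marker formula is unpublished; this definition reduces to the squared
(partial) correlation in the OLS limit, which is property-tested. Bonferroni
thresholds alpha/m reproduce the published values at m = 1,714 and 1,707.
The "single extreme individual" flag is operationalized as a leave-one-out
refit: remove the most trait-extreme carrier of the minor genotype class and
flag the association if the refit no longer passes the threshold (the
original procedure is not described).

# Synthetic data: what it emulates, and what it does not

Defaults are the stated world of the emulated trial: 11 provenances with
22-55 trees each (323 total), ring records 1978-2011, droughts in 1993,
2000 and 2003 with the 2000 event strongest (event-year growth multipliers
0.50 / 0.22 / 0.60 and two-year post-event multipliers 0.72 / 0.27 / 0.80,
sized from the published growth reductions of up to ~80% and the published
Rs ranges), ~1,700 variable SNPs in two Balding-Nichols clusters at Fst
0.015, and a genotyped panel of 45% of trees chosen as phenotype extremes.

Key generator choices:

- **Effects act on the log scale**, so the Lloret ratios inherit the
  intended variance decomposition cleanly.
- **Per-provenance repeatability targets** (default 0 to 0.44, the
  published heterogeneous pattern) set the individual-variance fraction of
  each provenance's drought multiplier; the tree-weighted mean (~0.19)
  matches the published overall repeatability of drought resistance.
- **Causal markers** (default target R2 0.10 / 0.05 / 0.03 pooled) have
  their effects scaled by provenance susceptibility
  (sqrt(r_target / mean r_target)), so provenances without repeatable
  drought response carry no marker signal: the high-repeatability subset
  then shows larger marker R2 than the pooled panel, the pattern the
  subset scan exists to exploit. A configuration whose summed causal R2
  exceeds the mean individual fraction is rejected as inconsistent.
- **Post-drought years are event-level constants**: individual deviations
  do not persist into the recovery years. This makes resilience carry
  almost no heritable signal (as observed in the emulated trial) and keeps
  consecutive events uncorrelated — the 2000 post-window is the 2003
  pre-window, and letting tree effects persist would destroy the
  compound-symmetry structure the repeatability model assumes (this was
  verified empirically: a damped-persistence variant biased recovered r
  from 0.35 down to ~0.20).
- **Drought calibration is part of the stated world**: May/June
  precipitation of drought years is scaled down iteratively until the
  site-interpolated growing-season SPI falls below -2 (February-April and
  July scale with the square root of the factor, making the drought
  season-wide).
- **Non-drought springs are under-dispersed.** February-July of non-drought
  years share a per-year signal (Gaussian copula, rho 0.93) and are drawn
  from the upper 65% of each month's gamma. Real precipitation records are
  not truncated like this; the compression is what makes the configured
  droughts the *only* extreme growing-season deficits, so that event
  detection can be tested in closed loop. Consequently a green
  event-recovery test establishes that the SPI/event machinery is correct,
  not that real records would ever separate this cleanly.
- Densities and the earlywood/latewood split follow the published sign
  structure (drought years: narrower rings, higher maximum density), with
  levels typical of Norway spruce (ring density ~450 kg/m3). They carry no
  engineered genetic signal.

# Numerical choices and degenerate inputs

- Variance components are clamped at 0; the residual variance keeps a small
  positive floor so the covariance stays invertible, and estimates within
  twice the floor are reported as exactly 0 with SE 0.
- Gamma MLE: Nelder-Mead from Thom's initialization, relative tolerance
  1e-12.
- The MLM records markers whose fixed-effects matrix is singular (e.g.,
  collinear with Q*) as untestable rather than failing the scan; kinship
  matrices that are not PSD beyond -1e-6 (relative) raise an error.
- Ties in categorization go to the lower class everywhere.
- The pipeline re-runs SNP QC on the SubsetQD individuals rather than
  reusing the full-panel marker list, reproducing the published situation
  of slightly different marker counts (1,714 vs 1,707).

# Known limitations

- Configuration files are JSON, not TOML (no TOML parser is available in
  the dependency environment).
- No detrending beyond the per-tree unit-mean index; spline or RCS
  standardization families are out of scope.
- The MLM is Gaussian even for binomial/categorical traits (by design,
  matching the emulated analysis), so its p-values for those traits are
  approximations.
- Checkpointing is file-based and coarse (stage outputs are plain-text
  files that can be inspected and reused); there is no workflow-engine
  integration.
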