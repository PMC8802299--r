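---
title: "Analysing bud dormancy from temperature, phenology and qPCR time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing bud dormancy from temperature, phenology and qPCR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buddorm)
```

## The problem

Deciduous fruit trees such as apple pass through winter in a dormant state
with distinct phases. During *endodormancy* the buds themselves block
growth until a cultivar-specific amount of cold has been perceived (the
chilling requirement, CR); during *ecodormancy* only unfavourable weather
prevents growth, and bud break follows once enough warmth has accumulated
(the heat requirement, HR). Apple is essentially insensitive to
photoperiod, so ambient temperature is the dominant environmental signal,
and the molecular machinery behind dormancy progression — DAM/SVP
MADS-box factors, FLC-like genes, ABA signalling components, PIF4 and
others — shows strong, phase-specific expression dynamics.

`buddorm` implements the full analysis chain used in dense-time-series
candidate-gene studies of dormancy: thermal-time models on hourly
temperature records, phenological dating of the endo-to-ecodormancy
transition from scion forcing assays, relative quantification of
high-throughput qPCR panels, clustering of expression trajectories, and
correlation of expression with short-window temperature covariates. A
coupled synthetic-data generator produces campaigns with known ground
truth so that every stage is testable end to end.

## Thermal-time models

Three classical models convert an hourly temperature series
(`hourly_temps`) into accumulated units:

* **Chilling hours (CH)** — one unit per hour with temperature in the
  effective band, by default $0 < T \le 7.2\,°C$. The literature is
  ambiguous about the boundaries; we adopt the open-at-0 / closed-at-7.2
  convention and expose both limits (`chilling_hours(series, low, high)`).
* **Chill portions (CP, dynamic model)** — a two-step kinetic model. Per
  hour, with $T$ in Kelvin, an intermediate $x$ relaxes toward its
  equilibrium $x_s(T) = (a_0/a_1)\,e^{(e_1 - e_0)/T}$ at rate
  $k_1(T) = a_1 e^{-e_1/T}$:
  $x \leftarrow x_s - (x_s - x)e^{-k_1}$. Whenever $x \ge 1$ at the start
  of an hour, the fraction $\xi(T) = \mathrm{sr}/(1+\mathrm{sr})$ with
  $\mathrm{sr} = e^{\,\mathrm{slp}\cdot \mathrm{tetmlt}\,(T -
  \mathrm{tetmlt})/T}$ is banked irreversibly as chill portions and
  $(1-\xi)x$ carries over. This makes chilling partially reversible by
  warm spells, unlike CH. We use the canonical published constants
  (`dynamic_model_params()`: slp 1.6, tetmlt 277 K, $a_0$ 139500, $a_1$
  2.567×10¹⁸, $e_0$ 4153.5 K, $e_1$ 12888.8 K) and initialise the
  intermediate at 0 at the series start.
* **Growing degree hours (GDH, ASYMCUR)** — an asymmetric curvilinear
  response with base, optimal and critical temperatures (defaults 4, 25,
  36 °C): a half-cosine rise from 0 at the base to $T_u - T_b$ (= 21 GDH)
  at the optimum, a quarter-cosine fall back to 0 at the critical
  temperature, 0 outside. Both branches agree at the optimum; a stress
  factor in (0, 1] scales every credit.

All accumulation queries use half-open intervals $(\text{start},
\text{end}]$, with calendar days anchored at their last hour (23:00,
timezone-naive). This single convention makes interval sums exactly
additive, makes `chilling_requirement(start, start)` zero, and is applied
unchanged in the 14-day pre-sampling windows (`windowed_chill_sum`).
Gaps of at most 6 h in the input record are closed by linear
interpolation; longer gaps are an error unless explicitly allowed. Mean
daily temperature requires at least 20 of 24 hours so sparse days are
never silently averaged.

## Phenology

The transition date of a cultivar is estimated from a weekly scion
forcing assay: the earliest cutting date whose buds reach at least BBCH
59 ("balloon") after 5 weeks under forcing conditions
(`transition_from_forcing`). Replicates of one cutting date are combined
by their **median** stage by default — robust to a single misscored
shoot; `min` (all must release) and `any` are available because the
aggregation rule is rarely reported in field studies. The chilling
requirement is then the CH or CP accumulated from the season start to the
transition date, and the heat requirement the GDH from the transition to
bud break; because field bud break is usually recorded as a window, both
endpoints are reported (`phenology_events`). When chill counting starts
is a genuine free parameter of such studies; the default is the first
sampling date of the campaign, echoed in every output.

## qPCR expression

Quality control removes whole samples and whole assays (primer pairs)
whose mean quality score falls below the threshold (default 0.65),
mirroring plate-level amplification-curve checks, and logs each removed
unit (`qc_filter`). Candidate reference genes are ranked by two
stability measures — a pairwise-variation measure in the geNorm style
(mean SD of pairwise log-ratios on replicate-averaged sample means) and
the comparative ΔCt measure (mean SD of per-replicate Ct differences) —
aggregated by the geometric mean of the per-measure ranks
(`reference_stability`). The two components coincide numerically when
computed at the same aggregation level, which is why they are computed at
the two levels their source methods use.

Relative expression uses the 2^−ΔΔCt method (`delta_delta_ct`):
technical replicates are averaged in Ct space within each biological
replicate, ΔCt is the target Ct minus the arithmetic mean Ct of the
reference genes (equivalently the geometric mean of their linear
quantities), and ΔΔCt subtracts the calibrator sample's ΔCt, so the
calibrator sits at 1 for every gene. Non-detected reactions are missing,
never zero; a gene with no detected reaction anywhere is excluded and
surfaced through the `undetected_genes` attribute (such "no expression"
genes are a real feature of dormancy panels); a calibrator lacking a gene
that *is* detected elsewhere is an error. Profile summarisation
(`summarize_profiles`) averages biological replicates per (gene, date,
cultivar) after the technical stage, so unbalanced designs weight each
biological replicate equally.

## Clustering

Trajectories of both cultivars are concatenated into one feature vector
per gene; genes with more than 30 % missing cells are dropped, interior
gaps are interpolated linearly along time, and rows are z-scored by
default so that *shape*, not amplitude, drives the clustering (a flag
disables this). `kmeans_best_of_n` runs `stats::kmeans`
(Hartigan–Wong, squared Euclidean) from `n_starts = 25` random starting
assignments with sub-seeds derived deterministically from one master
seed, and keeps the run with the smallest total within-cluster sum of
squares. A rare restart that ends with an empty cluster is scored
infinite and ignored. Because k-means labels are arbitrary, clusters are
reported in a canonical order (by the time index of each centroid's
maximum), which makes repeated runs comparable.

`wss_curve` reports the best-of-n WSS over a range of k and suggests an
elbow as the k maximising the second difference of the curve. The
suggestion is advisory: the heuristic provably peaks at the true k only
when planted clusters are about equally separated, whereas realistic
dormancy archetypes are not — early/endodormancy shapes resemble each
other more than they resemble the bud-break cluster — so on such data
the suggestion is typically smaller than the biologically chosen k. The
final k is deliberately left to the user.

## Correlation with temperature

`build_covariates` computes, per sampling date, the mean daily
temperature and the CH and CP accumulated in the 14 days before sampling
(configurable; a GDH column is optional). Windows truncated at the start
of the record are flagged and excluded from correlation by default.
`correlate` reports Pearson's r with the two-sided p-value from the t
transform, plus the OLS slope and intercept, per gene × covariate, both
pooled across cultivars (n ≈ 56) and per cultivar (n ≈ 28); no
multiple-testing correction is applied by default, matching per-test
reporting practice in the field, with an optional Benjamini–Hochberg
column clearly labelled as an extension. Zero-variance inputs yield a
missing r with a stated reason. `fit_line_by_group` exposes the
per-cultivar slopes and their difference — the readout for asking
whether two cultivars differ in the temperature sensitivity of a gene —
and `expression_onset_temperature` returns the warmest sampling day at
which a gene is still expressed. A useful property worth knowing when
reading pooled results: when two groups share a slope sign but differ in
intercept, pooling attenuates |r| below both per-group values.

## The synthetic-data generator

`simulate_dataset` produces a coupled campaign whose defaults emulate a
cool-temperate (Dresden-like) winter study design:

* **Temperature** — hourly from Sept 1 to Apr 30: an annual sinusoid
  (mean 9.5 °C, half-amplitude 9.5 °C, coldest around Jan 15, held
  constant within each day), a diurnal sinusoid (half-amplitude 3.5 °C,
  warmest at 14:00) and AR(1) noise (φ = 0.8, innovation SD 1.2 °C).
  Under these defaults a season accumulates roughly 70–90 CP by
  mid-to-late January, the range reported for apple cultivars in this
  climate.
* **Phenology** — the *true* transition is the first day cumulative CP
  reaches the cultivar threshold (defaults 72.9 and 83.9 CP for an early
  and a late cultivar); bud break is the first day the GDH accumulated
  since the transition reaches 2750. The forcing table scores 3
  replicates weekly from Dec 1 to early March with a 2 % per-replicate
  misclassification probability.
* **Expression** — 28 weekly samplings from Sept 20, two cultivars,
  3 biological × 2 technical replicates. 36 trajectory genes follow six
  archetypes built from Gaussian bumps anchored to the cultivar's
  transition (high-early plus ecodormancy peak with a minimum near the
  transition; a single endodormancy peak; a broad curve; an ecodormancy
  peak; a late ecodormancy peak; a logistic bud-break induction). Four
  genes are linearly temperature-coupled, `fold = a + b·T_daily` (one
  with cultivar-specific slope and intercept), three reference genes are
  flat, and two genes are silent. Fold changes become Ct via
  `Ct = base − log2(fold)` with biological (0.4 cycles) and technical
  (0.15 cycles) noise — typical qPCR magnitudes, chosen as generator
  defaults, not measured values. The first timepoint of the first
  cultivar is the calibrator.

The generator reproduces the statistical *structure* the analysis
assumes — coupled thresholds, archetypal shapes, replicate noise — but
not everything about real data: no primer-efficiency differences, no
amplification failures correlated with RNA quality, no within-tree
spatial variation, and weather beyond sinusoid + AR(1) (fronts, snow
cover) is absent. Passing recovery tests therefore demonstrates the
pipeline's correctness, not field-level power.

## Problem sizes and numerical choices in the test suite

The shipped tests run the dynamic-model oracle comparison on 1,000-hour
random series (tolerance 1e-9), the phenology round trip on 20
independently seeded winters with a planted 70 CP threshold, clustering
recovery on 36 genes × 6 archetypes with per-replicate noise at 20 % of
the 3-log2-unit signal range (adjusted Rand ≥ 0.9 required), correlation
recovery on 200 simulated 28-timepoint campaigns (slope −0.5, noise 20 %
of range; ≥ 95 % detection, null inflation ≤ 3 points), and the pooling
attenuation property on 100 simulations. These sizes keep the whole
suite under a minute while leaving the pass thresholds far from the
observed margins.

## Limitations

* The dynamic model is initialised with an empty intermediate at the
  series start; records beginning mid-winter will underestimate CP
  slightly for the first hours.
* Chilling and heat requirements inherit the resolution of the forcing
  assay (weekly here); estimates are upper brackets of the true
  requirement within one sampling interval's accumulation.
* 2^−ΔΔCt assumes equal (perfect) primer efficiencies;
  efficiency-corrected quantification is out of scope.
* The elbow suggestion, pooling behaviour and stability ranking are
  descriptive aids, not inference.
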