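---
title: "Models and methods behind dielMetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dielMetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielMetab)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the places
where the design was genuinely open and we had to decide. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The problem

In sunlit ocean surface waters, particulate (cell-associated) metabolite
concentrations oscillate with the day–night cycle: anabolism during the
day, catabolism at night. Given triplicate samples every 4 h over
multi-day periods, the questions are: which compounds oscillate with a
24-h period; when do they peak; how large is the daily swing; what does
that swing imply as a net carbon/nitrogen flux; which taxa and enzymes
(via transcripts) plausibly drive each pool; and does time of day
structure the community metabolome as a whole.

## 2. Signal model and the synthetic study

Each signal (metabolite or taxon × KEGG-ortholog transcript series) is

$$ y(t) = B\,\bigl(1 + a\,w(\theta(t))\bigr)\,\varepsilon, \qquad
   a = \frac{F-1}{F+1}, $$

where $B$ is the baseline, $w$ a unit waveform with maximum 1 at the peak
clock hour and minimum $-1$, and $\varepsilon$ multiplicative lognormal
noise with unit mean and coefficient of variation `noise_cv`. The
parameterization $a = (F-1)/(F+1)$ makes the peak-to-trough ratio of the
noiseless curve equal the fold change $F$ *exactly*, which keeps the
fold-change algebra of every downstream check closed-form.

Choices and why:

- **Waveform.** Default cosine; no waveform is stated for the field data,
  and the cosine makes phase and fold-change recovery exact on the
  sampling grid. A `truncated_cosine` option flattens the trough third of
  the cycle (cosine clipped at $-0.5$, rescaled to $[-1,1]$) because real
  series are non-negative and often asymmetric; the fold-change guarantee
  is preserved by the rescaling.
- **Noise.** Multiplicative lognormal per replicate (concentrations are
  positive; errors scale with signal), with $\sigma = \sqrt{\log(1+cv^2)}$
  and mean exactly 1. Within-triplicate CVs were not reported for the
  field study, so the default `noise_cv = 0.2` is a placeholder, exposed
  everywhere.
- **Design.** The default `study_design()` reproduces the field campaign:
  start 06:00, two periods of 4 and 3 days at 4-h resolution (25 and 19
  time points, both endpoints sampled), a 36-h gap (so period two starts
  at 18:00), triplicates, 3.5 L filtered.
- **Measurement layer.** Peak area = concentration × volume × response
  factor × ion suppression × per-sample injection factor × noise. The
  injection factor (lognormal, CV 0.1 by default) is shared by every
  compound and internal standard in a sample — exactly the variance BMIS
  is designed to remove. Ion suppression (default 0.7, i.e. the matrix
  response factor is 70% of the clean-water one) is per compound.
  Extraction blanks carry 2% of baseline. Calibration acquisitions
  (standard-addition curves, water/matrix spike pairs) are generated
  noise-free: they represent dedicated runs whose uncertainty is not the
  object of study here.
- **Covariates.** POC with baseline 2.0 µmol C L⁻¹ and a 1.2× daily fold
  change peaking at dusk; PN at a Redfield-like 0.30 µmol N L⁻¹;
  *Crocosphaera* at 1.6×10⁵ cells L⁻¹ (the value that, times the
  light-end quota of 0.8 fmol cell⁻¹, reproduces the printed ~128
  pmol L⁻¹ scale) and *Prochlorococcus* at 2×10⁸ cells L⁻¹, both with
  dusk-peaking cycles and 5% noise.
- **What the generator does *not* emulate:** chromatography and peak
  integration, detection limits and censoring, autocorrelated
  day-to-day drift, water-mass changes (the field design was Lagrangian
  precisely to suppress those), compositional coupling between compounds,
  and transcript count overdispersion. A green test therefore establishes
  that the *statistical machinery* is correct and calibrated under the
  stated noise model — not that field data meet that model.

## 3. Quantification

BMIS: for each compound and candidate internal standard, the normalized
area is `raw × mean(IS over pooled-QC) / IS in that sample`; the candidate
minimizing pooled-QC RSD wins, but only if it improves on "none" by at
least `min_improvement = 0.4` — the cut-off of the originating BMIS
method; the field paper itself states no number, so it is configurable.
Because the factor is anchored at the QC mean of the IS, the absolute
scale after normalization carries a bias of order $cv/\sqrt{n_{QC}}$; the
package's exact round-trip invariant is therefore stated (and tested) at
zero injection CV, and the noisy round trip is tested against the
replicate-noise bound instead.

The three calibration modes mirror field practice: isotopologue ratios
(exact under any shared per-sample factor, since the co-eluting heavy
partner is equally suppressed), standard additions (OLS of response on
added amount; endogenous = intercept/slope; the delta-method SE is
propagated; negative extrapolations are clipped to zero and flagged,
because concentrations are physical), and matrix-matched external
response factors (`rf_matrix = (spiked − unspiked)/spike`), with
`rf_matrix/rf_water` reported as the suppression factor. For
standard-addition compounds the fitted slope doubles as the matrix
response factor for the rest of the time series — the addition curve is
acquired once on a pooled sample, not per time point.

Blanks: the field protocol collects extraction blanks but does not state
how they were applied; we flag compounds whose mean field area is below
3× the mean blank area and never subtract, because subtraction is not
described and flags preserve data. Compounds with known extraction losses
(DMSP) carry an `underestimate` annotation through all outputs.

## 4. Rhythm detection

**Test statistic.** Observations are per-time-point triplicate medians
pooled by clock-phase class (6 classes at 4-h sampling) across the days of
an analysis scope. For each candidate peak class $k$, classes are arranged
cyclically from the antiphase (trough) class rising to $k$ and falling
back, and the umbrella statistic sums the pairwise Mann–Whitney counts
consistent with that rise-then-fall ordering (midranks for ties). This is
the Mack–Wolfe peak-known statistic applied to each cyclic rotation — the
same family RAIN draws on.

**Exact null.** For tie-free data the statistic decomposes as

$$ A_k \;=\; C \;+\; J_{up} \;+\; J_{down}, $$

where $C$ is the Mann–Whitney count of the peak class against everything
else and $J_{up}, J_{down}$ are Jonckheere–Terpstra statistics within each
arm (peak excluded) — and the three are *independent* under the null:
conditioning on which ranks land in the peak class fixes $C$, and the
within-arm arrangements are uniform and independent given any rank split.
The exact distribution is then a convolution of Gaussian-binomial
polynomials, costing polynomial time instead of enumerating
$N!/\prod n_i!$ assignments. The test suite verifies the decomposition
against brute-force enumeration on every design with ≤ 4 classes × 2
observations, and the normal approximation against the exact tail at
$n = 24$.

**Ties and large n.** Above `exact_n_max = 30` observations, or when ties
occur, a normal approximation is used with mean
$\tfrac12\sum_{(i,j)} n_i n_j$ over the counted ordered pairs, the
component-sum variance, a global Kendall-style tie factor
$1-\sum(t^3-t)/(N^3-N)$, and a 0.5 continuity correction. An exact
tie-corrected umbrella variance is not standard; since the pipeline's
inputs are continuous (medians of lognormals), ties are a measure-zero
event there, and the approximation is only a fallback.

**Multiple phases.** The $K$ candidate-phase p-values are combined by
Bonferroni, $p = \min(1, K \min_k p_k)$. RAIN's sharper correction for
the dependence among candidate phases is specific to its publication;
Bonferroni is conservative, which preserves the FDR < 0.05 contract. The
measured cost (computed by the acceptance script, not asserted here) is a
null rejection rate around 0.04 at $\alpha = 0.05$ rather than 0.05.

**Scopes.** Rhythm is assessed for each sampling period independently and
jointly; the joint scope runs one test on the pooled medians, since both
periods share the same 4-h clock grid, and BH correction is applied
across signals *within* each scope (the field methods do not say whether
FDR was re-run per period; within-scope is the self-consistent choice).

**Peak, amplitude, fold change.** Peak clock hour and amplitude come from
cosinor regression — closed-form `atan2` phase for one harmonic (the
default; the field paper's "periodic function" is not specified further),
a 0.1-h grid scan of the fitted curve for two. The mean daily fold change
is max/min of the medians within each complete 24-h window (windows start
at the first sample's clock hour by default; the field windowing is
unstated and the start is configurable), averaged across windows;
zero-minimum windows are excluded and counted. Peak-time precision is
limited by the 4-h sampling grid; the acceptance criterion (median error
≤ 2 h, half the interval) reflects that.

## 5. Budgets

All concentrations are pmol L⁻¹ internally; budget outputs are nmol C L⁻¹
d⁻¹. %POC is `100 × conc × n_C / (POC × 10⁶)` (pmol vs µmol), additive
across compounds. Net turnover is the mean daily max−min swing of the
medians — a conservative floor on the instantaneous flux, since
intra-window turnover and exchange with the dissolved pool are invisible
to it. Totals include only diel-flagged compounds by default.

Quota attribution multiplies taxon cell abundance by culture-measured
light-end/dark-end quotas to bracket the pool a taxon could account for,
and inverts the field pool into apparent fmol cell⁻¹ and
mg (g cell C)⁻¹ series.

The diazotroph budget: a trehalose swing × 2 glucose equivalents, ×
`atp_per_glucose`/`atp_per_n2` or `electrons_per_glucose`/`electrons_per_n2`,
whichever is limiting, over the measured N₂-fixation rate. The respiratory
constants are *assumptions* (defaults 30 ATP and 24 e⁻ per glucose; the
source literature defers to biochemistry references without printing
constants) and are configurable; fixation costs are the canonical 16 ATP
and 8 e⁻ per N₂. The oxygen-drawdown adjustment multiplies by
$1 - f_{O_2}$ with $f_{O_2} = 0.60$, so adjusted/unadjusted = 0.4 —
the identity behind the printed 9→3.6 and 28→11(.2) pair.

## 6. Linkage and phase lags

Metabolite–ortholog links are a curated offline TSV (live KEGG queries
would version-drift and need network). Transcript tables are group-summed
to taxon × KO; prokaryotic and eukaryotic layers are processed identically
but never merged. Lags are wrapped into $(-12, 12]$ with the antiphase
boundary mapped to $+12$.

One statistical honesty note: correlating *unwrapped* transcript peaks
(each moved to its representative within ±12 h of its metabolite peak)
against metabolite peaks is biased toward positive correlation by
construction — for independent peaks it converges to
$\mathrm{sd}(m)/\sqrt{\mathrm{sd}(m)^2+\mathrm{sd}(lag)^2} \approx 0.7$.
The package therefore reports Pearson on the raw peak hours as the primary
statistic (this is also the variant under which "no significant
relationship" is a meaningful null result), the unwrapped variant for
completeness, and the Jammalamadaka–SenGupta circular–circular correlation
as the statistically appropriate check.

## 7. Multivariate structure

Compounds are z-scored across samples before Euclidean distances (the
field figure says "standardized" without naming the metric; Bray–Curtis is
offered as the alternative and the tests pin both against brute-force
recomputation). Missing values are imputed as the compound minimum —
a minimal-assumption placeholder, logged. ANOSIM is rank-based:
$R = (\bar r_{between} - \bar r_{within})/(M/2)$, permutation p
$(1 + \#\{R^* \ge R\})/(1+B)$, with exhaustive relabeling available at
small n (the tests verify it against full enumeration at $n = 6$, and the
$R$ statistic against an independent implementation). NMDS is deliberately
not implemented — ordination internals are off-the-shelf and only the
grouping test is part of the tested surface.

## 8. Numerical and degenerate-input policy

- Constant series: umbrella p = 1, cosinor amplitude 0 with undefined
  (flagged) peak; ANOSIM on all-tied dissimilarities gives R = 0.
- Heavy-isotopologue area ≤ 0, zero cell abundance, zero POC/PN,
  nonpositive calibration slopes: flagged or refused with named errors,
  never silently patched.
- All randomness flows from explicit seeds; per-stage substreams are
  derived deterministically, and `run_pipeline` writes a manifest whose
  parameter hash is reproducible for identical configs.
- The exact-null cache is keyed by class sizes and peak position, so a
  1,000-signal batch on a shared design pays the convolution cost once.

## 9. Known limitations

- Pooling medians across days within a phase class treats days as
  independent — the independence assumption of the rank test; day-to-day
  autocorrelation would make the test anticonservative.
- Bonferroni across candidate phases is conservative (~0.04 observed null
  rate at α = 0.05); power figures should be read accordingly.
- The fold-change estimator (max/min on the 4-h grid) underestimates the
  continuous-time fold change when the peak falls between samples, and
  noise biases it upward; the two effects partially cancel at the tested
  noise levels.
- The "affected by internal standard adjustments" sample annotations of
  the source data have no described procedure and are not implemented.
- Full-field replication (downloading the public cruise data) is outside
  the desk-scale scope; the acceptance battery is property-based on the
  generator.
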