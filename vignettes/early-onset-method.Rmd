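---
title: "Detecting early-onset cancer signatures in small areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early-onset cancer signatures in small areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(earlyonset)
```

## The problem

Air pollution is an established lung carcinogen, but its effect is hard to
demonstrate in small areas: incident cases are sparse, rate-based indicators
have little power, and pollutant measurements rarely align with the
source under suspicion. An alternative signal is *timing*: a shared local
exposure tends to pull the age at cancer onset downward. If an area's
residents develop lung cancer systematically earlier than their age
structure predicts, that anticipation — measured in years — is itself a
quantitative signature of the exposure, and one that needs nothing beyond
routinely collected incidence and population counts.

The obvious confounder is demography: older populations have older onset
medians. The method therefore calibrates a **standard curve** across
reference cancer registries: the median age at onset `y` regressed on the
median age of the resident population `x`, one point per registry and sex.
The registries' scatter around that line absorbs, indirectly, the combined
effect of the many onset-shifting risk factors (smoking above all) that
vary between populations; an area must fall outside that scatter — not
merely off the line — before it is called divergent.

## Model

For reference registries \(i = 1, \dots, n\) of one sex,

\[
y_i \sim \mathcal N(\alpha + \beta x_i,\; \tau^{-1}),
\qquad
\alpha \sim \mathcal N(0, 10^{6}),\;
\beta \sim \mathcal N(0, 10^{6}),\;
\tau \sim \mathrm{Gamma}(0.5,\; 0.01),
\]

with Normal distributions parameterized by variance and the Gamma by shape
and rate. The posterior is sampled by a conjugate Gibbs sampler:
\((\alpha, \beta) \mid \tau\) is drawn jointly from its bivariate normal
full conditional and \(\tau \mid (\alpha, \beta)\) from its gamma full
conditional. The model is exactly conditionally conjugate under these
priors, so there is nothing to tune and the chain mixes essentially
immediately (split-\(\hat R\) < 1.01 and near-nominal effective sample
sizes in all test fixtures; see `convergence_diagnostics()`).

Sexes are modeled separately end to end — separate curves, separate
eligible counts, separate thresholds — because both the onset distribution
and the confounder mix differ by sex.

For a new unit with population median \(x\), the **posterior predictive
replicate** is \(y^{\mathrm{rep}} = \alpha + \beta x + \varepsilon\),
\(\varepsilon \sim \mathcal N(0, \tau^{-1})\), evaluated with one stored
standard-normal deviate per retained draw. Its equal-tailed 95% interval is
the band in which a new registry-like unit is expected with 95%
probability (`predictive_interval()`); a unit outside it is a visual
outlier.

## Per-area quantities

For a study area with observed onset median \(y_{\mathrm{obs}}\) at
population median \(x\):

* **Residual** — draws \(r_d = y_{\mathrm{obs}} - (\alpha_d + \beta_d x +
  \varepsilon_d)\); the reported residual is the draw mean (in years,
  negative = early onset) with its equal-tailed 95% credibility interval.
* **Posterior probability (PP)** — the lower-tail quantity
  \(\Pr(y^{\mathrm{rep}} \le y_{\mathrm{obs}} \mid x)\). Small PP means the
  observed onset is improbably early; PP near 1, improbably late; a unit
  on the curve has PP ≈ 0.5. One lower-tail number serves a two-sided
  decision rule: early if \(\mathrm{PP} \le t\), late if \(\mathrm{PP} \ge
  1 - t\).

Both quantities exist in two modes. The default **predictive** mode
includes the residual noise \(\varepsilon\) and asks whether the area is
an outlier with respect to the reference *scatter*; this is the mode
consistent with judging areas against the predictive band, and it is the
mode used for significance flags. The **parameter** mode omits
\(\varepsilon\) and asks only whether the area is off the *line*; it is
always more extreme than the predictive PP and is emitted alongside it
(`pp_parameter`) so the choice is auditable. In predictive mode the PP is
computed exactly given the draws, as the average of
\(\Phi\!\big((y_{\mathrm{obs}} - \alpha_d - \beta_d x)\sqrt{\tau_d}\big)\),
which removes the Monte-Carlo noise an indicator-based estimate would add.

**Eligibility and multiplicity.** Areas with more than one incident case
and a defined onset median are eligible; the rest are reported with
category `no_data`. The familywise level \(\alpha = 0.05\) is divided by
the per-sex eligible count (Bonferroni), and the comparison is inclusive
(\(\mathrm{PP} \le t\) is significant): with 40 eligible areas the
threshold is 0.00125, with 35 it is 0.05/35 ≈ 0.00143. The eligible count
is always computed from the data, never assumed.

**Map categories.** Residuals are binned for mapping into five bands:
\(\ge +2\) years postponement, between \(-2\) and \(+2\) neutral,
\((-4, -2]\), \((-6, -4]\), and \(\le -6\) years anticipation. The bands
partition the real line; the round boundaries are closed on the early
side, the convention adopted here since band labels quoted to two decimals
("+1.99 to −1.99") do not determine which side owns the boundary.

## Grouped medians

Registry tables arrive as quinquennial age bins (0–4, …, 85+), so medians
are estimated by the classical interpolation
\(m = L + \frac{N/2 - CF}{f}\,h\) within the median bin. This equals the
exact median of the density that spreads each bin's count uniformly over
the bin — a property the tests assert against an independent
CDF-inversion oracle, not approximately. Two conventions are fixed and
documented: when \(N/2\) falls exactly on a bin edge, the formula is
applied in the bin above the edge (continuity of the formula; the value is
that bin's lower edge); and a median falling in the open 85+ bin is
reported as undefined rather than extrapolated, because the bin has no
upper edge. Population and case medians share one code path. Users whose
medians come from exact ages can supply them directly via
`read_median_pairs()`; both input routes are first-class.

## The synthetic-data generator

Real small-area registry data of this kind are access-restricted, so the
generator reproduces the *statistical structure* the method assumes and
makes every stage testable end to end:

* **Reference registries** (default 36): \(x_i \sim \mathrm{U}(40, 50)\)
  years — the range of population medians typical of Italian regional
  registries — and \(y_i = 56 + 0.4\,x_i + \mathcal N(0, 1.5^2)\). The
  line and dispersion were chosen once to match the magnitude of the
  male lung-cancer standard curve (intercept in the mid-50s, shallow
  positive slope, a few years of registry scatter).
* **Study areas** (default 41, 30 cases each): each area gets a target
  median \(y^* = \text{line} + \text{shift}\), and its observed median is
  the *sample median* of `n_cases` individual onset ages drawn
  \(\mathcal N(y^*, 9^2)\). The 9-year within-area spread is a plausible
  dispersion for lung-cancer onset ages; what matters for validation is
  that sparse areas inherit realistic small-\(n\) median noise, including
  areas with 0–1 cases that the eligibility rule must exclude. Generated
  medians are therefore *not* the analytic target value — no inverse
  crime.
* **Binned route**: `binned_counts_for_median()` inverts the grouped
  median exactly by allocating real-valued counts to the two bins
  straddling the target (exact inversion on the integer lattice is
  impossible — achievable grouped medians form a discrete set — so case
  counts use rounded allocation and the binned case route is exact only
  to ~0.5 years, which the tests state explicitly).

The generator has a second study-noise mode, `study_noise = "model"`,
drawing area medians directly from the reference model
\(\text{line} + \mathcal N(0, \sigma^2)\). This is the exact null
hypothesis of the method and is what calibration simulations use: an
area generated by individual sampling has median noise
\(\approx \sigma_{\mathrm{onset}}\sqrt{\pi/(2n)}\) that the reference
curve does not model, so it is *not* null with respect to the predictive
band unless the two dispersions happen to coincide. Conversely, passing
calibration under `"model"` noise says nothing about how far real
sparse-area median noise departs from the reference scatter — that gap is
a genuine feature of the method, visible in the generator's default mode.

## Numerical choices

* Chains default to the production configuration (3 chains, 100,000
  burn-in + 100,000 retained) but every fit in the test suite runs
  desk-scale chains (hundreds of burn-in, a few thousand retained), which
  the conjugate sampler makes entirely adequate; a paper-scale fit takes
  a few seconds.
* The predictor is not centered by default, so the reported intercept is
  at \(x = 0\) and directly comparable to published curve equations; a
  `center_x` flag improves conditioning and maps draws back to the raw
  scale.
* Reference pairs are unweighted regardless of registry size.
* Seed determinism is end to end: identical inputs and seed give
  bit-identical draws, and the per-draw predictive deviates are stored in
  the curve object so `predictive_interval()` and `residual_summary()`
  share them.
* Validation problem sizes: the closed-form-posterior comparison runs
  3 × 5,000 retained draws; calibration uses 500 replicates of 40 null
  areas; power uses 100 replicates; predictive coverage uses 2,000 fresh
  registries across 100 reference draws (coverage is a *marginal*
  property over the joint draw of reference set and new unit —
  conditional on one 36-registry fit it fluctuates by a few percentage
  points).
* The MCMC is cross-checked two independent ways: against the exact
  posterior of the conditionally conjugate model, obtained by 1-D
  quadrature over \(\tau\) (no Monte Carlo), and against an independent
  JAGS run of the same model.

## Known limitations

* Confounding is handled only through the reference scatter; the method
  cannot attribute an early-onset signal to any specific pollutant, and a
  local excess of a non-pollution risk factor (e.g. occupational smoking
  clusters) produces the same signature.
* The weakly informative \(\mathrm{Gamma}(0.5, 0.01)\) precision prior
  slightly favors larger \(\tau\); at \(n = 36\) reference units this
  narrows the predictive band marginally (empirical coverage ≈ 94–95%
  rather than exactly 95%).
* No spatial structure: areas are tested independently, with a Bonferroni
  family; there is no spatial smoothing, autocorrelation model, or
  scan statistic, and no FDR alternative.
* Grouped medians from quinquennial bins carry interpolation error of a
  fraction of a bin width; onset medians in the open 85+ bin are
  undefined by construction.
* The sensitivity of results to the reference set is real and is handled
  operationally: rerun the analysis with a different reference CSV (e.g.
  a regional subset) and compare reports — no special code path.
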