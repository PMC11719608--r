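---
title: "Dietary cadmium risk assessment for chocolate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary cadmium risk assessment for chocolate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chocrisk)
```

chocrisk estimates the health risk that dietary cadmium in milk and dark
chocolate poses to different consumer groups. This vignette is the package's
account of the underlying science: the exposure models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic data generator does and does not emulate, the numerical
conventions, and the known limitations.

## The exposure and risk models

Cadmium accumulates in cocoa solids, so dark chocolate typically carries
more of it than milk chocolate, and the EU caps the concentration by cacao
content (0.1 / 0.3 / 0.8 mg/kg below 30 %, from 30 to below 50 %, and at
50 % and above — half-open intervals, boundary in the upper category).
Given a concentration `C` and a consumer group's chocolate ingestion rate,
four indices are computed.

**Estimated weekly intake and its share of the tolerable limit.** With `C`
in µg/kg and the weekly ingestion rate `IngR_w` in kg chocolate per kg body
weight per week,

$$\mathrm{EWI} = \mathrm{IngR}_w \cdot C, \qquad
  \%\mathrm{PTWI} = 100 \cdot \mathrm{EWI} / \mathrm{PTWI},$$

with the EFSA provisional tolerable weekly intake for cadmium,
PTWI = 2.5 µg/kg bw/week. EWI is in µg Cd per kg body weight per week.

**Hazard quotient (non-carcinogenic risk).** The USEPA chronic-dose ratio

$$\mathrm{HQ} = \frac{EF \cdot ED \cdot C \cdot \mathrm{IngR}_d \cdot CF}
                     {AT_{nc} \cdot BW \cdot RfD},$$

with exposure frequency `EF` = 350 days/year, exposure duration `ED` in
years, `C` in mg/kg, a daily ingestion rate, the g-to-kg conversion
`CF` = 1e-3, and the oral reference dose `RfD` = 1e-3 mg/kg/day. Because
the non-carcinogenic averaging time is defined as `AT_nc = 365 · ED` days,
`ED` cancels algebraically; `hq()` evaluates the reduced form
`(EF/365) · C · IngR · CF / (BW · RfD)` so the cancellation holds
bit-exactly, and `AT_nc` is never a separate configuration knob (keeping
the identity testable). HQ at or below 1 means no adverse non-carcinogenic
effect is expected.

**Cancer risk.** The incremental lifetime cancer probability

$$\mathrm{CR} = \frac{EF \cdot ED \cdot C \cdot \mathrm{IngR}_d \cdot CF
                      \cdot CSF}{AT_c \cdot BW},$$

with the cancer slope factor `CSF` = 6.1 (mg/kg/day)⁻¹ and the fixed
carcinogenic averaging time `AT_c` = 25,550 days (70 years). Unlike HQ, CR
grows linearly with `ED`. CR at or below 1e-6 is negligible, up to 1e-4
moderate, above that unacceptable.

**Intake conventions.** Consumption surveys report ingestion both per kg
body weight and in absolute grams per day, and the two lead to two model
forms. In *per-bw* mode (the deterministic default) `IngR_d` is in
g/kg bw/day and `BW` drops out of the equations. In *absolute* mode
`IngR_d` is in g/day and is divided by `BW`; this is the only form in
which body-weight variability is meaningful, so the Monte Carlo engine
uses it. At the nominal body weight the two modes agree exactly (a tested
identity).

`RfD` = 1e-3 mg/kg/day is a documented assumption: risk-assessment
practice for cadmium commonly uses this value, but sources print it
inconsistently, so it lives in the constants config where it can be
overridden.

## Population parameters

Seven consumer groups are modelled, each with weekly milk- and
dark-chocolate ingestion rates (kg/kg bw/week, from Serbian consumption
data), an exposure duration, and a nominal body weight:

| group          | milk rate | dark rate | ED (y) | BW (kg) |
|----------------|-----------|-----------|--------|---------|
| toddlers       | 0.00703   | 0.00525   | 2      | 12      |
| other_children | 0.00589   | 0.00547   | 5      | 23      |
| adolescents    | 0.00350   | 0.00157   | 7      | 43.4    |
| adults         | 0.00259   | 0.00154   | 30     | 70      |
| elderly        | 0.00179   | 0.00134   | 15     | 70      |
| pregnant_women | 0.00186   | 0.00214   | 30     | 70      |
| vegetarians    | 0.00322   | 0.00211   | 30     | 70      |

The nominal body weights are EFSA default values, not survey data; they
matter only in absolute mode, where they set both the absolute ingestion
rate and the dose divisor (which is why the two modes coincide at the
nominal weight).

## The synthetic concentration generator

The per-sample concentration measurements behind the published group
summaries are not public, so the package generates datasets with the same
statistical structure instead: for each of the three regulatory categories
it knows the sample count, minimum, maximum, mean and median
(3 / 98 / 49 samples; e.g. the dark category spans 0.014–0.29 mg/kg with
mean 0.057 and median 0.042).

For each category a lognormal is fitted in closed form from the mean and
median — `meanlog = ln(median)`, `sdlog = sqrt(2 ln(mean/median))`, from
the moment identities `median = exp(µ)` and `mean = exp(µ + σ²/2)` — and
values are drawn from it truncated to the published \[min, max\] by
*rejection*, never clamping, so the generated distribution has no atoms at
the boundaries and every generated value respects the published range.
Cacao content is drawn uniformly within the category's bounds; it
determines the MRL category but none of the risk indices.

Two quirks of the published summaries are handled explicitly. The
milk-below-30 % category's published median (0.031) exceeds its own
published maximum (0.030) — internally inconsistent — so the generator
fits that group from the mean and the range midpoint and says so with a
message. And a lognormal requires mean ≥ median; an infeasible pair raises
an error rather than a silent fallback.

What the generator does *not* emulate: any dependence of concentration on
cacao percentage within a category (in real data the two correlate), brand
or origin structure, measurement error, or values below the limit of
quantification. Passing tests on the fixture therefore demonstrate that
the *pipeline* reproduces the published boundary results under
summary-matched inputs, not that the generator recreates the real
dataset's fine structure.

Truncation shifts moments slightly: the fitted lognormal's untruncated
mean and median equal the published ones, the truncated sample's only
approximately (within 10 % at large n, a tested tolerance).

## The Monte Carlo engine

Parameter uncertainty is propagated by plain Monte Carlo (10,000
repetitions by default, no variance reduction), with each input given one
of three distribution families, following common spreadsheet risk-tool
practice: concentrations lognormal, ingestion rates and exposure frequency
triangular, body weight lognormal, all remaining constants point values.
Milk and dark exposures are drawn with their own concentration and
ingestion-rate variables and summed into one intake term; all inputs are
drawn independently (no correlation structure is published).

The distribution *families* are given; the *spreads* are not published
anywhere, so the defaults below are this package's documented choices, all
configurable and all echoed into the result object:

* ingestion rates: triangular at (0.8, 1.0, 1.2) × nominal — a ±20 %
  judgement band typical for consumption-survey uncertainty;
* exposure frequency: triangular (300, 350, 365) days/year — mode at the
  conventional 350 with plausible under- and over-shoot;
* concentration: lognormal fitted per chocolate type from the sample
  data's mean and median (the same closed form the generator uses), which
  makes the concentration spread the *between-sample* spread;
* body weight: lognormal with CV 0.2 around the nominal weight.

Because exact percentile values depend entirely on these unpublished
spreads, the package treats published percentiles as qualitative
orderings, not targets. Two orderings are robust under the defaults:
toddlers and other children have the highest HQ 90th percentiles (their
per-body-weight ingestion rates are much higher), and every group's CR
90th percentile exceeds 1e-6.

**Reproducibility.** One root seed governs a run; each symbol draws from
its own deterministically derived substream, so adding a symbol to a model
(say, switching HQ to CR) leaves every shared symbol's draws untouched — a
tested contract. Identical model + seed reproduce outputs bit-for-bit.

**Numerical conventions.** Triangular draws use the closed-form inverse
CDF (no installed package provides a triangular distribution, so the
package carries this small primitive itself). Percentiles use linear
interpolation between order statistics (R's "type 7"), stated because
percentile definitions differ across risk tools. A model in which every
input is a point collapses exactly — not approximately — to the
deterministic index value, which is asserted to machine precision in the
tests. Non-positive reference-dose draws (possible only with a
user-supplied stochastic RfD) are rejected and redrawn with a message.

## Sensitivity analysis

Contribution to variance follows the de-facto convention of spreadsheet
risk tools: the Spearman rank correlation of each input's draws with the
output is squared, the squares are normalized to sum to 100 %, and each
share keeps its correlation's sign. Point-valued inputs contribute exactly
0; a zero-variance output is flagged degenerate with all-zero
contributions. Ranking is by absolute contribution, ties broken
alphabetically. Body weight enters with a negative sign in absolute mode —
heavier consumers receive a smaller dose per kg — and is reliably the
dominant factor among the consumption/exposure inputs.

One honest caveat. With the concentration spread set to the
between-sample spread, the two concentration variables dominate the
variance share (together roughly 87 % for adults), and the remaining
contributions of exposure frequency and the two ingestion rates are nearly
identical in expectation (all ≈ 0.48–0.49 %, differing by less than 0.02
percentage points). Their relative order in any single 10,000-iteration
run is therefore decided by simulation noise. The package reports the
ranking at the default configuration and documents this fragility rather
than widening any spread to force a stable order; if the ordering of these
minor factors matters for an application, the spreads must come from real
survey uncertainty data.

## Problem sizes and runtimes

The test suite exercises the closed-form operations at full precision,
Monte Carlo properties at 2,000–10,000 iterations, the analytic 80/20
variance-share check at 10,000 iterations, and generator parameter
recovery at 100,000 draws; the full-population pipeline examples run at a
few hundred iterations per group. These sizes make the whole suite run in
seconds while keeping every stochastic assertion inside three standard
errors of its analytic expectation.

## Known limitations

* Single contaminant, single food: no hazard-index aggregation across
  metals or across the diet, so absolute risk statements concern chocolate
  only.
* Published group means and extremes of the deterministic indices are
  reproduced only approximately on synthetic fixtures, because the real
  per-sample data are unpublished and the published summary tables contain
  the internal inconsistencies noted above.
* The lognormality of real concentration data is unverifiable from the
  published summaries; the choice mirrors the probabilistic model's own
  assumption.
* Exact Monte Carlo percentiles are not reproducible without the original
  spread parameters; only the qualitative orderings above are.
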