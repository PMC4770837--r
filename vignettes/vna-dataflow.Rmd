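---
title: "Methods: the vnaflow batch data flow and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vnaflow batch data flow and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnaflow)
```

# Scope

`vnaflow` models the batch data flow of an isotope-dilution GC-MS/MS assay
for six volatile nitrosamines (VNAs) in urine — NDMA, NMEA, NDEA, NPIP, NPYR
and NMOR — at the concentrations relevant for population biomonitoring
(single-digit to low-hundreds of pg/mL). This vignette documents the
measurement model, the unit mapping, the synthetic-data generator and its
limits, the numerical choices, and the statistical reasoning behind the
validation estimators. It is a methods document; the README covers usage.

# The measurement model and unit mapping

Every sample receives a fixed spike of deuterated internal standard (ISTD)
per analyte. The instrument reports peak areas; quantitation happens in ratio
space, which cancels injection-volume and matrix effects to first order:

- response ratio $r$ = quant-ion area of native analyte / ISTD area,
- amount ratio $x$ = native mass / ISTD mass in the vial.

The calibration model is a straight line $r = a + b\,x$ fitted by weighted
least squares and inverted: $\hat x = (r - a)/b$. A fit with slope $b \le 0$
is rejected as unusable.

Two sample types share one curve, so the unit mapping matters:

- **Urine samples.** A 2 mL aliquot is extracted to a 500 µL final-volume
  equivalent. A urine concentration $c$ pg/mL corresponds to amount ratio
  $x = c \cdot 2 / 500 = c/250$; hence `ratio_to_conc()` multiplies by 250
  and amount ratio 1 is 250 pg/mL.
- **Solution calibrants.** A calibrant at $c$ ng/mL injected at 100 µL into
  the same 500 µL ISTD basis gives $x = c/5$. The working curve spans
  2–400 ng/mL, i.e. amount ratios 0.4–80 over eight log-spaced levels
  (`default_calibration_levels()`); the bottom standard corresponds to
  100 pg/mL urine-equivalent, near the analytes' limits of detection.

## Weighting

The default weighting is $1/x$. Over a 200-fold calibration range with
approximately proportional noise, ordinary least squares lets the top
standard dominate and distorts the low end where the biomonitoring signal
lives; $1/x$ is the conventional compromise between `none` and the more
aggressive `1/x2`, both of which remain available. The reported
$r^2$ is the *weighted* coefficient of determination — residual and total
sums of squares both computed under the fit weights about the weighted mean —
so that all three weightings are judged on the same scale they were fitted
under. `summary()` reports per-level back-calculation errors, which is the
diagnostic a reviewer actually reads.

# Batch anatomy

A batch is one 48-well plate: dichloromethane (DCM) method blanks in wells
A1 and F8, a low QC pool (50 pg/mL) in A2, a high QC pool (200 pg/mL
nominal) in A3, and 44 unknowns. The injection sequence is one leading
acetonitrile (ACN) blank, the calibrants in ascending order, three ACN
blanks to flush after the top standard, then the 48 wells in row-major
order — $1 + L + 3 + 48$ injections for $L$ calibration levels.

## Blank subtraction

The mean of the two DCM blanks' raw concentrations is subtracted from every
non-blank result in the batch; blanks keep their raw values. Negative
blank-subtracted results are retained (and flagged below-LOD) rather than
truncated: truncation would bias population means and defeat downstream
averaging. A run is rejected outright if any blank *strictly exceeds* its
per-analyte blank limit (a blank exactly at the limit passes), or if a blank
is missing or unquantifiable.

## Per-sample QA

Eight rules are evaluated for every (sample, analyte): quant-peak and ISTD
retention-time windows (±0.1 min), confirmation ion ratio within ±20 %
relative of the expected value (closed interval; a sample with no quant peak
fails this rule), a minimum ISTD area, the blank limit (real check for blank
roles, trivially passing otherwise), a carryover follow-up, a repeatability
check on reinjection pairs, and quantifiability (the response ratio must be
computable). The carryover rule flags any unknown whose immediate
predecessor in the sequence measured above 200 pg/mL blank-subtracted in
*any* analyte — the conservative reading, since a high injection can
contaminate the next regardless of which channel was high. Reinjection pairs
must agree within 20 % of their mean below 50 pg/mL and 10 % at or above it;
a passing reinjection is reported (value source "reinjection"), a failing
one sends the sample to re-preparation.

A *sample* is reportable only when all rules pass across all of its
analytes. This is deliberately strict: a failed ion ratio or ISTD in one
channel indicates an injection- or preparation-level problem, so the whole
injection is suspect. One consequence worth knowing: a specimen genuinely
containing none of an analyte produces no quant peak and therefore fails QA.
At biomonitoring concentrations with blank-level contamination present this
is rare for the panel as configured, but simulations with true
concentrations of exactly zero will show it prominently.

## Batch QC

The two QC pools are scored as z-values against a frozen characterization
(mean, SD per analyte and pool) and passed through a Westgard multirule
engine: 1_2s (warning only), 1_3s, 2_2s (across pools in the current run and
sequentially within a pool), R_4s, 4_1s and 10_x, each individually
switchable. The shipped characterization is derived analytically from the
simulator's noise model so that simulated batches are in-control by
construction; a production deployment replaces it with `characterize_qc()`
output from real history. In-control false-rejection behavior is testable:
with only 1_3s enabled, the theoretical rate is $2\Phi(-3) \approx 0.27\%$,
and the test suite verifies the engine hits it within binomial error at
$n = 10^5$.

# The synthetic-data generator

For each injection and analyte the generator draws

$$\text{quant area} = g \cdot x \cdot \text{ISTD area} \cdot f_{\text{run}}
  \cdot (1 + \varepsilon_{\text{prop}}) + \varepsilon_{\text{add}},$$

truncated at zero, where $g$ is the analyte's response factor, $x$ the true
amount ratio, $f_{\text{run}} \sim N(1, 0.05)$ a per-batch factor shared by
natives and ISTDs, $\varepsilon_{\text{prop}} \sim N(0, 0.05)$ proportional
noise, and $\varepsilon_{\text{add}} \sim N(0, 800)$ additive area noise.
ISTD areas are $N(10^5, 5\%)$; at the default response factors the additive
term corresponds to about 2 pg/mL of concentration noise, which sets the
LOD scale. Confirmation ions follow the expected ion ratio with their own
proportional noise; retention times jitter with SD 0.01 min. A non-cascading
carryover fraction (default 0.2 %) of the previous injection's signal can be
added. NDMA receives a constant process-contamination term (default
9.81 pg/mL, 1.5× its LOD) in *all* plate-processed wells — blanks, QCs and
unknowns alike — mimicking the ubiquitous environmental NDMA background that
motivates blank subtraction in the first place.

All randomness is keyed: `sim_config(seed)` plus a string key (batch id,
study id) is hashed to a 31-bit sub-seed, so studies are reproducible,
independent across keys, and never disturb the caller's RNG state.

**Scope and limits.** The generator models signal formation, not
chromatography: no peak shapes, no integration errors, no retention drift
within a batch, no matrix-specific suppression differences between urine
and solvent, and truncation-at-zero is its only detector nonlinearity.
It is a test harness for the *data flow*, not a simulator of the instrument.

# A documented consequence of the shipped defaults

The shipped blank limits are placeholders at 2× the shipped LODs
(13–16 pg/mL; 13.08 for NDMA). Consider what a blank measurement looks like
under the default noise model. The curve is fitted from single injections of
eight levels with 5 % proportional noise; the zero-extrapolation
uncertainty of that curve, propagated to a blank-level back-calculation,
is of order 10 pg/mL in concentration units — the intercept of a $1/x$-
weighted line is strongly influenced by the two or three lowest standards,
each carrying 5 % noise at 100–430 pg/mL urine-equivalent. Blank
measurements therefore scatter with an SD comparable to the blank limits
themselves, and a strict "any blank, any analyte, strictly above the limit"
rule rejects the majority (roughly 70–85 %) of fully-default-noise simulated
batches.

This is retained, not tuned away, because each ingredient is individually
correct: the rejection rule is the assay's actual rule; the limits are
documented placeholders; the noise defaults are realistic for single
injections. A production assay escapes this corner by (a) deriving blank
limits from its own long-term blank distribution and (b) running replicate
calibrant injections, which shrink the intercept noise. The acceptance
script reports the observed acceptance rate rather than asserting one.

# Validation statistics

## Limits of detection

`estimate_lod_3s0()` regresses per-pool SD on pool concentration (ordinary
least squares across at least three pools near the expected LOD) and reports
$3 S_0$, where $S_0$ is the intercept — the SD extrapolated to zero
concentration. A convex SD profile can extrapolate to a negative intercept;
that is an estimation failure, and the function says so and recommends the
CLSI alternative rather than reporting a nonsensical LOD.
`estimate_lod_clsi()` implements the classical LoB/LoD construction:
$\mathrm{LoB} = \bar b + 1.645\, s_b$ from blanks,
$\mathrm{LoD} = \mathrm{LoB} + 1.645\, s_{\text{low}}$ with the low-pool SD
pooled across pools.

A subtlety for anyone validating the $3S_0$ estimator against the
generator: pool measurements near zero are truncated at zero area, which
biases a naive SD estimate low. The clean construction subtracts each run's
own blank from its pool values; with the NDMA contamination term lifting raw
values well above zero, the blank-corrected values are Gaussian with
$S_0 = \sqrt{2} \times$ the additive concentration SD (the $\sqrt 2$ from
differencing two equal-variance measurements). The test suite recovers
$3 S_0$ this way over hundreds of simulated 60-run studies.

## Precision

`precision_summary()` reports intra-run CVs (SD/mean within each run) and an
inter-run CV defined as the CV of the run means. Both are scale-invariant by
construction. Two statistical facts shape how these should be read, and how
the tests are written:

- With 6 replicates per run, a single run's CV estimate has substantial
  sampling error, and the SD estimator carries the finite-sample $c_4$
  bias (about −5 % at $n = 6$).
- With 5 runs, a single study's inter-run CV has a relative sampling error
  around 35 %. Under proportional noise of 5 % and a run factor of 5 %,
  the *expected* intra-run CV is about 4.8 % and the expected inter-run CV
  about 5.1 % — so the ordering "inter > intra" holds reliably only in
  aggregate across many studies, never per-study at a high rate. The test
  suite therefore asserts the aggregate ordering over 200 studies, not a
  per-study one.

## Accuracy

`accuracy_summary()` computes baseline-corrected spike recovery,
$(\text{measured} - \text{baseline})/\text{nominal}$, across a 3-pool ×
3-level × 3-replicate matrix; `solution_accuracy_check()` verifies a
second-source calibrant against the working curve with a 90–110 % window.

# Numerical choices

- Calibration uses `stats::lm()` with explicit weights; the tests compare
  coefficients against a hand-rolled normal-equations solver at $10^{-10}$
  relative tolerance.
- Blank subtraction is exact arithmetic; a conservation identity
  (subtracted + blank mean = raw) holds to a few ulps and is enforced.
- The LIMS export fixes concentrations at three decimals
  (`sprintf("%.3f")`), making export → reimport → export byte-stable.
- Derived seeds are 31-bit (`< 2^31`), valid for `set.seed()` everywhere,
  and all seeded code restores the caller's RNG state.

# Problem sizes

A batch is 60 injections × 6 analytes = 360 records, quantified and
QA-evaluated (8 rules → 2,880 flags) in well under a second. Validation
studies (6 × 5 precision, 3 × 3 × 3 accuracy, 60-run LOD) and the
full acceptance run (hundreds of simulated batches and studies plus a
$10^5$-sample Westgard calibration) complete in seconds on a laptop-class
machine.

# Limitations

- The generator's scope limits above apply: no chromatographic artifacts,
  no within-batch drift, no urine-matrix heterogeneity.
- The shipped LODs, blank limits and QC characterization are documented
  placeholders; every production number must come from the deploying lab's
  own data.
- The Westgard engine evaluates one batch against supplied history; it does
  not persist history between calls — that is the caller's (or LIMS's) job.
- Reinjection and re-preparation are bookkeeping dispositions; no scheduling
  or instrument control is attempted.
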