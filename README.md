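# vnaflow

Automated batch data flow for isotope-dilution GC-MS/MS quantitation of six
volatile nitrosamines (VNAs) in human urine: NDMA, NMEA, NDEA, NPIP, NPYR and
NMOR. The package models the complete data path of a production assay — from
a 48-well plate worklist, through calibration, in-batch blank subtraction,
per-sample quality-assurance rules and Westgard multirule batch quality
control, to a LIMS-ready export — together with the method-validation
statistics (limits of detection, precision, accuracy) used to characterize
such an assay, and a synthetic injection-data generator for end-to-end
testing of all of it.

## The measurement model

Each analyte is paired with a deuterated internal standard (ISTD) spiked at a
fixed mass into every 2 mL urine aliquot, with a final extract volume
equivalent of 500 µL. Quantitation works in ratio space:

* **response ratio** = quant-ion peak area of the native analyte / peak area
  of its ISTD;
* **amount ratio** = native analyte mass / ISTD mass in the vial.

An eight-point calibration (amount ratios 0.4 to 80, log-spaced; solution
concentrations 2–400 ng/mL) is fitted by weighted least squares — weights
`1/x` by default, with `none` and `1/x2` available — and inverted to convert
each sample's response ratio to a urine concentration in pg/mL (amount ratio
1 corresponds to 250 pg/mL under the 2 mL / 500 µL mapping). Two
dichloromethane (DCM) blanks ride in wells A1 and F8 of every plate; their
mean concentration is subtracted from every non-blank result, and a run is
rejected outright if either blank exceeds the per-analyte blank limit.

Downstream of quantitation:

* **Per-sample QA** — eight rules per (sample, analyte): quant and ISTD
  retention time windows, confirmation ion ratio (±20 % relative; a missing
  quant peak fails), minimum ISTD area, blank limits, carryover follow-up
  (an unknown following any injection above 200 pg/mL must be reinjected,
  with tiered 20 %/10 % repeatability on the reinjection pair), and a
  quantifiability check. A sample is reportable only when every rule passes.
* **Batch QC** — low (50 pg/mL) and high (200 pg/mL) spiked urine pools are
  scored as z-values against a frozen characterization and run through a
  configurable Westgard engine (1_2s warning, 1_3s, 2_2s, R_4s, 4_1s, 10_x).
* **Method validation** — `estimate_lod_3s0()` (3·S₀ from a linear fit of
  per-pool SD against concentration), `estimate_lod_clsi()` (LoB/LoD),
  `precision_summary()` (intra-run and inter-run CVs) and
  `accuracy_summary()` (baseline-corrected spike recovery).

## Quick start

Fit and inspect a calibration:

```r
library(vnaflow)
x <- default_calibration_levels()        # 0.4 ... 80, log-spaced
set.seed(42)
y <- 0.93 * x * (1 + rnorm(8, 0, 0.03))  # synthetic responses
cal <- fit_calibration(x, y, weighting = "1/x")
cal
#> Isotope-dilution calibration
#>   response_ratio = 0.00427228 + 0.939757 * amount_ratio   [weights: 1/x]
#>   weighted r-squared: 0.999539   levels: 8   points: 8
predict(cal, response_ratio = c(0.02, 0.2, 2))
#> [1] 0.01673594 0.20827471 2.12366247
```

`summary(cal)` adds per-level back-calculation errors; `coef()`, `plot()` and
`residuals()` behave as for any fitted model object.

Run a full simulated batch through the pipeline:

```r
truth <- c(NDMA = 12, NMEA = 9, NDEA = 14, NPIP = 25, NPYR = 11, NMOR = 8)
cfg <- vna_config(sim = sim_config(seed = 7, proportional_cv = 0.01,
                                   true_conc_pg_ml = truth))
out <- run_pipeline(cfg, simulate = TRUE)
out$accepted
#> [1] TRUE
head(out$lims[out$lims$reportable,
              c("sample_id", "analyte", "conc_pg_ml", "below_lod")])
#>     sample_id analyte conc_pg_ml below_lod
#> 25 BATCH1-S02    NDEA     10.880     FALSE
#> 26 BATCH1-S02    NDMA     13.321     FALSE
#> 27 BATCH1-S02    NMEA      8.834     FALSE
#> 28 BATCH1-S02    NMOR      8.647     FALSE
#> 29 BATCH1-S02    NPIP     23.341     FALSE
#> 30 BATCH1-S02    NPYR      9.212     FALSE
table(out$qa$dispositions$disposition)
#>  fail_qa reinject   report
#>        6        1       53
```

The returned bundle also carries the injection sequence, the per-rule QA flag
table, the Westgard evaluation, the simulation truth table and a recovery
summary; passing `out_dir=` writes all of them as CSV files.

Estimate a limit of detection from a simulated 60-run blank/low-pool study:

```r
sim <- sim_config(seed = 11, proportional_cv = 0, istd_area_cv = 0,
                  run_cv = 0, response_factor = c(NDMA = 1))
d <- generate_validation_study("lod_pools_60", sim,
                               panel = default_panel()[1, ])
blanks <- d[d$sample_type == "dcm_blank", ]
pools  <- d[d$sample_type == "pool", ]
bc <- data.frame(nominal_pg_ml = pools$nominal_pg_ml,
                 measured_pg_ml = pools$measured_pg_ml -
                   blanks$measured_pg_ml[order(blanks$run)][pools$run])
estimate_lod_3s0(bc, analyte = "NDMA")
#> LOD (three_s0, NDMA): 8.786 pg/mL  [S0 = 2.929]
```

## A deliberate, documented behavior at the shipped defaults

The shipped blank limits are placeholders at 2× the shipped LODs. With the
default single-injection `1/x` curve and 5 % proportional noise, the
extrapolation noise of a blank-level measurement is of the same order as
those limits, so a large share of simulated batches at full default noise is
blank-rejected (the acceptance script reports the rate; around 15–25 %
accepted). This is a faithful consequence of combining a strict blank-limit
rule with placeholder limits, not a bug; a production deployment derives
blank limits from its own long-term blank characterization. The methods
vignette walks through the arithmetic.

## Tests and acceptance script

```sh
NOT_CRAN=true Rscript -e 'testthat::test_dir("tests/testthat",
                          package = "vnaflow", load_package = "installed")'
```

The suite includes brute-force oracle comparisons for the calibration
algebra, every QA rule and disposition, and the Westgard engine, plus
Monte-Carlo recovery checks for the LOD and precision estimators.

A standalone acceptance run writes the headline quantities (zero-noise
identity error, calibration r², blank-subtraction conservation, Westgard
1_3s false-rejection rate, precision CVs, mean 3·S₀ LOD, mean spike
recovery, batch acceptance rate) to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```

All randomness derives deterministically from `--seed`; the same seed gives
byte-identical output.

## Command-line interface

`inst/cli/vnaflow.R` wraps the pipeline for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vnaflow.R", package="vnaflow"))')" \
  simulate --seed 7 --out batch_out
```

## Documentation

Every exported function has reference documentation; the methods vignette
(`vignettes/vna-dataflow.Rmd`) covers the measurement model, the unit
mapping, the noise model and its limits, and the statistical reasoning
behind the validation estimators.
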