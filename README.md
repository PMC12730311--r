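# soilpmb

Targeted quantification of the lipopeptide antibiotic **polymyxin B
(PMB)** in soil from UPLC–MS/MS multiple-reaction-monitoring data, and
ecological risk assessment of the measured residues.

PMB is both a last-resort clinical antibiotic and a natural metabolite
of *Paenibacillus polymyxa*, a soil bacterium used as a crop inoculant.
Monitoring the soil PMB burden after inoculation — and deciding whether
it matters ecologically — takes a chain of computations that this
package implements as tested, reusable functions:

1. **Signal → concentration.** PMB is quantified as the sum of the peak
   areas of its two major components (B1: m/z 602.25 > 100.80, B2:
   m/z 595.40 > 101.25). Peaks are integrated above a straight-line
   baseline, summed, and back-calculated through an unweighted
   least-squares matrix-matched calibration *y = ax + b* over
   10–1000 ng/g. Detection limits use the S/N = 3 (LOD) and S/N = 10
   (LOQ) conventions.
2. **Method validation.** Accuracy, intra-/inter-day precision (RSD),
   extraction recovery (pre- vs post-extraction spike), matrix effect
   (post-extraction spike vs solvent), and blank selectivity, each
   classified against the standard acceptance windows (accuracy and
   matrix effect 85–115%, recovery 80–120%, RSD < 15%, interference
   ≤ 5%).
3. **Dissipation kinetics.** Log-linear first-order fits on the
   post-peak phase: *k*, DT50 = ln 2 / *k*, and elimination after five
   half-lives; one-way ANOVA of each sampling day against baseline.
4. **Risk.** The equilibrium-partitioning chain
   *K*<sub>soil-water</sub> = *F*<sub>water</sub> + *F*<sub>solid</sub> · *K*<sub>P,soil</sub> · ρ<sub>solid</sub>/1000,
   PNEC<sub>soil</sub> = PNEC<sub>water</sub> · *K*<sub>soil-water</sub>/1000,
   RQ = MEC/PNEC<sub>soil</sub>, with three risk tiers
   (RQ < 0.1 low, 0.1 ≤ RQ ≤ 1 medium, RQ > 1 high).

A first-class synthetic-data generator (`simulate_chromatogram()`,
`simulate_calibration_series()`, `simulate_validation_experiment()`,
`simulate_soil_timeseries()`) produces every input with known ground
truth, so the whole chain is testable at the desk.

## Worked example

```r
library(soilpmb)

# calibrate from simulated seven-level matrix-matched standards (3% CV)
m     <- signal_model(baseline_noise_sd = 0)
cal   <- simulate_calibration_series(model = m, noise_cv = 3, seed = 101)
resp  <- sum_calibration_responses(cal)
curve <- fit_calibration(resp$level, resp$response)
curve
#> Calibration: y = 33013.7 x + 91825  (R^2 = 0.9991, range 10-1000 ng/g, 7 levels)

# quantify a soil sample from its two component chromatograms
trs <- default_transitions()
chs <- lapply(analyte_subtypes("PMB"), function(s)
  simulate_chromatogram(trs[[s]], amount = 221, model = m, sample_id = "s1"))
quantify_sample(chs, curve)
#> Sample 's1': 224.8 ng/g (0.2248 mg/kg)

# 28-day dose-by-time soil series and its risk-quotient trajectory
ts  <- simulate_soil_timeseries(seed = 1)
res <- assess_timeseries(ts, risk_scenario())
res$table[res$table$dose_group == 2e8, ]
#>    dose_group day  mec_mg_kg        rq category
#> 26      2e+08   0 0.02259012 0.1003952   medium
#> 27      2e+08   7 0.19351494 0.8600206   medium
#> 28      2e+08  14 0.21214625 0.9428219   medium
#> 29      2e+08  21 0.19106349 0.8491258   medium
#> 30      2e+08  28 0.16210335 0.7204209   medium
```

The calibration R² above 0.999 reflects the 3% injection CV; the
quantified sample recovers its true 221 ng/g within that calibration
noise. The top-dose trajectory peaks at day 14 at an RQ just below 1:
elevated, medium-tier risk throughout the incubation, never crossing
into the high tier. The risk constants behind the table are
*K*<sub>P,soil</sub> = 2500 L/kg, *K*<sub>soil-water</sub> = 3750.2 and
PNEC<sub>soil</sub> = 0.225 mg/kg dry soil
(`pnec_soil(risk_scenario())`).

See `vignettes/soil-polymyxin-pipeline.Rmd` for the full account of the
models, defaults, and numerical choices.

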