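# fdgkin

Two-tissue-compartment FDG kinetic modeling and protocol simulation for
small-animal PET.

## What problem this solves

Quantifying cerebral glucose metabolism from a dynamic FDG scan requires
fitting the two-tissue-compartment model

    dC1/dt = K1·Cp − (k2 + k3)·C1 + k4·C2
    dC2/dt = k3·C1 − k4·C2

to a tissue time–activity curve (TAC) driven by the arterial plasma input
function (IF), with the measured signal composed as
`(1 − v_b)·(C1 + C2) + v_b·C_blood` to account for the fractional blood
volume `v_b` of the region. The macro-parameters follow as

    K_FDG  = K1·k3 / (k2 + k3)                    (mL/min/cm³)
    CMRglc = K_FDG / LC · G_p · 100               (µmol/min/100 g)

The estimated rate constants are notoriously sensitive to details that
are easy to get wrong: the assumed `v_b`, sub-10-second timing mismatches
between IF and TAC, scanner/counter calibration, data smoothing, the
blood-cell-uptake correction used to derive plasma from whole-blood
activity, and the administration protocol (bolus vs. infusion) combined
with the blood sampling interval. `fdgkin` implements the model, the
estimator, and a full synthetic-scan simulation framework to quantify
each of these error sources, for PET methodologists and preclinical
imaging labs.

Highlights:

* `fit_fdg2tc()` — bounded multistart nonlinear least squares returning a
  classed model object with `print`, `summary`, `coef`, `vcov`,
  `fitted`, `residuals`, `predict`, `plot` and `simulate` methods.
* `plasma_from_blood()` / `blood_from_plasma()` — four plasma/whole-blood
  conventions (mouse exponential, rat bi-exponential, constant 1.165,
  none).
* `fit_triexp()`, `simulate_if()`, `rescale_protocol()` — tri-exponential
  infusion IF modeling and equal-dose protocol conversion.
* `make_fixture()` — self-consistent synthetic scans (IF, blood, frame
  schedule, noise-free TAC, noisy replicates) from one seed.
* Study functions: `vb_sweep_study()`, `time_shift_study()`,
  `calibration_study()`, `smoothing_study()`, `blood_correction_study()`,
  `protocol_sampling_study()`, `k1_k2_tradeoff()`.

## Worked example

```r
library(fdgkin)

scan <- make_fixture(seed = 1)      # synthetic 300-s-infusion scan
scan
#> Synthetic FDG scan (seed 1): 300-s protocol, 36 frames, 10 noisy TAC replicates
#> Two-tissue-compartment parameters:
#>   K1 = 0.3203 mL/min/cm3, k2 = 0.543, k3 = 0.07958, k4 = 0 1/min, vb = 0.055

fit <- fit_fdg2tc(scan$tac, scan$plasma, scan$blood,
                  fit_k4 = FALSE, multistart = 3)
summary(fit, glucose = 11.9)
#> Two-tissue-compartment fit summary
#>
#>    Estimate Std. Error
#> K1  0.32031          0
#> k2  0.54297          0
#> k3  0.07958          0
#> k4  0.00000    (fixed)
#> vb  0.05500    (fixed)
#>
#> K(FDG) = 0.04094 mL/min/cm3, CMRglc = 81.2 umol/min/100g
#> chi2 = 1.87e-19 over 36 frames; converged: TRUE
```

The fit on the noise-free TAC recovers the generating parameters to
machine precision (the standard errors are zero because the residuals
are); `K_FDG` = 0.041 mL/min/cm³ and, with plasma glucose 11.9 mmol/L and
lumped constant 0.6, CMRglc = 81 µmol/min/100 g — typical numbers for
isoflurane-anesthetized mouse cortex.

The identifiability demonstration behind the infusion-duration
recommendation:

```r
tr <- k1_k2_tradeoff(kinetic_params(0.328, 0.550, 0.079, k4 = 0))
sprintf("k2 factor (SSD): %.4f  closed form: %.4f",
        tr$k2_factor, tr$k2_factor_closed_form)
#> "k2 factor (SSD): 1.1226  closed form: 1.1144"
```

i.e. a 10% increase in K1 is almost perfectly masked by an ~11% increase
in k2; the small residual that distinguishes the two sits around the
infusion stop and vanishes as the infusion lengthens
(`k1_k2_tradeoff(..., protocol = 900)`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the K_FDG values implied by
published rate-constant sets, the compensating k2 multiplier of the
K1/k2 trade-off under a 300-s infusion, and the asymptote of the mouse
plasma/blood correction, and writes them as a JSON record.

## Design notes

See `vignettes/fdg-kinetic-modeling.Rmd` for the model derivation,
numerical scheme, the synthetic world and its limits, and the reasoning
behind every tunable default.
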