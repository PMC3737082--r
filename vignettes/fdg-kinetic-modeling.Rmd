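---
title: "Two-tissue-compartment FDG kinetic modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tissue-compartment FDG kinetic modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Dynamic FDG PET quantification rests on the two-tissue-compartment (2TC)
model. FDG in arterial plasma (concentration $C_p(t)$) exchanges with a
free tissue pool $C_1$ and is phosphorylated into a trapped pool $C_2$:

$$
\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1 + k_4 C_2, \qquad
\frac{dC_2}{dt} = k_3 C_1 - k_4 C_2 .
$$

$K_1$ (mL/min/cm$^3$) is the plasma-to-tissue clearance, $k_2$ the efflux
rate, $k_3$ the phosphorylation rate and $k_4$ the dephosphorylation rate
(all min$^{-1}$). With $k_4 = 0$ the model is irreversible and the tissue
response to a plasma impulse,
$h(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$ with
$A_1 + A_2 = K_1$, has $\lambda_1 = 0$: a non-decaying trapped component
with amplitude $K_1 k_3/(k_2+k_3)$. That amplitude is the net uptake rate
constant

$$
K_{FDG} = \frac{K_1 k_3}{k_2 + k_3}, \qquad
CMR_{glc} = \frac{K_{FDG}}{LC}\, G_p \cdot 100,
$$

where $LC$ is the lumped constant (default 0.6), $G_p$ the plasma glucose
in mmol/L ($=$ µmol/cm$^3$), and the factor 100 converts to
µmol/min/100 g at an assumed tissue density of 1 g/cm$^3$ (the density is
a convention; no consensus value is printed in the small-animal
literature).

What the scanner measures in a tissue region also contains intravascular
activity. `model_tac()` composes the measured signal as

$$
C_{model}(t) = (1 - v_b)\,(h \ast C_p)(t) + v_b\,C_b(t),
$$

with $C_b$ the *whole-blood* curve and $v_b$ the fractional blood volume,
then averages over each reconstruction frame. Two conventions exist for
the blending; the $(1-v_b)$-scaled form above is the default (it is what
the common commercial tool uses), and `blend = "add"` gives the plain
additive form for cross-tool comparison. The whole-blood curve, not the
plasma curve, feeds the $v_b$ term, because the vasculature contains
blood.

**Contracts:** all input activities are assumed decay-corrected (the
package never applies radioactive decay), times are seconds, rate
constants per minute, activities kBq/cm$^3$.

## Numerical scheme

The convolution runs on a uniform 1-s internal grid — the native temporal
resolution of coincidence-counter blood data — using an FFT product with
trapezoid end corrections; frame values are trapezoid means over
$[t_{start}, t_{end}]$. Input curves are interpolated linearly onto the
grid (this is also how subsampled input functions at 30 s or 60 s enter
the fit). Against an independent fixed-step Runge–Kutta integration of
the state equations the frame values agree to better than 0.1% (tested
over random parameter sets), and the late-time Patlak slope of an
irreversible simulation reproduces $K_{FDG}$ to 4 significant digits.

## Fitting

`fit_fdg2tc()` estimates $K_1, k_2, k_3$ (optionally $k_4$ and $v_b$) by
bounded nonlinear least squares on the frame values. The reference
implementation in the field uses Levenberg–Marquardt; that library is not
part of this stack, so the package uses the PORT trust-region routine
(`nlminb`) with box bounds (rates in $[0, 5]$, $v_b \in [0, 0.2]$), which
solves the same normal-equations problem with equivalent local behaviour.
Robustness ("convergence to unique solutions") comes from multistart: the
default start ($K_1{=}0.2, k_2{=}0.4, k_3{=}0.05, k_4{=}0.01,
v_b{=}0.05$) plus $\pm 50\%$ jittered restarts under a fixed seed; the
best loss is polished at tight tolerance. Weights are uniform per frame
by default — the reference tool's weighting is not public — with
frame-duration weighting as an option.

The Pearson statistic $\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ is reported
as a goodness-of-fit *indicator*, never used as the loss: as a loss it is
undefined near zero activity and would upweight early empty frames.
Because the fit objective differs from whatever the reference tool
minimizes, absolute $\chi^2$ values are not comparable across tools; only
orderings and argmins are used in the studies. Parameter standard errors
come from the Jacobian-based covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum.

Two structural identities anchor the estimator tests: multiplying the TAC
by a calibration factor at $v_b = 0$ is absorbed exactly by $K_1$ (the
rate constants sit in the exponents and cannot absorb a scale), and a
joint rescaling of TAC and input function changes nothing.

## Input functions

Whole-blood activity understates plasma activity because FDG enters red
cells slowly. `plasma_to_blood_ratio()` implements four conventions: the
mouse mono-exponential correction
$0.386\,e^{-0.191 t} + 1.165$ ($t$ in minutes; asymptote 1.165, the
equilibrium plasma/blood partition coefficient), a rat bi-exponential
correction, the constant factor 1.165, and no correction (whole blood as
input function). Conversions between plasma and blood are pointwise and
mutually exact inverses.

Infusion-shaped input functions are described by a tri-exponential model:
during a constant-rate infusion the plasma activity rises as a weighted
sum of three saturating exponentials toward the extrapolated steady state
$A + B + Z$, and decays component-wise after the stop $t_i$; the weights
are the fractional areas $f_a = A\alpha / (A\alpha + B\beta + Z\zeta)$
(cyclic), which sum to one. Amplitudes are proportional to the infusion
rate, so `rescale_protocol()` converts between protocols at equal dose by
scaling $A, B, Z$ with the inverse duration ratio.

`fit_triexp()` exploits that the curve is *linear* in the effective
weights $w_c = (A{+}B{+}Z) f_c$ once the rates are fixed: a Nelder–Mead
search over the three log-rates with an inner non-negative linear solve
(variable projection), restarted from a log-spaced rate grid. This is
deterministic and much more reliable than a single-start 6-parameter
spreadsheet fit. The infusion stop is detected as the raw curve maximum
inside the window flagged by a 5-sample moving average — a deterministic
surrogate for "reading the maximum off the plot" that is exact on clean
curves (the moving average alone is biased early because the post-stop
decay is steeper than the rise).

A caution established by the package's own Monte-Carlo tests: the
extrapolated steady state $A+B+Z$ is dominated by the slow component
($\zeta = 0.01$ min$^{-1}$), which is only $\sim$5% saturated after a
5-min infusion. Under the stated measurement noise a plain unweighted fit
recovers it with errors up to $\sim$15%; inverse-variance weighting with
the known noise SD (the `sd` argument) brings the mean error under 5%.
Rate constants of the *kinetic* fit are far less sensitive, because they
depend on the curve over the scan, not on an extrapolation.

## The synthetic world

`make_fixture()` generates self-consistent scans:

* **Canonical input function.** Rates $(\alpha, \beta, \zeta) = (3.0,
  0.3, 0.01)$ min$^{-1}$ and a 300-s stop with peak 2000 kBq/cm$^3$ are
  fixture conventions (real per-scan fitted parameters are not publicly
  available). The amplitude split (effective weights $800:1000:8800$) was
  chosen once so the plasma tail at 45 min is $\approx$15% of the peak,
  matching the shape of measured FDG infusion input functions in mice; a
  thin-tailed alternative would make the steady state unidentifiable and
  the blood integral unrealistically small.
* **Truth parameters** center on $K_1 = 0.328$, $k_2 = 0.550$,
  $k_3 = 0.079$ min$^{-1}$, $k_4 = 0$, $v_b = 0.055$ — a typical
  experimental rate-constant set — with an optional uniform $\pm$5% draw
  on $K_1, k_2, k_3$ emulating between-animal spread.
* **Blood** is derived from the plasma curve by exact inversion of the
  mouse correction, as in the simulation design it emulates.
* **Frame schedule**: 33–39 contiguous frames over 45 min, 10-s frames
  bracketing the protocol stop, none longer than 240 s, built
  deterministically (pre-stop filler, 10-s peak block, graded
  30/60/120/240-s tail).
* **Noise**: input-function samples get Gaussian noise with
  SD $= 32.5 + 0.05\,C_p$ kBq/cm$^3$ (midpoints of the stated 25–40 and
  4–6% ranges); TAC frames get SD $= 0.8\,C/\Delta t$. One noisy input
  function and ten noisy TACs per scan. Negative post-noise values are
  kept; clipping would bias low-activity frames.

The generator does **not** emulate scanner resolution, partial-volume
effects, scatter/randoms, decay, dispersion in the sampling catheter, or
a fast initial bolus distribution phase. A green test therefore
establishes correctness of the estimator and the direction/size of
methodological distortions *within this idealized world*, not agreement
with any particular animal's numbers.

## Study design choices

* **LOWESS smoothing** uses span 0.1 and 2 robustifying iterations
  (MATLAB `rlowess`-like); there is no field-wide span convention, so the
  span is an exposed configuration knob.
* **Time shifts** move the input function's sample times and re-sample
  onto the original grid with constant-end extrapolation.
* **Statistics**: homoscedastic two-tailed t tests for independent
  simulation arms, paired t tests for same-scan treatment arms,
  Bonferroni correction with the number of comparisons $m$ exposed as an
  argument rather than hidden in the implementation.
* **Protocol/sampling study** estimates $k_4$ by default, as kinetic
  modeling tools conventionally do. This matters: with $k_4$ frozen at the
  generator's true 0, the $k_3$ inflation under coarse bolus sampling
  disappears (the compensation then runs entirely through $K_1$ and
  $k_2$), while with $k_4$ free every rate constant participates and all
  of them inflate.
* **K1/k2 trade-off**: the compensating $k_2$ multiplier is defined as
  the minimizer of the sum of squared differences between the
  frame-averaged TACs. The closed-form multiplier that preserves
  $K_{FDG}$, $(c\,(k_2+k_3) - k_3)/k_2 = 1.114$ for $c = 1.1$, serves as
  an independent oracle. The SSD minimizer depends mildly on the residual
  weighting: equal-weight frames emphasize the dense 10-s frames around
  the infusion stop and give $\approx 1.12$; relative-error weighting
  gives $\approx 1.11$. The package reports both the SSD minimizer and
  the closed form.

## Known limitations

* Absolute $\chi^2$ levels are implementation-specific; only shapes and
  argmins transfer across tools.
* Free-$v_b$ fits on infusion data are structurally ill-conditioned (the
  package's own replicate studies show the $v_b$ coefficient of variation
  an order of magnitude above that of $K_{FDG}$); fixing $v_b$ to an
  anatomical literature value is the recommended practice.
* The 2TC implementation deliberately excludes 1-tissue and 3-tissue
  variants, spectral analysis, and graphical methods (Patlak appears only
  as a test oracle).
* On the synthetic fixtures $k_3$ *rises* slightly with the assumed
  $v_b$ while $K_1$ and $k_2$ fall; experimental data showed all
  constants falling, with the $k_3/k_4$ pattern described as complex.
  The direction properties asserted in the tests are restricted to the
  transport parameters.

## A minimal session

```{r, eval = FALSE}
library(fdgkin)
scan <- make_fixture(seed = 1)
fit <- fit_fdg2tc(scan$tac, scan$plasma, scan$blood)
summary(fit, glucose = 11.9)
vb_profile(scan$tac, scan$plasma, scan$blood)
```
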