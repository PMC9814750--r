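---
title: "Models and methods behind ionspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionspec)
```

`ionspec` quantifies where Hofmeister ions sit around a small zwitterionic
dipeptide by combining three spectroscopic analyses. This vignette explains
the models each module implements, the assumptions they make, the defaults
and why they were chosen, and what the synthetic-data generator does and
does not emulate.

## Dielectric relaxation

### Model

A two-mode relaxation model describes aqueous peptide solutions at
microwave frequencies: a Debye mode for the slow rotational relaxation of
the zwitterion (loss peak near 1 GHz) and a Cole–Cole mode for the water
network (near 20 GHz), plus a high-frequency offset $\varepsilon_\infty$
and an Ohmic conductivity term,

$$\hat\varepsilon(\nu) = \frac{S_{2Ala}}{1 + 2\pi i \nu\,\tau_{2Ala}}
 + \frac{S_{H2O}}{1 + (2\pi i \nu\,\tau_{H2O})^{1-\alpha}}
 + \varepsilon_\infty + \frac{\kappa}{2\pi i \nu\,\varepsilon_0}.$$

The sign convention is $\hat\varepsilon = \varepsilon' - i\varepsilon''$
with positive loss; the conductivity is treated as real and
frequency-independent and contributes to $\varepsilon''$ only. Units are
GHz for frequency, ps for relaxation times, S/m for $\kappa$, mol/L for
concentrations (converted to m$^{-3}$ internally).

### Fitting

`fit_spectrum()` minimizes the concatenated real and imaginary residuals
with bounded Levenberg–Marquardt (`minpack.lm`). Equal weighting is the
default; `weighting = "modulus"` divides residuals by
$|\hat\varepsilon|$ and is the right objective when the noise is
multiplicative (constant relative error), which is how the synthetic
generator draws its noise — the pipeline therefore uses modulus weighting
for conductivity-dominated salt series, where the low-frequency loss would
otherwise dominate the cost function.

Starting values come from the data: a provisional $\kappa$ from the two
lowest frequencies (where the $1/\nu$ term dominates), mode times from the
two largest local maxima of the smoothed, conductivity-corrected loss, and
amplitudes from the corresponding dispersion steps of $\varepsilon'$. A
second deterministic start encodes the canonical aqueous-peptide mode
structure ($\tau \approx 160$ and $8.3$ ps), and the remaining restarts
(default 5 in total, seeded) jitter both; the best optimum by residual
wins. Bounds: $\alpha \in [0, 0.5]$, $\varepsilon_\infty \in [1, 10]$,
$\tau \in [0.1, 1000]$ ps, amplitudes and $\kappa$ non-negative. Mode
labels are assigned after the fit so that the peptide mode is the slower
one. A non-converged fit is returned with `converged = FALSE`, never
silently. $\kappa$ can instead be fixed at a measured DC value
(`fix_kappa`) — both paths are provided because either is defensible
experimentally.

### Dipole moments

`effective_dipole()` uses the spherical-cavity Cavell form
$\mu_{eff} = \sqrt{3 k_B T \varepsilon_0 (2\varepsilon_s+1) S /
(\varepsilon_s N_A c)}$ with CODATA 2018 constants and $T = 298.15$ K by
default. The cavity-field factor is isolated in `cavity_field_factor()` so
an ellipsoidal shape factor can be substituted without touching the rest
of the conversion; the spherical form reproduces the expected
$\mu_{eff} \approx 30$ D from the default amplitude-per-concentration
ratio of 27.6 L/mol. `dipole_concentration_check()` reports the relative
spread of $\mu_{eff}(c)$; below 10% (configurable) the series is
classified as free of dipole–dipole correlations, which is the assumption
the salt analysis rests on.

## NMR shift analysis

Shifts are referenced by a rigid offset to an external standard (2.5 ppm
nominal). The five-proton labelling is positional: two methyl peaks in
0.8–1.6 ppm (H-2 upfield, H-1 downfield), two $\alpha$-CH peaks in
3.5–4.2 ppm (H-3 upfield, H-4 downfield), one amide peak above 6 ppm
(H-5). `peak_detect_assign()` finds local maxima, filters them by
topographic prominence against a noise floor estimated from the
differenced spectrum, and refines positions by parabolic interpolation
through the three samples around each maximum; peaks are modelled as
Lorentzian singlets (J-coupling multiplets are out of scope).

The differential statistic $\Delta\delta = \delta_{rel}(H\!-\!5) -
\delta_{rel}(H\!-\!1)$ cancels medium effects and referencing errors
exactly (any rigid per-spectrum offset drops out). Its slope versus salt
concentration is fitted by unweighted OLS — the underlying study does not
state a weighting, and with a constant reproducibility floor of
$\pm 0.005$ ppm weighted and unweighted fits coincide anyway. The slope
standard error is floored at the value implied by that reproducibility
($\sigma_{\Delta\delta} = 2 \times 0.005$ ppm per point). Classification
uses a $2\sigma$ rule: slope significantly negative → anion–amide
shielding; significantly positive → de-shielding (the
guanidinium-like signature); otherwise medium-effect only. The linear
analysis presumes weak binding; the generator's saturating variant
($\Delta\delta_{max} K c/(1+Kc)$) exists to verify that a binding
isotherm with $K c_{max} \gtrsim 1$ produces a detectable $r^2$ drop, i.e.
that the linear regime is actually diagnosable from the data.

## 2D-IR simulation and analysis

### Lineshape model

Each band carries a Kubo FFCF $C(t) = \sum_i \Delta_i^2 e^{-t/\tau_i}$
(amplitudes in cm$^{-1}$, converted to rad/ps internally) with lineshape
function
$g(t) = \sum_i \Delta_i^2\tau_i^2 (e^{-t/\tau_i} + t/\tau_i - 1) + t/T_2$.
Components with $\Delta_i\tau_i < 0.2$ (angular units) are treated as
motionally narrowed: they contribute a homogeneous Lorentzian width
$2\Delta_i^2\tau_i$ but no pump–probe correlation, and they are exempt
from the grid-resolution check in `kubo_lineshape()` because their $g(t)$
reduces to an analytic pure-dephasing line.

### Response-function engine

`simulate_2dir()` builds purely absorptive spectra as the sum of rephasing
and non-rephasing third-order responses in the impulsive (delta-pulse)
limit, evaluated on a 128-point coherence-time grid (step 0.075 ps,
zero-padded 4× for ~0.9 cm$^{-1}$ frequency pixels) and double-FFTed.
Ground-state bleach / stimulated emission appear negative on the diagonal;
excited-state absorption appears positive, red-shifted by the
anharmonicity (default 20 cm$^{-1}$, a typical amide I value) on the probe
axis. Population relaxation enters as $e^{-T_2/T_1}$; lifetime broadening
during the coherence times is deliberately omitted so that the variance
split of the FFCF maps cleanly onto the instantaneous CLS (see below).
Bands are uncoupled at the response-function level; energy transfer is
modelled as a separate kinetic channel that adds Gaussian cross-peak lobe
pairs whose amplitude follows
$f(T) = \frac{k_r}{k_r-k_d}(e^{-k_d T} - e^{-k_r T})$, maximal at
$t_{max} = \ln(k_r/k_d)/(k_r-k_d)$.

A second, closed-form spectrum constructor (`gaussian_2dir()`: bivariate
Gaussian bleach plus shifted ESA) exists deliberately: for equal marginal
widths the CLS of that construction equals its correlation coefficient
exactly, which makes it the independent oracle for the response-function
engine.

### Center line slope

`extract_cls()` takes pump slices whose bleach depth reaches 60% of the
deepest slice (a conventional choice; configurable), finds each slice's
bleach extremum by parabolic interpolation, and reports the OLS slope of
extremum position versus pump frequency. Only the bleach lobe is used; the
probe window is cut at center − anharmonicity/2 to exclude the ESA. The
identity the analysis relies on — CLS(T₂) ≈ inhomogeneous FFCF normalized
by the *total* frequency variance, implemented in `cls_theory()` — holds
for Gaussian dynamics whose fast components are motionally narrowed, and
the simulations reproduce it within 0.05. The extremum-based estimator
carries a small systematic slow bias (order 5–10% on the decay time) from
residual ESA overlap within the probe window; it is resolution-independent
and documented rather than hidden, and both the fitted CLS₀ and the
measured CLS(T₂=0) are reported since the two differ in general.

### Kinetics

Bleach volumes are signed sums over a window enclosing the lobe (absolute
value, times pixel area); with a generously enclosing window the volume
decay tracks $e^{-T_2/T_1}$ to better than 1%, and `fit_ver()` recovers
the lifetime by a single-exponential fit. Cross peaks are declared
detected only when the windowed volume *rises* above its $T_2 = 0$ value —
diagonal-lobe tails only decay, so a rise is the unambiguous transfer
signature — and the two-rate fit then yields $t_{max}$.

## The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, under seeded, bit-reproducible randomness, and records every true
parameter in a ground-truth manifest so recovery tests never compare
against hard-coded numbers.

* **Dielectric.** Binary series: $S_{2Ala} = 27.6\,c$ L/mol,
  $\tau_{2Ala} \approx 160$ ps; water mode $S \approx 73$,
  $\tau \approx 8.3$ ps, $\alpha \approx 0.02$,
  $\varepsilon_\infty \approx 3.5$ — chosen to reproduce the ~20 GHz water
  loss peak and a static permittivity near 78 at low peptide content.
  Ternary series apply a linear peptide-amplitude reduction (per-salt
  defaults 25% for GdmCl/LiCl, 20% for KSCN, 10% for KCl/KI at 1.05 M),
  a linear slowdown of $\tau_{2Ala}$, water dilution, and a conductivity
  from an editable molar-conductivity table with a square-root
  concentration correction. Noise is multiplicative Gaussian (0.5%
  default), independent per channel; spectra are exact model evaluations
  (hence Kramers–Kronig-consistent) before noise.
* **NMR.** Baseline shifts 1.29/1.10/3.82/3.88/8.04 ppm; each proton
  shifts linearly with a common medium slope plus a per-proton excess
  (amide-only by default: −0.03 ppm·L/mol KI-like, −0.025 KSCN, +0.02
  GdmCl-like, 0 for KCl/LiCl); additive noise at the ±0.005 ppm
  reproducibility floor. The non-monotone low-concentration behaviour of
  guanidinium is not modelled — only the linear-fit sign.
* **2D-IR.** Amide I: 50/50 variance split between a motionally narrowed
  fast component and a slow 1.1 ps component ($\Delta = 8$ cm$^{-1}$
  each), $T_1 = 0.7$ ps, giving an instantaneous CLS ≈ 0.5. Carboxylate:
  $T_1 = 0.4$ ps with fast spectral diffusion (slow component 12 cm$^{-1}$,
  0.3 ps) under the no-salt condition, and a slowed, more inhomogeneous
  FFCF (8 cm$^{-1}$, 1.15 ps over a narrowed 8.5 cm$^{-1}$ part) under the
  LiCl condition. The carboxylate numbers are calibrated so the
  *extracted* observables emulate the experimental phenomenology
  (CLS₀ ≈ 0.2 → ≈ 0.5, i.e. a ~2.5× inhomogeneity contrast, decay
  0.3 → ~1.3 ps): for a 0.3 ps correlation time the slow component sits in
  the intermediate Kubo regime, so its microscopic amplitude is not
  observable directly and these values are emulation parameters, not
  measured ones — the manifest flags them as such in spirit by recording
  both the parameters and the variance-ratio prediction.

What the generator does **not** emulate: instrument transfer functions and
calibration, finite pulses, polarization effects, the D₂O background, the
guanidinium C–N band overlapping amide I, J-coupling multiplets, and
activity corrections. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the analysis chain, not
robustness to every instrumental artefact of real data.

## Pipeline, problem sizes, determinism

`run_full_analysis()` chains all three modalities from one seeded
configuration. Dielectric salt series are analysed as 8 replicate
datasets per salt (mirroring the 8 independent measurements an
experimentalist would average); per-concentration amplitudes are replicate
means with scatter-derived uncertainties. The 2D-IR waiting-time grid
(0–2.5 ps, denser below 1 ps) resolves both the 1.1 ps amide and ~0.3 ps
carboxylate spectral diffusion, and CLS points are used only while a
band's bleach stays above ~8× the robust noise floor — the fast-relaxing
carboxylate is simply gone at late waiting times, as it would be in the
lab. Default problem sizes (101-point frequency grids, 128-point coherence
grids, 100-seed Monte-Carlo recovery checks, 200-replicate bias checks)
run the full suite in well under a minute on one core while keeping
Monte-Carlo standard errors a few times smaller than the tolerances they
guard. All randomness flows through explicit integer seeds; generator
calls restore the caller's RNG state, so identical configurations produce
byte-identical outputs.

## Known limitations

* The Cavell conversion implements the spherical cavity only; for
  strongly non-spherical solutes the shape factor must be supplied.
* The CLS estimator's small slow bias (above) means decay times carry a
  systematic uncertainty of order 5–10% in addition to the statistical
  one.
* Uncertainties from the dielectric fits are asymptotic
  (Jacobian-based); for strongly correlated parameters (e.g. $S_{H2O}$
  vs $\varepsilon_\infty$ at high conductivity) replicate scatter is the
  more trustworthy error estimate, which is why the pipeline uses it.
* The energy-transfer channel is phenomenological (added lobes), not a
  coupled-exciton response-function calculation; cross-peak *shapes*
  should not be over-interpreted.
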