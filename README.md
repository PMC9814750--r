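# ionspec

Multimodal spectroscopic analysis of ion binding to a small zwitterionic
dipeptide (alanyl–alanine-like: COO⁻ and NH₃⁺ termini flanking a single
amide bond). Hofmeister salts perturb such a peptide in ways that no single
experiment resolves; `ionspec` implements the three complementary analyses
that together locate the ions:

* **Dielectric relaxation (DRS).** Complex permittivity spectra
  ε̂(ν) = ε′(ν) − iε″(ν) over 0.25–125 GHz are fitted with a Debye mode for
  the peptide plus a Cole–Cole mode for water,

  ε̂(ν) = S₂ₐₗₐ / (1 + 2πiν τ₂ₐₗₐ) + S_H₂O / (1 + (2πiν τ_H₂O)^(1−α)) + ε_∞ + κ/(2πiν ε₀).

  The peptide amplitude S₂ₐₗₐ converts to an effective dipole moment via
  the Cavell relation, µ_eff = √(3k_B T ε₀ (2ε_s+1) S / (ε_s N_A c)), and
  the salt-induced amplitude reduction R(c) = 1 − S(c)/S(c_ref) quantifies
  kinetic depolarization — larger when ions sit closer to the dipole.

* **¹H-NMR shift titrations.** Concentration-relative shifts
  δ_rel(c) = δ(c) − δ(c_ref) and the differential statistic
  Δδ = δ_rel(H‑5) − δ_rel(H‑1) (amide N–H minus a methyl reporter) cancel
  medium and referencing effects; the sign and slope of Δδ(c) classify
  site-specific binding at the amide.

* **2D-IR spectroscopy.** Purely absorptive 2D spectra of the amide I
  (~1660 cm⁻¹) and anti-symmetric COO⁻ stretch (~1590 cm⁻¹) bands are
  simulated from Kubo frequency-fluctuation correlation functions
  (FFCF: C(t) = Σᵢ Δᵢ² e^(−t/τᵢ)) through third-order response functions,
  and analysed by center line slope (CLS(T₂) = CLS₀ e^(−kT₂), spectral
  diffusion), bleach peak-volume decays (vibrational lifetime τ_VER) and
  cross-peak rise–decay kinetics (energy transfer).

Because no raw spectra are distributed with the underlying study, a seeded
synthetic-data generator (`gen_dielectric_series()`, `gen_nmr_series()`,
`gen_2dir_dataset()`) emulates each experiment with a machine-readable
ground-truth manifest, so every analysis stage is validated end to end.

## Worked example

Fit a noiseless synthetic peptide concentration series and check that the
effective dipole moment is concentration-independent (the signature of
uncorrelated zwitterion rotation):

```r
library(ionspec)
conc <- seq(0.05, 0.25, by = 0.05)                       # mol/L
g    <- gen_dielectric_series(c_2ala = conc, noise = 0, seed = 1)
fits <- lapply(g$spectra, fit_spectrum)
mu   <- effective_dipole(sapply(fits, function(f) f$S_2Ala), conc,
                         sapply(fits, static_permittivity))
mu
#>   conc_M mu_eff_D eps_static temperature_K
#> 1   0.05   30.109      78.08        298.15
#> 2   0.10   30.107      79.46        298.15
#> 3   0.15   30.106      80.84        298.15
#> 4   0.20   30.104      82.22        298.15
#> 5   0.25   30.103      83.60        298.15
```

µ_eff ≈ 30 D at every concentration (relative spread 0.02%): the peptide
rotates as an uncorrelated point dipole, so salt-induced amplitude changes
can be read as ion–peptide proximity rather than as peptide–peptide
correlations. `run_full_analysis(list(seed = 11))` chains all three
modalities into a cross-modality study report (salt ranking by
depolarization, Δδ slopes with classification, CLS/lifetime tables per
band and condition).

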