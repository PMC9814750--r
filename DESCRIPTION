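Package: ionspec
Title: Multimodal Spectroscopic Analysis of Ion Binding to a Zwitterionic Dipeptide
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ion-specific interactions with a small zwitterionic
    peptide from three spectroscopic modalities. Fits a Debye + Cole-Cole +
    conductivity relaxation model to complex permittivity spectra and converts
    peptide relaxation amplitudes to effective dipole moments (Cavell
    relation); computes concentration-relative and differential 1H chemical
    shifts with linear salt-slope analysis; simulates linear-IR and purely
    absorptive 2D-IR spectra from Kubo frequency-fluctuation correlation
    functions and extracts center line slopes, spectral-diffusion times,
    vibrational lifetimes and cross-peak kinetics. A seeded synthetic-data
    generator emulates the statistical structure of all three experiments so
    every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
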