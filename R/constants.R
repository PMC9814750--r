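# Physical constants (CODATA 2018) and unit conversions shared across modules.
.const <- list(
  kB    = 1.380649e-23,       # Boltzmann constant, J/K
  N_A   = 6.02214076e23,      # Avogadro constant, 1/mol
  eps0  = 8.8541878128e-12,   # vacuum permittivity, F/m
  c_cm_ps = 2.99792458e-2,    # speed of light, cm/ps
  debye = 3.33564e-30         # 1 Debye in C m
)

# angular frequency [rad/ps] <-> wavenumber [cm^-1]
wn_to_ang <- function(wn) 2 * pi * .const$c_cm_ps * wn
ang_to_wn <- function(w) w / (2 * pi * .const$c_cm_ps)

# log-spaced grid helper (frequencies, GHz)
logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
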