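# Built-in per-salt defaults for the generators. Reductions emulate the
# reported amplitude depolarization at the top of the 0.05-1.05 M series;
# molar conductivities (S cm^2/mol) are an editable table used only to give
# the spectra a realistic Ohmic loss; NMR slopes (ppm L/mol) give each salt
# a medium effect (all protons) plus an amide-specific excess.
.salt_defaults <- data.frame(
  salt = c("GdmCl", "LiCl", "KCl", "KI", "KSCN"),
  reduction = c(0.25, 0.25, 0.10, 0.10, 0.20),
  molar_cond = c(120, 115, 150, 150, 140),
  medium_slope = c(-0.030, -0.025, -0.030, -0.040, -0.035),
  h5_excess = c(0.020, 0.000, 0.000, -0.030, -0.025),
  stringsAsFactors = FALSE
)

#' Per-salt generator defaults
#' @return data.frame of the built-in salt parameter table.
#' @export
salt_defaults <- function() .salt_defaults

.salt_row <- function(salt) {
  r <- .salt_defaults[.salt_defaults$salt == salt, ]
  if (nrow(r) == 0)
    r <- data.frame(salt = salt, reduction = 0.15, molar_cond = 130,
                    medium_slope = -0.03, h5_excess = 0)
  r
}

#' Generate a synthetic dielectric spectrum series
#'
#' Emulates a microwave permittivity experiment on aqueous peptide
#' solutions: a binary series (peptide amplitude proportional to
#' concentration, `S/c = 27.6` L/mol by default, peptide mode near 1 GHz,
#' water mode near 20 GHz) or a ternary salt series in which the peptide
#' amplitude is reduced linearly with salt concentration, the peptide mode
#' slows down, the water amplitude is diluted, and the conductivity follows
#' a molar-conductivity table. Spectra are exact model evaluations
#' (Kramers-Kronig consistent) before multiplicative Gaussian noise is
#' applied.
#'
#' @param c_2ala peptide concentrations, mol/L: a vector for a binary
#'   series, a scalar for a ternary (salt) series.
#' @param salt,c_salt salt identity and strictly increasing concentrations
#'   (mol/L) for a ternary series; `NULL` for a binary series.
#' @param S_per_c peptide amplitude per concentration, L/mol.
#' @param tau_2ala_ps peptide relaxation time at zero salt.
#' @param water water-mode parameters
#'   (`list(S, tau_ps, alpha, eps_inf)`).
#' @param reduction_at_cmax fractional peptide-amplitude reduction at the
#'   highest salt concentration (default from the salt table; must be < 1).
#' @param tau_slope_ps_per_M slowdown of the peptide mode with salt.
#' @param water_dilution_per_M fractional water-amplitude loss per mol/L of
#'   salt.
#' @param molar_cond molar conductivity, S cm^2/mol (default from table).
#' @param freq frequency grid, GHz (default 101 log-spaced points over
#'   0.25-125).
#' @param noise multiplicative Gaussian noise s.d. (relative; default
#'   0.005); 0 for noiseless spectra.
#' @param seed integer seed (mandatory).
#' @return list with `spectra` (list of [dielectric_spectrum()]) and `truth`
#'   (ground-truth manifest: per-sample true parameters plus the config
#'   echo and seed).
#' @export
gen_dielectric_series <- function(c_2ala = 0.25, salt = NULL, c_salt = NULL,
                                  S_per_c = 27.6, tau_2ala_ps = 160,
                                  water = list(S = 73.2, tau_ps = 8.3,
                                               alpha = 0.02, eps_inf = 3.5),
                                  reduction_at_cmax = NULL,
                                  tau_slope_ps_per_M = 20,
                                  water_dilution_per_M = 0.10,
                                  molar_cond = NULL,
                                  freq = logspace(0.25, 125, 101),
                                  noise = 0.005, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (min(freq) < 0.2 || max(freq) > 130)
    stop("frequency grid must lie within ~0.25-125 GHz")
  ternary <- !is.null(salt)
  if (ternary) {
    if (length(c_2ala) != 1) stop("ternary series uses a single peptide concentration")
    if (any(diff(c_salt) <= 0)) stop("c_salt must be strictly increasing")
    row <- .salt_row(salt)
    if (is.null(reduction_at_cmax)) reduction_at_cmax <- row$reduction
    if (reduction_at_cmax >= 1) stop("amplitude reduction must be < 100%")
    if (is.null(molar_cond)) molar_cond <- row$molar_cond
    cs <- c_salt
    frac <- (cs - cs[1]) / (max(cs) - cs[1])
    S2 <- S_per_c * c_2ala * (1 - reduction_at_cmax * frac)
    tau2 <- tau_2ala_ps + tau_slope_ps_per_M * (cs - cs[1])
    Sw <- water$S * pmax(0.2, 1 - water_dilution_per_M * cs)
    kappa <- 0.1 * molar_cond * cs * (1 - 0.25 * sqrt(cs))
    labels <- sprintf("%s_%0.2fM", salt, cs)
  } else {
    cs <- rep(0, length(c_2ala))
    S2 <- S_per_c * c_2ala
    tau2 <- rep(tau_2ala_ps, length(c_2ala))
    Sw <- rep(water$S, length(c_2ala))
    kappa <- rep(0, length(c_2ala))
    labels <- sprintf("2Ala_%0.2fM", c_2ala)
  }
  n <- length(labels)
  rng <- .seeded_rng(seed)
  spectra <- vector("list", n)
  truth_fits <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- relaxation_fit(S_2Ala = S2[i], tau_2Ala = tau2[i], S_H2O = Sw[i],
                          tau_H2O = water$tau_ps, alpha = water$alpha,
                          eps_inf = water$eps_inf, kappa = kappa[i])
    m <- eval_permittivity(fit, freq)
    er <- m$eps_real; ei <- m$eps_imag
    if (noise > 0) {
      er <- er * (1 + stats::rnorm(length(freq), 0, noise))
      ei <- ei * (1 + stats::rnorm(length(freq), 0, noise))
    }
    meta <- list(peptide_conc_M = if (ternary) c_2ala else c_2ala[i],
                 salt = if (ternary) salt else NA_character_,
                 salt_conc_M = cs[i], temperature_K = 298.15,
                 label = labels[i])
    spectra[[i]] <- dielectric_spectrum(freq, er, ei, meta)
    truth_fits[[i]] <- unclass(fit)[c("S_2Ala", "tau_2Ala", "S_H2O",
                                      "tau_H2O", "alpha", "eps_inf", "kappa")]
  }
  rng$restore()
  list(spectra = spectra,
       truth = list(modality = "drs", seed = seed, labels = labels,
                    c_2ala = if (ternary) rep(c_2ala, n) else c_2ala,
                    salt = if (ternary) salt else NA_character_,
                    c_salt = cs, S_per_c = S_per_c,
                    reduction_at_cmax = if (ternary) reduction_at_cmax else 0,
                    noise = noise, fits = truth_fits))
}

# printed five-proton assignment of the dipeptide (ppm)
.base_shifts <- c("H-1" = 1.29, "H-2" = 1.10, "H-3" = 3.82, "H-4" = 3.88,
                  "H-5" = 8.04)

#' Generate a synthetic NMR shift titration
#'
#' Linear weak-binding regime: every proton shifts with the medium,
#' \eqn{\delta_j(c) = \delta_j(0) + m\,c + b_j c}, with a site-specific
#' excess slope \eqn{b_j} only for configured protons (the amide H-5 by
#' default). A saturating 1:1-isotherm variant
#' \eqn{\delta_j(0) + \Delta\delta_{max} K c/(1+Kc)} is available to emulate
#' strong binding. Additive Gaussian noise at the reproducibility floor.
#'
#' @param salt salt identifier (sets default medium and excess slopes from
#'   the built-in table; `"none"` gives a peptide-only titration with zero
#'   slopes).
#' @param conc strictly increasing titrant concentrations, mol/L.
#' @param base named baseline shifts, ppm.
#' @param medium_slope common medium-effect slope, ppm L/mol.
#' @param excess named vector of site-specific excess slopes, ppm L/mol.
#' @param saturating optional `list(K =, dmax =)` replacing the excess term
#'   by a binding isotherm for the protons named in `excess`.
#' @param noise additive noise s.d., ppm (default 0.005).
#' @param seed integer seed (mandatory).
#' @param full_spectra if `TRUE`, also return synthetic Lorentzian spectra
#'   (0-10 ppm, 0.001 ppm sampling) per concentration.
#' @param linewidth_ppm Lorentzian half width at half maximum for the full
#'   spectra.
#' @return list with `series` (a [shift_series()]), `truth` manifest, and
#'   optionally `spectra`.
#' @export
gen_nmr_series <- function(salt = "KI", conc = seq(0.05, 1.05, by = 0.25),
                           base = .base_shifts, medium_slope = NULL,
                           excess = NULL, saturating = NULL, noise = 0.005,
                           seed, full_spectra = FALSE, linewidth_ppm = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(medium_slope))
    medium_slope <- if (salt == "none") 0 else .salt_row(salt)$medium_slope
  if (is.null(excess))
    excess <- if (salt == "none") c("H-5" = 0)
  else c("H-5" = .salt_row(salt)$h5_excess)
  rng <- .seeded_rng(seed)
  dc <- conc - conc[1]
  shifts <- matrix(NA_real_, length(conc), length(base),
                   dimnames = list(NULL, names(base)))
  for (j in names(base)) {
    b <- if (j %in% names(excess)) excess[[j]] else 0
    site <- if (!is.null(saturating) && j %in% names(excess) && b != 0)
      saturating$dmax * sign(b) * saturating$K * dc / (1 + saturating$K * dc)
    else b * dc
    shifts[, j] <- base[[j]] + medium_slope * dc + site +
      stats::rnorm(length(conc), 0, noise)
  }
  spectra <- NULL
  if (full_spectra) {
    ppm <- seq(0, 10, by = 0.001)
    spectra <- lapply(seq_along(conc), function(i) {
      y <- rep(0, length(ppm))
      for (j in seq_len(ncol(shifts)))
        y <- y + 1 / (1 + ((ppm - shifts[i, j]) / linewidth_ppm)^2)
      data.frame(ppm = ppm, intensity = y)
    })
  }
  rng$restore()
  list(series = shift_series(conc, shifts, ref_conc = conc[1],
                             uncertainty = max(noise, 1e-12), salt = salt),
       truth = list(modality = "nmr", seed = seed, salt = salt,
                    base = as.list(base), medium_slope = medium_slope,
                    excess = as.list(excess), saturating = saturating,
                    noise = noise),
       spectra = spectra)
}

# default FFCF band plans per condition: amide I inhomogeneity and
# spectral diffusion are salt-insensitive; LiCl slows the carboxylate FFCF
# and raises its inhomogeneous fraction ~2.5x.
.ir2d_bands <- function(condition) {
  amide <- ffcf_model(1660, data.frame(Delta_cm = c(8, 8),
                                       tau_ps = c(0.05, 1.1)),
                      T1 = 0.7, anharmonicity = 20)
  coo <- if (condition == "LiCl")
    ffcf_model(1590, data.frame(Delta_cm = c(8.5, 8),
                                tau_ps = c(0.04, 1.15)),
               T1 = 0.4, anharmonicity = 18, transition_strength = 0.9)
  else
    ffcf_model(1590, data.frame(Delta_cm = c(8, 12),
                                tau_ps = c(0.04, 0.3)),
               T1 = 0.4, anharmonicity = 18, transition_strength = 0.9)
  list(amideI = amide, coo = coo)
}

#' Generate a synthetic 2D-IR waiting-time series
#'
#' Simulates purely absorptive 2D-IR spectra of the amide I (~1660 cm^-1)
#' and anti-symmetric carboxylate (~1590 cm^-1) bands over a waiting-time
#' series, from per-band FFCF models whose defaults emulate the
#' experimental phenomenology: slow amide spectral diffusion (~1.1 ps,
#' instantaneous CLS ~0.5, T1 ~0.7 ps), fast carboxylate spectral diffusion
#' (~0.3 ps, T1 ~0.4 ps), and under the `"LiCl"` condition a slowed
#' carboxylate FFCF with ~2.5x the inhomogeneous fraction. A weak
#' energy-transfer coupling produces cross peaks maximal near 200 fs.
#' Additive detector noise.
#'
#' @param condition `"none"` or `"LiCl"` (selects the band plan), or pass
#'   `bands` explicitly.
#' @param bands optional list of [ffcf_model()] overriding the plan.
#' @param T2_fs waiting times, fs.
#' @param coupling energy-transfer channel passed to [simulate_2dir()];
#'   `NULL` disables cross peaks.
#' @param noise additive detector noise s.d. relative to the maximum signal
#'   amplitude (default 0.002).
#' @param seed integer seed (mandatory).
#' @param dt,nt simulation grid, see [simulate_2dir()].
#' @return list with `spectra` (one [twodir_spectrum()] per waiting time),
#'   `linear_ir` (band-summed linear spectrum from the same lineshape
#'   functions), and `truth` manifest echoing every FFCF parameter.
#' @export
gen_2dir_dataset <- function(condition = c("none", "LiCl"), bands = NULL,
                             T2_fs = c(0, 250, 500, 1000, 1500, 2500),
                             coupling = list(amplitude = 0.02,
                                             k_rise_per_ps = 10,
                                             k_decay_per_ps = 2.5),
                             noise = 0.002, seed, dt = 0.075, nt = 128L) {
  if (missing(seed)) stop("seed is mandatory")
  condition <- match.arg(condition)
  if (is.null(bands)) bands <- .ir2d_bands(condition)
  rng <- .seeded_rng(seed)
  spectra <- lapply(T2_fs, function(Tw) {
    s <- simulate_2dir(bands, Tw, coupling = coupling, dt = dt, nt = nt)
    if (noise > 0)
      s$signal <- s$signal + stats::rnorm(length(s$signal), 0,
                                          noise * max(abs(s$signal)))
    s$meta$condition <- condition
    s
  })
  rng$restore()
  li <- NULL
  for (b in bands) {
    sp <- linear_ir_spectrum(b, dt = 0.02, nt = 2048)
    sp$absorbance <- sp$absorbance * b$transition_strength^2
    li <- if (is.null(li)) sp else {
      merged <- li
      merged$absorbance <- merged$absorbance +
        stats::approx(sp$wavenumber_cm, sp$absorbance,
                      xout = merged$wavenumber_cm, rule = 2)$y
      merged
    }
  }
  truth <- list(modality = "ir2d", seed = seed, condition = condition,
                T2_fs = T2_fs, noise = noise, coupling = coupling,
                bands = lapply(bands, function(b) {
                  list(center = b$center,
                       Delta_cm = b$components$Delta_cm,
                       tau_ps = b$components$tau_ps, T1 = b$T1,
                       anharmonicity = b$anharmonicity,
                       cls0_theory = cls_theory(b, 0))
                }))
  list(spectra = spectra, linear_ir = li, truth = truth)
}
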