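#' Effective dipole moment from a relaxation amplitude (Cavell relation)
#'
#' Converts a dipolar relaxation amplitude \eqn{S} at solute concentration
#' \eqn{c} into an effective dipole moment using the spherical-cavity Cavell
#' form
#' \deqn{\mu_{eff} = \sqrt{\frac{3 k_B T \varepsilon_0 (2\varepsilon_s + 1)\,S}
#'   {\varepsilon_s N_A c}},}
#' reported in Debye. The cavity-field factor is isolated in
#' [cavity_field_factor()] so a non-spherical shape factor can be substituted.
#'
#' @param S relaxation amplitude (dimensionless, >= 0).
#' @param conc solute concentration, mol/L (> 0).
#' @param eps_static static permittivity of the solution (> 1); for a fitted
#'   spectrum use [static_permittivity()].
#' @param temperature K.
#' @param cavity_factor function of `eps_static` returning the cavity-field
#'   factor; defaults to the spherical form \eqn{(2\varepsilon_s+1)/\varepsilon_s}.
#' @return data.frame with columns `conc_M`, `mu_eff_D`, `eps_static`,
#'   `temperature_K` (vectorised over `S`/`conc`/`eps_static`).
#' @export
effective_dipole <- function(S, conc, eps_static, temperature = 298.15,
                             cavity_factor = cavity_field_factor) {
  if (any(conc <= 0)) stop("concentration must be > 0")
  if (any(S < 0)) stop("relaxation amplitude must be >= 0")
  if (any(eps_static <= 1)) stop("eps_static must exceed 1")
  n_m3 <- conc * 1e3 * .const$N_A
  mu2 <- 3 * .const$kB * temperature * .const$eps0 *
    cavity_factor(eps_static) * S / n_m3
  data.frame(conc_M = conc, mu_eff_D = sqrt(mu2) / .const$debye,
             eps_static = eps_static, temperature_K = temperature)
}

#' Spherical cavity-field factor
#' @param eps_static static permittivity (> 1).
#' @return \eqn{(2\varepsilon_s + 1)/\varepsilon_s}.
#' @export
cavity_field_factor <- function(eps_static) (2 * eps_static + 1) / eps_static

#' Dipole-moment flatness across a concentration series
#'
#' For uncorrelated dipolar rotation the effective dipole moment is
#' concentration-independent; a rising or falling trend flags dipole-dipole
#' correlations (or conformational change). Computes mu_eff per concentration
#' and the relative spread `(max - min)/mean`.
#'
#' @param S amplitudes per concentration.
#' @param conc concentrations, mol/L (>= 3 values).
#' @param eps_static static permittivities per concentration (recycled).
#' @param temperature K.
#' @param threshold relative spread below which the series is reported as
#'   showing no dipole correlations (default 0.10).
#' @return list with `table` (per-concentration dipoles), `spread`,
#'   `correlated` (logical flag) and a human-readable `message`.
#' @export
dipole_concentration_check <- function(S, conc, eps_static,
                                       temperature = 298.15,
                                       threshold = 0.10) {
  if (length(conc) < 3L) stop("need at least 3 concentrations")
  tab <- effective_dipole(S, conc, eps_static, temperature)
  spread <- (max(tab$mu_eff_D) - min(tab$mu_eff_D)) / mean(tab$mu_eff_D)
  flagged <- spread >= threshold
  list(table = tab, spread = spread, correlated = flagged,
       message = if (flagged)
         sprintf("mu_eff varies by %.1f%% across the series: dipole-dipole correlations or conformational change suspected", 100 * spread)
       else "no dipole-dipole correlation detected")
}

#' Salt-induced depolarization of the peptide relaxation amplitude
#'
#' Relative reduction \eqn{R(c) = 1 - S_{2Ala}(c)/S_{2Ala}(c_{ref})} in
#' percent across a salt concentration series, with first-order uncertainty
#' propagation from the per-fit amplitude variances.
#'
#' @param c_salt strictly increasing salt concentrations, mol/L; the first
#'   element is the reference.
#' @param fits list of [relaxation_fit()] objects, one per concentration.
#' @param salt salt identifier carried into the output.
#' @return data.frame with `salt`, `c_salt_M`, `S_2Ala`, `reduction_pct`,
#'   `reduction_se_pct`.
#' @export
amplitude_depolarization <- function(c_salt, fits, salt = "salt") {
  if (length(c_salt) != length(fits)) stop("one fit per concentration required")
  if (any(diff(c_salt) <= 0)) stop("c_salt must be strictly increasing")
  conv <- vapply(fits, function(f) isTRUE(f$converged) || is.na(f$converged),
                 logical(1))
  if (!all(conv)) stop("all fits must have converged (reference fit included)")
  S <- vapply(fits, function(f) f$S_2Ala, numeric(1))
  vS <- vapply(fits, function(f) {
    if (!is.null(f$covariance) && "S_2Ala" %in% rownames(f$covariance))
      f$covariance["S_2Ala", "S_2Ala"] else NA_real_
  }, numeric(1))
  S0 <- S[1]
  R <- 100 * (1 - S / S0)
  seR <- 100 * sqrt(vS / S0^2 + (S / S0^2)^2 * vS[1])
  seR[1] <- 0
  data.frame(salt = salt, c_salt_M = c_salt, S_2Ala = S,
             reduction_pct = R, reduction_se_pct = seR)
}

#' Rank salts by depolarization at the highest common concentration
#'
#' @param tables list of outputs of [amplitude_depolarization()].
#' @return data.frame sorted by decreasing reduction at the highest
#'   concentration shared by all series.
#' @export
rank_depolarization <- function(tables) {
  cmax <- min(vapply(tables, function(t) max(t$c_salt_M), numeric(1)))
  rows <- lapply(tables, function(t) t[which.min(abs(t$c_salt_M - cmax)), ])
  out <- do.call(rbind, rows)
  out[order(-out$reduction_pct), ]
}
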