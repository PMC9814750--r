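#' Construct a dielectric spectrum
#'
#' Bundles a measured (or simulated) complex permittivity spectrum: a strictly
#' increasing microwave frequency grid with the real permittivity
#' \eqn{\varepsilon'} (in-phase polarization) and the dielectric loss
#' \eqn{\varepsilon''} (out-of-phase, absorptive polarization), using the
#' convention \eqn{\hat\varepsilon = \varepsilon' - i\varepsilon''} with
#' positive loss.
#'
#' @param freq frequencies in GHz, strictly increasing, length >= 8.
#' @param eps_real real permittivity per frequency (dimensionless, > 1 for
#'   aqueous samples).
#' @param eps_imag dielectric loss per frequency (dimensionless).
#' @param meta named list of sample descriptors; recognised entries are
#'   `peptide_conc_M`, `salt`, `salt_conc_M`, `temperature_K` (defaults to
#'   298.15 K when absent).
#' @return object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(freq, eps_real, eps_imag, meta = list()) {
  if (length(freq) < 8L)
    stop("a dielectric spectrum needs at least 8 frequency points")
  if (length(eps_real) != length(freq) || length(eps_imag) != length(freq))
    stop("freq, eps_real and eps_imag must have equal length")
  if (any(diff(freq) <= 0)) stop("freq must be strictly increasing")
  if (any(freq <= 0)) stop("frequencies must be positive")
  if (is.null(meta$temperature_K)) meta$temperature_K <- 298.15
  structure(list(freq = as.numeric(freq),
                 eps_real = as.numeric(eps_real),
                 eps_imag = as.numeric(eps_imag),
                 meta = meta),
            class = "dielectric_spectrum")
}

#' Construct a relaxation-model parameter set
#'
#' Parameters of the two-mode relaxation model used throughout: a Debye mode
#' for the peptide, a Cole-Cole mode for water, a high-frequency offset and an
#' Ohmic conductivity term,
#' \deqn{\hat\varepsilon(v) = \frac{S_{2Ala}}{1 + 2\pi i v \tau_{2Ala}}
#'  + \frac{S_{H2O}}{1 + (2\pi i v \tau_{H2O})^{1-\alpha}}
#'  + \varepsilon_\infty + \frac{\kappa}{2\pi i v \varepsilon_0}.}
#'
#' @param S_2Ala peptide relaxation amplitude (>= 0).
#' @param tau_2Ala peptide relaxation time, ps; must exceed `tau_H2O` (the
#'   peptide mode is the lower-frequency one by construction).
#' @param S_H2O water relaxation amplitude (>= 0).
#' @param tau_H2O water relaxation time, ps.
#' @param alpha Cole-Cole broadening exponent in `[0, 1)`; 0 recovers a Debye
#'   mode.
#' @param eps_inf high-frequency permittivity (>= 1).
#' @param kappa conductivity, S/m (>= 0).
#' @param residual,covariance,converged fit diagnostics, filled by
#'   [fit_spectrum()].
#' @return object of class `relaxation_fit`.
#' @export
relaxation_fit <- function(S_2Ala, tau_2Ala, S_H2O, tau_H2O, alpha = 0,
                           eps_inf = 1, kappa = 0, residual = NA_real_,
                           covariance = NULL, converged = NA) {
  if (S_2Ala < 0 || S_H2O < 0) stop("relaxation amplitudes must be >= 0")
  if (tau_2Ala <= 0 || tau_H2O <= 0) stop("relaxation times must be > 0")
  if (tau_2Ala <= tau_H2O)
    stop("tau_2Ala must exceed tau_H2O (peptide mode is the slower one)")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(S_2Ala = S_2Ala, tau_2Ala = tau_2Ala, S_H2O = S_H2O,
                 tau_H2O = tau_H2O, alpha = alpha, eps_inf = eps_inf,
                 kappa = kappa, residual = residual, covariance = covariance,
                 converged = converged),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat("Two-mode relaxation fit (Debye + Cole-Cole + conductivity)\n")
  cat(sprintf("  peptide: S = %.3f, tau = %.2f ps\n", x$S_2Ala, x$tau_2Ala))
  cat(sprintf("  water:   S = %.3f, tau = %.3f ps, alpha = %.4f\n",
              x$S_H2O, x$tau_H2O, x$alpha))
  cat(sprintf("  eps_inf = %.3f, kappa = %.4f S/m\n", x$eps_inf, x$kappa))
  if (is.finite(x$residual))
    cat(sprintf("  residual SS = %.4g, converged = %s\n", x$residual,
                x$converged))
  invisible(x)
}

#' Evaluate the relaxation model on a frequency grid
#'
#' @param fit a [relaxation_fit()] (or plain list with the same fields).
#' @param freq frequencies in GHz (> 0).
#' @return data.frame with columns `freq_GHz`, `eps_real`, `eps_imag`; the
#'   conductivity term contributes to the loss only.
#' @export
eval_permittivity <- function(fit, freq) {
  if (any(freq <= 0)) stop("frequencies must be positive")
  if (fit$alpha < 0 || fit$alpha >= 1) stop("alpha must lie in [0, 1)")
  # 2*pi*v*tau with v in GHz and tau in ps is dimensionless after *1e-3
  wt1 <- 2e-3 * pi * freq * fit$tau_2Ala
  wt2 <- 2e-3 * pi * freq * fit$tau_H2O
  e <- fit$S_2Ala / (1 + 1i * wt1) +
    fit$S_H2O / (1 + (1i * wt2)^(1 - fit$alpha)) +
    fit$eps_inf
  loss <- -Im(e) + fit$kappa / (2 * pi * freq * 1e9 * .const$eps0)
  data.frame(freq_GHz = freq, eps_real = Re(e), eps_imag = loss)
}

#' Loss-peak frequency of a Debye or Cole-Cole mode
#'
#' The dielectric loss of both mode types is maximal at \eqn{1/(2\pi\tau)}
#' (the Cole-Cole loss is symmetrically broadened about the same maximum).
#'
#' @param tau_ps relaxation time in ps (> 0).
#' @return peak frequency in GHz.
#' @export
loss_peak_frequency <- function(tau_ps) {
  if (any(tau_ps <= 0)) stop("tau must be > 0")
  1e3 / (2 * pi * tau_ps)
}

#' Static permittivity implied by a fit
#'
#' Zero-frequency limit of the relaxation model, `eps_inf + S_2Ala + S_H2O`.
#' @param fit a [relaxation_fit()].
#' @return static permittivity (dimensionless).
#' @export
static_permittivity <- function(fit) fit$eps_inf + fit$S_2Ala + fit$S_H2O
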