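# Heuristic starting values: provisional kappa from the two lowest
# frequencies (eps'' ~ a/f + b*f there), then tau's from the two largest
# local maxima of the smoothed, conductivity-corrected loss and amplitudes
# from the corresponding dispersion steps of eps'.
.init_from_spectrum <- function(spec) {
  f <- spec$freq; er <- spec$eps_real; ei <- spec$eps_imag
  A <- rbind(c(1 / f[1], f[1]), c(1 / f[2], f[2]))
  ab <- tryCatch(solve(A, ei[1:2]), error = function(e) c(0, 0))
  # eps''_cond = kappa / (2*pi*f_GHz*1e9*eps0), so a [eps''*GHz] -> kappa
  kappa0 <- max(0, ab[1] * 2 * pi * 1e9 * .const$eps0)
  ei_c <- pmax(0, ei - kappa0 / (2 * pi * f * 1e9 * .const$eps0))
  k <- min(5L, length(ei_c))
  sm <- stats::filter(ei_c, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- ei_c[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  ismax <- which(diff(sign(diff(sm))) < 0) + 1L
  ismax <- ismax[order(sm[ismax], decreasing = TRUE)]
  if (length(ismax) >= 2L) {
    pk <- sort(f[ismax[1:2]])
  } else if (length(ismax) == 1L) {
    pk <- c(f[ismax[1]] / 20, f[ismax[1]])   # assume missing slow mode
  } else {
    pk <- c(1, 20)
  }
  tau <- 1e3 / (2 * pi * pk)                  # tau[1] slow, tau[2] fast
  f_mid <- sqrt(pk[1] * pk[2])
  er_mid <- stats::approx(f, er, xout = f_mid, rule = 2)$y
  eps_inf0 <- max(1, min(er[n], 10))
  S1 <- max(0.1, er[1] - er_mid)
  S2 <- max(1, er_mid - eps_inf0)
  list(S_2Ala = S1, tau_2Ala = tau[1], S_H2O = S2, tau_H2O = tau[2],
       alpha = 0.02, eps_inf = eps_inf0, kappa = kappa0)
}

.eval_par <- function(p, freq, fix_kappa = NULL) {
  kap <- if (is.null(fix_kappa)) p[["kappa"]] else fix_kappa
  wt1 <- 2e-3 * pi * freq * p[["tau_2Ala"]]
  wt2 <- 2e-3 * pi * freq * p[["tau_H2O"]]
  e <- p[["S_2Ala"]] / (1 + 1i * wt1) +
    p[["S_H2O"]] / (1 + (1i * wt2)^(1 - p[["alpha"]])) + p[["eps_inf"]]
  list(re = Re(e), im = -Im(e) + kap / (2 * pi * freq * 1e9 * .const$eps0))
}

#' Fit the two-mode relaxation model to a complex permittivity spectrum
#'
#' Bounded Levenberg-Marquardt least squares, jointly on \eqn{\varepsilon'}
#' and \eqn{\varepsilon''} (equal weights by default). Starting values follow
#' a peak-picking heuristic on the conductivity-corrected loss; a seeded
#' multi-start (jittered initializations) guards against local minima. Mode
#' labels are assigned so that `tau_2Ala > tau_H2O`.
#'
#' @param spec a [dielectric_spectrum()].
#' @param init optional list of starting values (fields as in
#'   [relaxation_fit()]); by default derived from the data.
#' @param fix_kappa optionally fix the conductivity at a measured DC value
#'   (S/m) instead of fitting it.
#' @param restarts number of jittered restarts beyond the heuristic start.
#' @param weighting `"uniform"` (concatenated raw residuals) or `"modulus"`
#'   (residuals divided by \eqn{|\hat\varepsilon|}).
#' @param seed integer seed for the restart jitter.
#' @return a [relaxation_fit()] with residual sum of squares, a parameter
#'   standard-error summary in `$covariance`, and a `converged` flag (a
#'   non-converged fit is returned flagged, not silently).
#' @export
fit_spectrum <- function(spec, init = NULL, fix_kappa = NULL, restarts = 5,
                         weighting = c("uniform", "modulus"), seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(spec, "dielectric_spectrum"))
  f <- spec$freq
  if (min(f) > 1 || max(f) < 20)
    stop("spectrum must cover both dispersion regions (below 1 GHz and above 20 GHz)")
  free <- c("S_2Ala", "tau_2Ala", "S_H2O", "tau_H2O", "alpha", "eps_inf",
            if (is.null(fix_kappa)) "kappa")
  if (2L * length(f) < length(free))
    stop("fewer data points than free parameters")
  w <- if (weighting == "modulus") {
    1 / pmax(sqrt(spec$eps_real^2 + spec$eps_imag^2), 1e-6)
  } else rep(1, length(f))
  resid_fn <- function(p) {
    p <- as.list(p)
    m <- .eval_par(p, f, fix_kappa)
    c((m$re - spec$eps_real) * w, (m$im - spec$eps_imag) * w)
  }
  lower <- c(S_2Ala = 0, tau_2Ala = 0.1, S_H2O = 0, tau_H2O = 0.1,
             alpha = 0, eps_inf = 1, kappa = 0)
  upper <- c(S_2Ala = Inf, tau_2Ala = 1000, S_H2O = Inf, tau_H2O = 1000,
             alpha = 0.5, eps_inf = 10, kappa = Inf)
  p0 <- .init_from_spectrum(spec)
  if (!is.null(init)) p0[names(init)] <- init[names(init)]
  p0 <- unlist(p0[c("S_2Ala", "tau_2Ala", "S_H2O", "tau_H2O", "alpha",
                    "eps_inf", "kappa")])
  if (!is.null(fix_kappa)) p0 <- p0[setdiff(names(p0), "kappa")]
  # second deterministic start: canonical aqueous-peptide mode structure
  # (slow zwitterion near 1 GHz, water near 20 GHz), amplitudes from the
  # low-frequency dispersion step
  S_tot <- max(2, spec$eps_real[1] - 3.5)
  p_can <- c(S_2Ala = 0.08 * S_tot, tau_2Ala = 160, S_H2O = 0.92 * S_tot,
             tau_H2O = 8.3, alpha = 0.02, eps_inf = 3.5,
             kappa = unname(p0["kappa"]))
  if (!is.null(fix_kappa)) p_can <- p_can[setdiff(names(p_can), "kappa")]
  starts <- list(p0, p_can[names(p0)])
  if (restarts > 2) {
    rng <- .seeded_rng(seed)
    for (r in seq_len(restarts - 2)) {
      base <- if (r %% 2) p0 else starts[[2]]
      jit <- base * exp(stats::rnorm(length(p0), 0, 0.25))
      jit <- pmin(pmax(jit, lower[names(p0)] + 1e-8),
                  pmin(upper[names(p0)], 1e6))
      starts[[r + 2]] <- jit
    }
    rng$restore()
  }
  starts <- starts[seq_len(min(length(starts), max(1, restarts)))]
  best <- NULL
  for (s in starts) {
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower[names(s)],
                         upper = upper[names(s)], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fitres)) next
    if (is.null(best) || fitres$deviance < best$deviance) best <- fitres
  }
  if (is.null(best)) stop("relaxation fit failed for every start")
  p <- as.list(stats::coef(best))
  p$kappa <- if (is.null(fix_kappa)) p$kappa else fix_kappa
  # label modes: the peptide mode is the slower of the two
  if (p$tau_2Ala < p$tau_H2O) {
    p[c("S_2Ala", "S_H2O")] <- p[c("S_H2O", "S_2Ala")]
    p[c("tau_2Ala", "tau_H2O")] <- p[c("tau_H2O", "tau_2Ala")]
  }
  dof <- max(1L, 2L * length(f) - length(stats::coef(best)))
  sig2 <- best$deviance / dof
  covm <- tryCatch({
    v <- sig2 * solve(best$hessian / 2)
    dimnames(v) <- list(names(stats::coef(best)), names(stats::coef(best)))
    v
  }, error = function(e) NULL)
  converged <- best$info %in% 1:4
  relaxation_fit(S_2Ala = p$S_2Ala, tau_2Ala = max(p$tau_2Ala, p$tau_H2O * (1 + 1e-9)),
                 S_H2O = p$S_H2O, tau_H2O = p$tau_H2O, alpha = p$alpha,
                 eps_inf = p$eps_inf, kappa = p$kappa,
                 residual = best$deviance, covariance = covm,
                 converged = converged)
}

# run code under a temporary RNG state
.seeded_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
}
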