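#' 2D-IR spectrum container
#'
#' @param pump,probe strictly increasing frequency axes, cm^-1.
#' @param signal real matrix `length(pump) x length(probe)`; the sign
#'   convention is bleach/stimulated emission negative, excited-state
#'   absorption positive.
#' @param T2_fs waiting time, fs.
#' @param meta list of band descriptors / condition labels.
#' @return object of class `twodir_spectrum`.
#' @export
twodir_spectrum <- function(pump, probe, signal, T2_fs, meta = list()) {
  signal <- as.matrix(signal)
  if (any(diff(pump) <= 0) || any(diff(probe) <= 0))
    stop("axes must be strictly increasing")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (nrow(signal) != length(pump) || ncol(signal) != length(probe))
    stop("signal must be length(pump) x length(probe)")
  structure(list(pump = pump, probe = probe, signal = signal,
                 T2_fs = T2_fs, meta = meta),
            class = "twodir_spectrum")
}

#' Simulate a purely absorptive 2D-IR spectrum from FFCF models
#'
#' Sums rephasing and non-rephasing third-order response functions built
#' from the Kubo lineshape function of each band (impulsive pulses,
#' delta-function pump/probe), double-FFTs over both coherence times, and
#' returns the real absorptive spectrum. Each band contributes a negative
#' ground-state-bleach/stimulated-emission doublet partner on the diagonal
#' and a positive excited-state absorption red-shifted by the anharmonicity
#' on the probe axis; signals decay with waiting time as
#' \eqn{e^{-T_2/T_1}}. Bands are treated as uncoupled; energy-transfer cross
#' peaks can be added as a separate kinetic channel via `coupling`.
#'
#' @param bands an [ffcf_model()] or list of them.
#' @param T2_fs waiting time, fs.
#' @param coupling optional
#'   `list(amplitude =, k_rise_per_ps =, k_decay_per_ps =)`: adds, for every
#'   ordered band pair, a Gaussian cross-peak lobe pair at
#'   (pump = donor, probe = acceptor) whose amplitude follows the two-rate
#'   rise-decay law
#'   \eqn{f(T) = \frac{k_r}{k_r - k_d}(e^{-k_d T} - e^{-k_r T})}.
#' @param dt coherence-time step, ps.
#' @param nt number of time points per coherence axis.
#' @param pad_cm half-width of the retained frequency window around the band
#'   centers.
#' @return a [twodir_spectrum()].
#' @export
simulate_2dir <- function(bands, T2_fs, coupling = NULL, dt = 0.075,
                          nt = 128L, pad_cm = 60) {
  if (inherits(bands, "ffcf_model")) bands <- list(bands)
  Tw <- T2_fs / 1000
  t <- (seq_len(nt) - 1) * dt
  nz <- 4L * nt
  # frequency axis of the zero-padded FFT (rad/ps, detuning from the frame)
  k <- seq_len(nz) - 1
  k[k >= nz / 2] <- k[k >= nz / 2] - nz
  wax <- 2 * pi * k / (nz * dt)
  ord <- order(wax)
  frame <- mean(vapply(bands, function(b) b$center, numeric(1)))
  span <- ang_to_wn(pi / dt)
  for (b in bands) {
    need <- abs(b$center - frame) + 4 * sqrt(sum(b$components$Delta_cm^2)) +
      b$anharmonicity
    if (need > span)
      stop("frequency axes too narrow for band at ", b$center,
           " cm^-1: reduce dt or the band detuning")
  }
  Sw <- matrix(0 + 0i, nz, nz)
  Snw <- matrix(0 + 0i, nz, nz)
  for (b in bands) {
    d <- wn_to_ang(b$center - frame)
    A <- wn_to_ang(b$anharmonicity)
    g1 <- .kubo_g(b, t)
    gw <- .kubo_g(b, Tw)
    g1w <- .kubo_g(b, t + Tw)
    g1w3 <- matrix(.kubo_g(b, outer(t + Tw, t, `+`)), nt, nt)
    # rephasing / non-rephasing lineshape factors
    Fr <- exp(gw + outer(-g1 - g1w, -g1 - g1w, `+`) + g1w3)
    Fnr <- exp(-gw + outer(-g1 + g1w, -g1 + g1w, `+`) - g1w3)
    amp <- b$transition_strength^2 * exp(-Tw / b$T1)
    ph1r <- exp(-1i * d * t)
    ph1n <- exp(+1i * d * t)
    ph3 <- exp(+1i * d * t) - exp(+1i * (d - A) * t)
    Rr <- amp * (ph1r %o% ph3) * Fr
    Rn <- amp * (ph1n %o% ph3) * Fnr
    # half-weight the t = 0 samples (one-sided integrals)
    Rr[1, ] <- Rr[1, ] / 2; Rr[, 1] <- Rr[, 1] / 2
    Rn[1, ] <- Rn[1, ] / 2; Rn[, 1] <- Rn[, 1] / 2
    Z <- matrix(0 + 0i, nz, nz)
    Zr <- Z; Zr[1:nt, 1:nt] <- Rr
    Zn <- Z; Zn[1:nt, 1:nt] <- Rn
    # t3 (columns): e^{-i w3 t3}; t1 (rows): e^{+i w1 t1} for rephasing,
    # e^{-i w1 t1} for non-rephasing
    Zr <- t(stats::mvfft(t(Zr)))
    Zr <- stats::mvfft(Zr, inverse = TRUE)
    Zn <- t(stats::mvfft(t(Zn)))
    Zn <- stats::mvfft(Zn)
    Sw <- Sw + Zr
    Snw <- Snw + Zn
  }
  S <- -Re(Sw + Snw) * dt^2
  S <- S[ord, ord]
  pump <- frame + ang_to_wn(wax[ord])
  probe <- pump
  lo <- min(vapply(bands, function(b) b$center, numeric(1))) - pad_cm
  hi <- max(vapply(bands, function(b) b$center, numeric(1))) + pad_cm
  ip <- which(pump >= lo & pump <= hi)
  spec <- twodir_spectrum(pump[ip], probe[ip], S[ip, ip], T2_fs,
                          meta = list(bands = bands, frame = frame,
                                      coupling = coupling))
  if (!is.null(coupling) && length(bands) > 1) {
    spec <- .add_cross_peaks(spec, bands, coupling, Tw)
  }
  spec
}

# Gaussian cross-peak lobes for every ordered donor -> acceptor pair.
.add_cross_peaks <- function(spec, bands, coupling, Tw_ps) {
  kr <- coupling$k_rise_per_ps
  kd <- coupling$k_decay_per_ps
  f <- if (abs(kr - kd) < 1e-12) kr * Tw_ps * exp(-kd * Tw_ps)
  else kr / (kr - kd) * (exp(-kd * Tw_ps) - exp(-kr * Tw_ps))
  for (i in seq_along(bands)) for (j in seq_along(bands)) {
    if (i == j) next
    don <- bands[[i]]; acc <- bands[[j]]
    sp <- sqrt(sum(don$components$Delta_cm^2))
    sr <- sqrt(sum(acc$components$Delta_cm^2))
    a <- coupling$amplitude * don$transition_strength * acc$transition_strength * f
    dp <- outer((spec$pump - don$center) / sp, rep(1, length(spec$probe)))
    blr <- outer(rep(1, length(spec$pump)), (spec$probe - acc$center) / sr)
    esr <- outer(rep(1, length(spec$pump)),
                 (spec$probe - acc$center + acc$anharmonicity) / sr)
    spec$signal <- spec$signal -
      a * exp(-(dp^2 + blr^2) / 2) + a * exp(-(dp^2 + esr^2) / 2)
  }
  spec
}

#' Analytic bivariate-Gaussian bleach/ESA spectrum
#'
#' Fast closed-form 2D spectrum: the bleach is a bivariate Gaussian over
#' (pump, probe) with given marginal widths and correlation, the ESA its
#' positive mirror shifted by the anharmonicity on the probe axis. For equal
#' marginal widths the center line slope of the bleach equals the
#' correlation coefficient, which makes this model the independent oracle
#' for the response-function engine.
#'
#' @param center band center, cm^-1.
#' @param sigma_pump,sigma_probe marginal standard deviations, cm^-1.
#' @param rho pump-probe correlation coefficient in `[0, 1)`.
#' @param anharmonicity ESA red-shift, cm^-1.
#' @param amplitude bleach depth (positive number; stored negative).
#' @param pump,probe axes, cm^-1 (defaults: center +/- 50 at 0.5 cm^-1).
#' @param T2_fs waiting-time label, fs.
#' @return a [twodir_spectrum()].
#' @export
gaussian_2dir <- function(center, sigma_pump, sigma_probe, rho,
                          anharmonicity = 20, amplitude = 1,
                          pump = NULL, probe = NULL, T2_fs = 0) {
  if (is.null(pump)) pump <- seq(center - 50, center + 50, by = 0.5)
  if (is.null(probe)) probe <- pump
  q <- function(shift) {
    zp <- outer((pump - center) / sigma_pump, rep(1, length(probe)))
    zr <- outer(rep(1, length(pump)), (probe - center - shift) / sigma_probe)
    (zp^2 - 2 * rho * zp * zr + zr^2) / (1 - rho^2)
  }
  sig <- -amplitude * exp(-q(0) / 2) + amplitude * exp(-q(-anharmonicity) / 2)
  twodir_spectrum(pump, probe, sig, T2_fs,
                  meta = list(bands = list(list(center = center,
                                                anharmonicity = anharmonicity)),
                              rho = rho))
}

#' Theoretical normalized CLS of an FFCF model
#'
#' The center-line-slope identity the analysis relies on: for Gaussian
#' frequency fluctuations whose fast components are motionally narrowed,
#' \deqn{CLS(T_2) \approx \frac{\sum_{slow} \Delta_s^2 e^{-T_2/\tau_s}}
#'   {\sum_{all} \Delta_i^2},}
#' i.e. the slow (inhomogeneous) part of the FFCF normalized by the total
#' frequency variance.
#'
#' @param model an [ffcf_model()].
#' @param T2_ps waiting times, ps.
#' @return numeric CLS values.
#' @export
cls_theory <- function(model, T2_ps) {
  D2 <- wn_to_ang(model$components$Delta_cm)^2
  if (!length(D2)) return(rep(0, length(T2_ps)))
  slow <- !.narrowed(model)
  num <- vapply(T2_ps, function(Tw)
    sum(D2[slow] * exp(-Tw / model$components$tau_ps[slow])), numeric(1))
  num / sum(D2)
}
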