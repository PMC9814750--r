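#' Frequency-fluctuation correlation function model of a vibrational band
#'
#' Microscopic model behind inhomogeneous broadening and spectral diffusion:
#' the band's instantaneous frequency fluctuates with correlation function
#' \eqn{C(t) = \sum_i \Delta_i^2 e^{-t/\tau_i}} (amplitudes in cm^-1,
#' converted to angular frequency internally), optionally plus a pure
#' dephasing time. Components with \eqn{\Delta_i\tau_i \ll 1} are motionally
#' narrowed: they contribute homogeneous Lorentzian width but no
#' pump-probe frequency correlation.
#'
#' @param center band center, cm^-1.
#' @param components data.frame or list with `Delta_cm` (fluctuation
#'   amplitudes, cm^-1) and `tau_ps` (correlation times, ps), all > 0;
#'   stored sorted by `tau_ps`.
#' @param homogeneous_T2 optional pure-dephasing time, ps.
#' @param T1 population lifetime, ps.
#' @param anharmonicity red-shift of the excited-state absorption, cm^-1
#'   (default 20, typical for amide I).
#' @param transition_strength relative band amplitude.
#' @return object of class `ffcf_model`.
#' @export
ffcf_model <- function(center, components = NULL, homogeneous_T2 = NULL,
                       T1 = 0.7, anharmonicity = 20,
                       transition_strength = 1) {
  if (is.null(components))
    components <- data.frame(Delta_cm = numeric(0), tau_ps = numeric(0))
  components <- as.data.frame(components)
  stopifnot(all(c("Delta_cm", "tau_ps") %in% names(components)))
  if (nrow(components) == 0 && is.null(homogeneous_T2))
    stop("a band needs FFCF components and/or a homogeneous_T2")
  if (any(components$Delta_cm <= 0) || any(components$tau_ps <= 0))
    stop("all Delta_i and tau_i must be > 0")
  if (T1 <= 0 || anharmonicity <= 0)
    stop("T1 and anharmonicity must be > 0")
  components <- components[order(components$tau_ps), , drop = FALSE]
  structure(list(center = center, components = components,
                 homogeneous_T2 = homogeneous_T2, T1 = T1,
                 anharmonicity = anharmonicity,
                 transition_strength = transition_strength),
            class = "ffcf_model")
}

# is component i motionally narrowed? (Delta * tau << 1, angular units)
.narrowed <- function(model, thresh = 0.2) {
  wn_to_ang(model$components$Delta_cm) * model$components$tau_ps < thresh
}

# Kubo lineshape function g(t), t in ps, angular-frequency units internally.
.kubo_g <- function(model, t) {
  g <- numeric(length(t))
  for (i in seq_len(nrow(model$components))) {
    D <- wn_to_ang(model$components$Delta_cm[i])
    tau <- model$components$tau_ps[i]
    g <- g + D^2 * tau^2 * (exp(-t / tau) + t / tau - 1)
  }
  if (!is.null(model$homogeneous_T2)) g <- g + t / model$homogeneous_T2
  g
}

#' Kubo lineshape function g(t)
#'
#' \deqn{g(t) = \sum_i \Delta_i^2 \tau_i^2 (e^{-t/\tau_i} + t/\tau_i - 1)
#'  + t/T_2,}
#' evaluated analytically per component (angular-frequency units).
#'
#' @param model an [ffcf_model()].
#' @param t time grid in ps, starting at 0 with uniform step; the step must
#'   resolve every component that is not motionally narrowed
#'   (step <= tau_i/5).
#' @return numeric g(t) (dimensionless).
#' @export
kubo_lineshape <- function(model, t) {
  if (t[1] != 0) stop("time grid must start at 0")
  dt <- diff(t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniform")
  if (length(dt)) {
    slow <- !.narrowed(model)
    if (any(slow & dt[1] > model$components$tau_ps / 5))
      stop("time step does not resolve the fastest non-narrowed FFCF component (need step <= tau_i/5)")
  }
  .kubo_g(model, t)
}

#' Linear absorption spectrum from a lineshape function
#'
#' \eqn{A(\omega) \propto \mathrm{Re}\int_0^\infty e^{i(\omega-\omega_0)t}
#' e^{-g(t)} dt}, evaluated by FFT. In the static limit the band is Gaussian
#' with standard deviation \eqn{\Delta}; in the motional-narrowing limit it
#' is Lorentzian with FWHM \eqn{2\Delta^2\tau} (angular units).
#'
#' @param model an [ffcf_model()].
#' @param dt time step, ps.
#' @param nt number of time points (zero-padded 4x for smooth axes).
#' @param lifetime if `TRUE`, include population-lifetime damping
#'   \eqn{e^{-t/(2T_1)}}.
#' @return data.frame with `wavenumber_cm` and `absorbance` (max-normalized).
#' @export
linear_ir_spectrum <- function(model, dt = 0.01, nt = 4096, lifetime = FALSE) {
  t <- (seq_len(nt) - 1) * dt
  y <- exp(-.kubo_g(model, t))
  if (lifetime) y <- y * exp(-t / (2 * model$T1))
  y[1] <- y[1] / 2
  n <- 4L * nt
  sp <- Re(stats::fft(c(y, rep(0, n - nt)), inverse = TRUE)) * dt
  k <- seq_len(n) - 1
  k[k >= n / 2] <- k[k >= n / 2] - n
  w <- 2 * pi * k / (n * dt)              # rad/ps, detuning from center
  ord <- order(w)
  wn <- model$center + ang_to_wn(w[ord])
  a <- sp[ord]
  data.frame(wavenumber_cm = wn, absorbance = a / max(a))
}

#' Baseline-correct and normalize a linear IR spectrum
#'
#' Subtracts the straight line through two anchor regions (averaged within
#' each) and divides by the maximum in the CO-peak window so the amide I
#' maximum equals 1.
#'
#' @param wavenumber,absorbance the spectrum; must cover 1500-1750 cm^-1.
#' @param anchors list of two `c(lo, hi)` wavenumber windows defining the
#'   baseline (defaults 1500-1520 and 1740-1760 cm^-1).
#' @param peak_window window containing the CO peak (default 1630-1690).
#' @return data.frame with `wavenumber_cm` and `absorbance` (CO max = 1).
#' @export
linear_ir_baseline_normalize <- function(wavenumber, absorbance,
                                         anchors = list(c(1500, 1520),
                                                        c(1740, 1760)),
                                         peak_window = c(1630, 1690)) {
  if (min(wavenumber) > 1500 || max(wavenumber) < 1750)
    stop("spectrum must cover 1500-1750 cm^-1")
  pts <- lapply(anchors, function(w) {
    sel <- wavenumber >= w[1] & wavenumber <= w[2]
    if (!any(sel)) stop(sprintf("empty anchor region %g-%g cm^-1", w[1], w[2]))
    c(x = mean(wavenumber[sel]), y = mean(absorbance[sel]))
  })
  slope <- (pts[[2]]["y"] - pts[[1]]["y"]) / (pts[[2]]["x"] - pts[[1]]["x"])
  base <- pts[[1]]["y"] + slope * (wavenumber - pts[[1]]["x"])
  corr <- absorbance - base
  sel <- wavenumber >= peak_window[1] & wavenumber <= peak_window[2]
  if (!any(sel)) stop("empty CO-peak window")
  data.frame(wavenumber_cm = wavenumber,
             absorbance = unname(corr / max(corr[sel])))
}
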