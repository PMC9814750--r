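#' Extract the center line slope of a bleach lobe
#'
#' For every pump slice whose bleach depth reaches at least `pump_frac` of
#' the deepest slice, the probe-frequency position of the bleach minimum is
#' located by parabolic interpolation; the CLS is the ordinary
#' least-squares slope of these positions versus pump frequency. Only the
#' bleach lobe is used: the probe window is bounded below by
#' `center - anharmonicity/2` to exclude the ESA.
#'
#' @param spec a [twodir_spectrum()].
#' @param center band center, cm^-1; defaults to the first band in the
#'   spectrum metadata.
#' @param anharmonicity ESA red-shift used for the probe cut; defaults to
#'   the band metadata (or 20 cm^-1).
#' @param pump_frac diagonal-depth threshold selecting usable pump slices
#'   (default 0.6).
#' @param pump_halfwidth optional half-width, cm^-1, restricting pump slices
#'   to `center +/- pump_halfwidth`.
#' @return CLS value (dimensionless) with attributes `n_slices` and
#'   `monotone`.
#' @export
extract_cls <- function(spec, center = NULL, anharmonicity = NULL,
                        pump_frac = 0.6, pump_halfwidth = NULL) {
  b1 <- spec$meta$bands[[1]]
  if (is.null(center)) center <- b1$center
  if (is.null(anharmonicity))
    anharmonicity <- if (!is.null(b1$anharmonicity)) b1$anharmonicity else 20
  jw <- which(spec$probe >= center - anharmonicity / 2 &
                spec$probe <= center + anharmonicity * 2)
  if (length(jw) < 5) stop("bleach probe window too narrow")
  ip <- seq_along(spec$pump)
  if (!is.null(pump_halfwidth))
    ip <- which(abs(spec$pump - center) <= pump_halfwidth)
  depth <- vapply(ip, function(i) min(spec$signal[i, jw]), numeric(1))
  dmin <- min(depth)
  if (dmin >= 0) stop("no bleach (negative signal) found in the window")
  use <- ip[depth <= pump_frac * dmin]
  if (length(use) < 5) stop("fewer than 5 usable pump slices")
  pos <- vapply(use, function(i) {
    s <- spec$signal[i, jw]
    j <- which.min(s)
    if (j == 1L || j == length(s)) return(spec$probe[jw[j]])
    y <- s[(j - 1):(j + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    dx <- spec$probe[jw[j + 1]] - spec$probe[jw[j]]
    if (denom == 0) spec$probe[jw[j]]
    else spec$probe[jw[j]] + 0.5 * (y[1] - y[3]) / denom * dx
  }, numeric(1))
  fit <- stats::lm(pos ~ spec$pump[use])
  cls <- unname(stats::coef(fit)[2])
  mono <- all(diff(pos) >= -1e-9) || all(diff(pos) <= 1e-9)
  structure(cls, n_slices = length(use), monotone = mono)
}

#' Fit an exponential decay to waiting-time-dependent center line slopes
#'
#' \eqn{CLS(T_2) = CLS_0 e^{-k T_2}}; the decay time \eqn{1/k} is the
#' spectral-diffusion time of the slow FFCF component.
#'
#' @param T2_fs waiting times, fs (>= 4 values including 0).
#' @param cls CLS per waiting time.
#' @param se optional per-point standard errors (weighted fit when given).
#' @return list of class `cls_result` with `T2_fs`, `cls`, `cls0`,
#'   `k_per_ps`, `decay_time_ps`, `cls_T2_0` (the measured zero-waiting-time
#'   slope), standard errors, and a `flat` flag when the decay rate is
#'   indistinguishable from zero.
#' @export
fit_cls_decay <- function(T2_fs, cls, se = NULL) {
  if (length(T2_fs) < 4) stop("need at least 4 waiting times")
  if (!any(T2_fs == 0)) stop("waiting-time series must include T2 = 0")
  t2 <- T2_fs / 1000
  flat <- stats::sd(cls) < 1e-6 * max(abs(cls), 1e-12)
  if (flat) {
    return(structure(list(T2_fs = T2_fs, cls = cls, cls0 = mean(cls),
                          cls0_se = 0, k_per_ps = 0, k_se = 0,
                          decay_time_ps = Inf,
                          cls_T2_0 = cls[which(T2_fs == 0)[1]], flat = TRUE),
                     class = "cls_result"))
  }
  pos <- cls > 0
  k0 <- if (sum(pos) >= 2)
    max(1e-3, -unname(stats::coef(stats::lm(log(cls[pos]) ~ t2[pos]))[2]))
  else 1
  w <- if (is.null(se)) rep(1, length(cls)) else 1 / se^2
  fit <- tryCatch(
    suppressWarnings(stats::nls(cls ~ c0 * exp(-k * t2), start = list(c0 = max(cls), k = k0),
               weights = w,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) stop("CLS decay fit failed")
  co <- summary(fit)$coefficients
  k <- co["k", "Estimate"]
  flat <- k < 2 * co["k", "Std. Error"] && k < 1e-3
  structure(list(T2_fs = T2_fs, cls = cls, cls0 = co["c0", "Estimate"],
                 cls0_se = co["c0", "Std. Error"], k_per_ps = k,
                 k_se = co["k", "Std. Error"],
                 decay_time_ps = if (k > 0) 1 / k else Inf,
                 cls_T2_0 = cls[which(T2_fs == 0)[1]], flat = flat),
            class = "cls_result")
}

#' Integrated bleach volume of a 2D band
#'
#' Absolute value of the signed sum of the signal over a rectangular window
#' enclosing the bleach lobe, times the pixel area.
#'
#' @param spec a [twodir_spectrum()].
#' @param pump_window,probe_window `c(lo, hi)` windows, cm^-1.
#' @return volume (signal units x cm^-2); warns when positive (ESA or
#'   neighbouring-band) signal contaminates the window by more than 5%.
#' @export
peak_volume <- function(spec, pump_window, probe_window) {
  ii <- spec$pump >= pump_window[1] & spec$pump <= pump_window[2]
  jj <- spec$probe >= probe_window[1] & spec$probe <= probe_window[2]
  if (!any(ii) || !any(jj)) stop("window does not intersect the spectrum")
  block <- spec$signal[ii, jj, drop = FALSE]
  px <- mean(diff(spec$pump)) * mean(diff(spec$probe))
  v <- abs(sum(block)) * px
  contam <- sum(block[block > 0]) * px
  if (contam > 0.05 * v)
    warning("window contaminated by positive signal exceeding 5% of the bleach volume")
  v
}

#' Vibrational population lifetime from a peak-volume decay
#'
#' Single-exponential fit \eqn{V(T_2) = V_0 e^{-T_2/\tau_{VER}}}.
#'
#' @param T2_fs waiting times, fs (>= 4, spanning at least one lifetime).
#' @param volumes bleach peak volumes per waiting time.
#' @param band identifier carried into the result.
#' @return list of class `ver_result` with `tau_VER_ps`, `tau_se_ps`, `V0`,
#'   and a `decaying` flag (FALSE when the series does not decay).
#' @export
fit_ver <- function(T2_fs, volumes, band = "band") {
  if (length(T2_fs) < 4) stop("need at least 4 waiting times")
  t2 <- T2_fs / 1000
  decaying <- stats::cor(t2, volumes) < 0
  tau0 <- if (decaying && all(volumes > 0))
    max(0.05, 1 / max(1e-3, -unname(stats::coef(stats::lm(log(volumes) ~ t2))[2])))
  else diff(range(t2))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(volumes ~ v0 * exp(-t2 / tau),
                 start = list(v0 = max(volumes), tau = tau0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  co <- if (!is.null(fit))
    tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) {
    return(structure(list(band = band, T2_fs = T2_fs, volumes = volumes,
                          tau_VER_ps = NA_real_, tau_se_ps = NA_real_,
                          V0 = NA_real_, decaying = decaying),
                     class = "ver_result"))
  }
  structure(list(band = band, T2_fs = T2_fs, volumes = volumes,
                 tau_VER_ps = co["tau", "Estimate"],
                 tau_se_ps = co["tau", "Std. Error"],
                 V0 = co["v0", "Estimate"], decaying = decaying),
            class = "ver_result")
}

#' Cross-peak rise-decay kinetics
#'
#' Integrates the off-diagonal cross-peak volume over a waiting-time series
#' and fits the two-rate energy-transfer law
#' \eqn{V(T) = A\,(e^{-k_d T} - e^{-k_r T})}, whose maximum lies at
#' \eqn{t_{max} = \ln(k_r/k_d)/(k_r - k_d)}.
#'
#' @param spectra list of [twodir_spectrum()] at increasing waiting times.
#' @param pump_window,probe_window off-diagonal window (donor pump range,
#'   acceptor probe range), cm^-1; must be disjoint from the diagonal lobes.
#' @param threshold detection threshold: the volume series must rise above
#'   its `T2 = 0` value by more than this fraction (the rise-then-decay
#'   shape is the energy-transfer signature; diagonal-lobe tails only ever
#'   decay), else the cross peak is reported as not detected.
#' @return list of class `crosspeak_result` with `T2_fs`, `volumes`,
#'   `detected`, and (when detected and fitted) `k_rise_per_ps`,
#'   `k_decay_per_ps`, `t_max_fs`.
#' @export
cross_peak_kinetics <- function(spectra, pump_window, probe_window,
                                threshold = 0.05) {
  T2 <- vapply(spectra, function(s) s$T2_fs, numeric(1))
  vols <- vapply(spectra, function(s)
    suppressWarnings(peak_volume(s, pump_window, probe_window)), numeric(1))
  if (which.max(vols) == 1L || max(vols) <= (1 + threshold) * vols[1]) {
    return(structure(list(T2_fs = T2, volumes = vols, detected = FALSE),
                     class = "crosspeak_result"))
  }
  t2 <- T2 / 1000
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(vols ~ a * (exp(-kd * t2) - exp(-kr * t2)),
                 start = list(a = max(vols) * 2, kr = 10, kd = 2),
                 lower = c(a = 0, kr = 1e-3, kd = 1e-3), algorithm = "port",
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(T2_fs = T2, volumes = vols, detected = TRUE,
                          k_rise_per_ps = NA_real_, k_decay_per_ps = NA_real_,
                          t_max_fs = 1000 * t2[which.max(vols)]),
                     class = "crosspeak_result"))
  }
  p <- stats::coef(fit)
  kr <- max(p[["kr"]], p[["kd"]]); kd <- min(p[["kr"]], p[["kd"]])
  tmax <- if (abs(kr - kd) < 1e-9) 1 / kr else log(kr / kd) / (kr - kd)
  structure(list(T2_fs = T2, volumes = vols, detected = TRUE,
                 k_rise_per_ps = kr, k_decay_per_ps = kd,
                 t_max_fs = 1000 * tmax),
            class = "crosspeak_result")
}
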