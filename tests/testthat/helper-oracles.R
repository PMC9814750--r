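# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Kramers-Kronig transform: eps'(nu) - eps_inf from eps''(x) by
# principal-value quadrature with singularity subtraction,
#   eps'(nu) - eps_inf = (2/pi) P int_0^inf x eps''(x) / (x^2 - nu^2) dx.
kk_real_from_loss <- function(loss_fn, nu, grid = NULL) {
  if (is.null(grid)) grid <- exp(seq(log(1e-4), log(1e6), length.out = 20000))
  x <- grid
  ei <- loss_fn(x)
  vapply(nu, function(v) {
    ev <- loss_fn(v)
    f <- (x * ei - v * ev) / (x^2 - v^2)
    pv <- sum((f[-1] + f[-length(f)]) / 2 * diff(x))
    a <- min(x); b <- max(x)
    # analytic PV of the subtracted constant term v*eps''(v)/(x^2 - v^2)
    corr <- v * ev * (1 / (2 * v)) * log(abs(((b - v) * (a + v)) /
                                               ((b + v) * (a - v))))
    (2 / pi) * (pv + corr)
  }, numeric(1))
}

# direct arithmetic Cavell oracle (CODATA 2018), independent of the package
cavell_oracle <- function(S, c_molL, eps_s, T = 298.15) {
  kB <- 1.380649e-23; NAv <- 6.02214076e23; e0 <- 8.8541878128e-12
  n <- c_molL * 1000 * NAv
  sqrt(3 * kB * T * e0 * (2 * eps_s + 1) * S / (eps_s * n)) / 3.33564e-30
}

# FWHM of a peaked curve by linear interpolation of the half-max crossings
fwhm_of <- function(x, y) {
  ymax <- max(y); half <- ymax / 2
  i <- which(y >= half)
  lo <- i[1]; hi <- i[length(i)]
  xl <- if (lo > 1)
    stats::approx(y[c(lo - 1, lo)], x[c(lo - 1, lo)], xout = half)$y
  else x[lo]
  xr <- if (hi < length(x))
    stats::approx(y[c(hi + 1, hi)], x[c(hi + 1, hi)], xout = half)$y
  else x[hi]
  xr - xl
}

# numerical Kubo lineshape by nested quadrature of the FFCF,
# g(t) = int_0^t int_0^t1 C(t2) dt2 dt1 with C(t) = Dw^2 exp(-t/tau)
kubo_g_quadrature <- function(Dw, tau, tvals, n = 20000) {
  vapply(tvals, function(tt) {
    if (tt == 0) return(0)
    t1 <- seq(0, tt, length.out = n)
    inner <- Dw^2 * tau * (1 - exp(-t1 / tau))   # analytic inner integral
    sum((inner[-1] + inner[-n]) / 2 * diff(t1))
  }, numeric(1))
}

# five printed proton shifts of the dipeptide (ppm)
printed_shifts <- c("H-1" = 1.29, "H-2" = 1.10, "H-3" = 3.82, "H-4" = 3.88,
                    "H-5" = 8.04)

# synthetic Lorentzian-singlet spectrum from a shift list
make_nmr_spectrum <- function(shifts, width = 0.01, ppm = seq(0, 10, 0.001)) {
  y <- rep(0, length(ppm))
  for (m in shifts) y <- y + 1 / (1 + ((ppm - m) / width)^2)
  list(ppm = ppm, intensity = y)
}

amide_model <- function() {
  ffcf_model(1660, data.frame(Delta_cm = c(8, 8), tau_ps = c(0.05, 1.1)),
             T1 = 0.7, anharmonicity = 20)
}
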