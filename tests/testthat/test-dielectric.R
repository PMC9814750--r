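water_fit <- function(...) {
  args <- utils::modifyList(
    list(S_2Ala = 6.9, tau_2Ala = 160, S_H2O = 73.2, tau_H2O = 8.3,
         alpha = 0.02, eps_inf = 3.5, kappa = 0), list(...))
  do.call(relaxation_fit, args)
}

test_that("static limit of the relaxation model is eps_inf + sum of amplitudes", {
  f <- water_fit()
  m <- eval_permittivity(f, 1e-5)
  expect_equal(m$eps_real, 6.9 + 73.2 + 3.5, tolerance = 1e-6)
  expect_lt(m$eps_imag, 1e-3)
})

test_that("Debye loss peaks at 1/(2 pi tau) with height S/2", {
  f <- relaxation_fit(S_2Ala = 6.9, tau_2Ala = 159.15, S_H2O = 1e-12,
                      tau_H2O = 1, alpha = 0, eps_inf = 1)
  nu <- loss_peak_frequency(159.15)
  expect_equal(nu, 1.0, tolerance = 1e-3)
  m <- eval_permittivity(f, nu)
  expect_equal(m$eps_imag, 6.9 / 2, tolerance = 1e-6)
  expect_equal(loss_peak_frequency(7.96), 20.0, tolerance = 1e-3)
})

test_that("alpha = 0 Cole-Cole is numerically a Debye mode", {
  grid <- exp(seq(log(0.25), log(125), length.out = 64))
  cc <- eval_permittivity(water_fit(alpha = 0), grid)
  # independent Debye evaluation
  wt <- 2e-3 * pi * grid * 8.3
  deb_r <- 6.9 / (1 + (2e-3 * pi * grid * 160)^2) + 73.2 / (1 + wt^2) + 3.5
  deb_i <- 6.9 * (2e-3 * pi * grid * 160) / (1 + (2e-3 * pi * grid * 160)^2) +
    73.2 * wt / (1 + wt^2)
  expect_lt(max(abs(cc$eps_real - deb_r)), 1e-12)
  expect_lt(max(abs(cc$eps_imag - deb_i)), 1e-12)
})

test_that("Cole-Cole loss maximum stays at 1/(2 pi tau) (grid-search oracle)", {
  f <- water_fit(S_2Ala = 1e-12, tau_2Ala = 1e3, alpha = 0.2, eps_inf = 1)
  grid <- exp(seq(log(0.1), log(1000), length.out = 20001))
  m <- eval_permittivity(f, grid)
  found <- grid[which.max(m$eps_imag)]
  expect_equal(found, loss_peak_frequency(8.3),
               tolerance = 2 * mean(diff(log(grid))))
})

test_that("model spectra are Kramers-Kronig consistent midband", {
  f <- water_fit()
  loss_fn <- function(x) eval_permittivity(f, x)$eps_imag
  nu <- exp(seq(log(1), log(50), length.out = 9))
  er <- eval_permittivity(f, nu)$eps_real
  kk <- kk_real_from_loss(loss_fn, nu)
  expect_lt(max(abs(kk - (er - f$eps_inf)) / (er - f$eps_inf)), 0.02)
})

test_that("domain errors are raised", {
  f <- water_fit()
  expect_error(eval_permittivity(f, c(-1, 2)), "positive")
  f$alpha <- 1.2
  expect_error(eval_permittivity(f, 1), "alpha")
  expect_error(relaxation_fit(1, 5, 1, 10), "tau_2Ala")
  expect_error(loss_peak_frequency(-1), "tau")
  expect_error(dielectric_spectrum(1:5, 1:5, 1:5), "at least 8")
})

test_that("noiseless fits recover the generating parameters to 0.1%", {
  truth <- water_fit(kappa = 0.5)
  freq <- exp(seq(log(0.25), log(125), length.out = 101))
  m <- eval_permittivity(truth, freq)
  fit <- fit_spectrum(dielectric_spectrum(freq, m$eps_real, m$eps_imag),
                      restarts = 2)
  for (p in c("S_2Ala", "tau_2Ala", "S_H2O", "tau_H2O", "eps_inf", "kappa"))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-3, label = p)
  expect_true(fit$converged)
  # idempotence: fitting the evaluation of a fit returns the same parameters
  m2 <- eval_permittivity(fit, freq)
  fit2 <- fit_spectrum(dielectric_spectrum(freq, m2$eps_real, m2$eps_imag),
                       restarts = 2)
  expect_equal(fit2$S_2Ala, fit$S_2Ala, tolerance = 1e-3)
  expect_equal(fit2$tau_2Ala, fit$tau_2Ala, tolerance = 1e-3)
})

test_that("Monte-Carlo amplitude recovery: median |rel err| of S_2Ala < 5% at 1% noise", {
  relerr <- vapply(1:100, function(s) {
    g <- gen_dielectric_series(c_2ala = 0.25, noise = 0.01, seed = 1000 + s)
    fit <- fit_spectrum(g$spectra[[1]], restarts = 2, seed = s)
    abs(fit$S_2Ala - g$truth$fits[[1]]$S_2Ala) / g$truth$fits[[1]]$S_2Ala
  }, numeric(1))
  expect_lt(stats::median(relerr), 0.05)
})

test_that("recovery error shrinks as noise shrinks", {
  err_at <- function(noise) stats::median(vapply(1:20, function(s) {
    g <- gen_dielectric_series(c_2ala = 0.25, noise = noise, seed = 500 + s)
    fit <- fit_spectrum(g$spectra[[1]], restarts = 2, seed = s)
    abs(fit$S_2Ala - g$truth$fits[[1]]$S_2Ala) / g$truth$fits[[1]]$S_2Ala
  }, numeric(1)))
  expect_lt(err_at(0.002), err_at(0.02))
})

test_that("conductivity-dominated water-only spectrum: kappa within 1%, S_2Ala ~ 0", {
  truth <- list(S_2Ala = 0, tau_2Ala = 160, S_H2O = 73.2, tau_H2O = 8.3,
                alpha = 0.02, eps_inf = 3.5, kappa = 5)
  freq <- exp(seq(log(0.25), log(125), length.out = 101))
  m <- eval_permittivity(truth, freq)
  fit <- fit_spectrum(dielectric_spectrum(freq, m$eps_real, m$eps_imag),
                      restarts = 3)
  expect_equal(fit$kappa, 5, tolerance = 0.01)
  se_S <- sqrt(max(fit$covariance["S_2Ala", "S_2Ala"], 1e-12))
  expect_lt(fit$S_2Ala, max(0.05, 3 * se_S))
})

test_that("fixing kappa at the DC value is honoured", {
  truth <- water_fit(kappa = 2)
  freq <- exp(seq(log(0.25), log(125), length.out = 64))
  m <- eval_permittivity(truth, freq)
  fit <- fit_spectrum(dielectric_spectrum(freq, m$eps_real, m$eps_imag),
                      fix_kappa = 2, restarts = 2)
  expect_identical(fit$kappa, 2)
  expect_equal(fit$S_2Ala, 6.9, tolerance = 1e-3)
})

test_that("spectra missing a dispersion region are rejected", {
  freq <- exp(seq(log(2), log(10), length.out = 16))
  m <- eval_permittivity(water_fit(), freq)
  expect_error(fit_spectrum(dielectric_spectrum(freq, m$eps_real, m$eps_imag)),
               "dispersion")
})
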