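test_that("generators are deterministic given seed and config", {
  a <- gen_dielectric_series(c_2ala = 0.25, salt = "LiCl",
                             c_salt = c(0.05, 0.55, 1.05), seed = 42)
  b <- gen_dielectric_series(c_2ala = 0.25, salt = "LiCl",
                             c_salt = c(0.05, 0.55, 1.05), seed = 42)
  expect_identical(a, b)
  n1 <- gen_nmr_series(salt = "KI", seed = 42)
  n2 <- gen_nmr_series(salt = "KI", seed = 42)
  expect_identical(n1, n2)
  i1 <- gen_2dir_dataset(condition = "none", T2_fs = c(0, 500), seed = 42,
                         nt = 64L)
  i2 <- gen_2dir_dataset(condition = "none", T2_fs = c(0, 500), seed = 42,
                         nt = 64L)
  expect_identical(i1, i2)
  expect_error(gen_dielectric_series(seed = 1,
                                     salt = "LiCl", c_salt = c(0.05, 1),
                                     reduction_at_cmax = 1.2), "100%")
  expect_error(gen_nmr_series(), "seed")
})

test_that("generated dielectric spectra are Kramers-Kronig consistent before noise", {
  g <- gen_dielectric_series(c_2ala = 0.25, noise = 0, seed = 1)
  sp <- g$spectra[[1]]
  tr <- g$truth$fits[[1]]
  loss_fn <- function(x) {
    m <- eval_permittivity(tr, x)
    m$eps_imag
  }
  nu <- exp(seq(log(1), log(50), length.out = 7))
  er <- stats::approx(sp$freq, sp$eps_real, xout = nu)$y
  kk <- kk_real_from_loss(loss_fn, nu)
  expect_lt(max(abs(kk - (er - tr$eps_inf)) / (er - tr$eps_inf)), 0.02)
})

test_that("binary series round-trips to a flat dipole at the configured value", {
  conc <- seq(0.05, 0.25, by = 0.05)
  g <- gen_dielectric_series(c_2ala = conc, noise = 0, seed = 1)
  fits <- lapply(g$spectra, fit_spectrum, restarts = 2)
  mu <- effective_dipole(vapply(fits, function(f) f$S_2Ala, numeric(1)),
                         conc,
                         vapply(fits, static_permittivity, numeric(1)))
  expect_lt((max(mu$mu_eff_D) - min(mu$mu_eff_D)) / mean(mu$mu_eff_D), 0.01)
})

test_that("ground-truth manifests echo the generating parameters", {
  g <- gen_dielectric_series(c_2ala = 0.25, salt = "KSCN",
                             c_salt = c(0.05, 0.55, 1.05), seed = 9)
  expect_equal(g$truth$seed, 9)
  expect_equal(g$truth$reduction_at_cmax, 0.20)
  expect_equal(length(g$truth$fits), 3)
  expect_equal(g$truth$fits[[1]]$S_2Ala, 27.6 * 0.25)
  n <- gen_nmr_series(salt = "KI", seed = 2)
  expect_equal(n$truth$excess[["H-5"]], -0.03)
  i <- gen_2dir_dataset(condition = "LiCl", T2_fs = c(0, 500), seed = 2,
                        nt = 64L)
  expect_equal(i$truth$bands$amideI$T1, 0.7)
  expect_equal(i$truth$bands$coo$tau_ps[2], 1.15)
})

test_that("NMR generator honours null and KI-like plans", {
  conc <- seq(0.05, 1.05, by = 0.25)
  null <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.03,
                         excess = c("H-5" = 0), seed = 5)
  r <- differential_shift(null$series)
  expect_lt(abs(r$slope), 2 * r$slope_se)
  ki <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.03,
                       excess = c("H-5" = -0.03), noise = 0, seed = 5)
  expect_equal(differential_shift(ki$series)$slope, -0.03, tolerance = 1e-9)
})

test_that("2D-IR generator round-trips CLS amplitudes and the salt contrast", {
  t2 <- c(0, 100, 200, 300, 500, 750, 1000, 1500)
  cls0 <- vapply(c("none", "LiCl"), function(cond) {
    g <- gen_2dir_dataset(condition = cond, T2_fs = t2, coupling = NULL,
                          noise = 0, seed = 6)
    b <- g$truth$bands$coo
    cls <- vapply(g$spectra, function(sp)
      tryCatch(as.numeric(extract_cls(sp, center = 1590,
                                      anharmonicity = b$anharmonicity,
                                      pump_halfwidth = 15)),
               error = function(e) NA_real_), numeric(1))
    ok <- !is.na(cls)
    fit_cls_decay(t2[ok], cls[ok])$cls0
  }, numeric(1))
  # LiCl raises the carboxylate inhomogeneous fraction ~2.5x
  expect_equal(cls0[["LiCl"]] / cls0[["none"]], 2.5, tolerance = 0.2)
  # homogeneous band with no inhomogeneity gives CLS ~ 0
  hom <- ffcf_model(1590, homogeneous_T2 = 0.6, T1 = 0.4, anharmonicity = 18)
  g0 <- gen_2dir_dataset(bands = list(coo = hom), T2_fs = c(0, 300),
                         coupling = NULL, noise = 0, seed = 6)
  expect_lt(abs(as.numeric(extract_cls(g0$spectra[[1]], center = 1590,
                                       anharmonicity = 18))), 0.02)
})
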