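test_that("referencing applies a rigid offset and round-trips", {
  pa <- proton_assignment(printed_shifts)
  expect_equal(reference_shifts(pa, 2.5)$delta, pa$delta)
  shifted <- reference_shifts(pa, 2.6)
  expect_equal(shifted$delta, pa$delta - 0.1)
  back <- reference_shifts(shifted, 2.4)   # undoes the offset exactly
  expect_lt(max(abs(back$delta - pa$delta)), 1e-12)
  expect_error(reference_shifts(pa, NA), "missing")
})

test_that("relative shifts are zero at the reference and track linear slopes", {
  conc <- seq(0.05, 1.05, by = 0.25)
  g0 <- gen_nmr_series(salt = "none", conc = conc, medium_slope = 0,
                       noise = 0, seed = 1)
  for (p in colnames(g0$series$shifts))
    expect_equal(relative_shift(g0$series, p)$delta_rel_ppm,
                 rep(0, length(conc)), label = p)
  g <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.02,
                      excess = c("H-5" = 0), noise = 0, seed = 1)
  dr <- relative_shift(g$series, "H-1")
  expect_equal(dr$delta_rel_ppm[length(conc)], -0.02 * (1.05 - 0.05),
               tolerance = 1e-12)
  expect_error(relative_shift(g$series, "H-9"), "unknown proton")
})

test_that("differential slope isolates the amide excess from the medium effect", {
  conc <- seq(0.05, 1.05, by = 0.25)
  # identical concentration dependence for H-1 and H-5 -> slope 0
  null <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.04,
                         excess = c("H-5" = 0), noise = 0, seed = 2)
  r0 <- differential_shift(null$series)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$classification, "medium-effect only")
  # KI-like excess slope is recovered exactly without noise
  ki <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.04,
                       excess = c("H-5" = -0.03), noise = 0, seed = 2)
  rk <- differential_shift(ki$series)
  expect_equal(rk$slope, -0.03, tolerance = 1e-10)
  # and within 2 SE with the reproducibility noise
  ki2 <- gen_nmr_series(salt = "KI", conc = conc, seed = 7)
  rk2 <- differential_shift(ki2$series)
  expect_lt(abs(rk2$slope - (-0.03)), 2.5 * rk2$slope_se)
  # GdmCl-like positive excess gives a positive slope
  gd <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.02,
                       excess = c("H-5" = 0.02), noise = 0, seed = 3)
  expect_gt(differential_shift(gd$series)$slope, 0)
  expect_error(differential_shift(
    shift_series(c(0.05, 0.3, 0.55), matrix(1:3, 3, 1,
                                            dimnames = list(NULL, "H-1")),
                 ref_conc = 0.05)), "H-5")
  expect_error(differential_shift(
    shift_series(c(0.05, 0.3),
                 matrix(1:4, 2, 2, dimnames = list(NULL, c("H-1", "H-5"))),
                 ref_conc = 0.05)), "3 concentrations")
})

test_that("differential shift is invariant under per-spectrum referencing offsets", {
  conc <- seq(0.05, 1.05, by = 0.25)
  g <- gen_nmr_series(salt = "KI", conc = conc, seed = 5)
  off <- g$series
  set.seed(9)
  offs <- stats::rnorm(length(conc), 0, 0.05)
  off$shifts <- off$shifts + offs   # rigid per-spectrum offset, all protons
  expect_equal(differential_shift(off)$slope, differential_shift(g$series)$slope,
               tolerance = 1e-9)
})

test_that("peak detection recovers the printed assignment and is translation covariant", {
  sp <- make_nmr_spectrum(printed_shifts)
  pa <- peak_detect_assign(sp$ppm, sp$intensity)
  expect_equal(pa$delta[["H-5"]], 8.04, tolerance = 1e-4)
  expect_equal(unname(pa$delta[c("H-1", "H-2")]), c(1.29, 1.10),
               tolerance = 1e-3)
  expect_equal(unname(pa$delta[c("H-3", "H-4")]), c(3.82, 3.88),
               tolerance = 1e-3)
  sp2 <- make_nmr_spectrum(printed_shifts + 0.1)
  pa2 <- peak_detect_assign(sp2$ppm, sp2$intensity)
  expect_equal(pa2$delta, pa$delta + 0.1, tolerance = 2e-3)
})

test_that("peak positions survive 1% additive noise within 0.005 ppm", {
  sp <- make_nmr_spectrum(printed_shifts)
  for (s in 1:10) {
    set.seed(s)
    noisy <- sp$intensity + stats::rnorm(length(sp$ppm), 0, 0.01)
    pa <- peak_detect_assign(sp$ppm, noisy)
    expect_lt(max(abs(pa$delta - printed_shifts[names(pa$delta)])), 0.005)
  }
})

test_that("wrong multiplicity in a window is reported with the found peaks", {
  sp <- make_nmr_spectrum(c(1.29, 3.82, 3.88, 8.04))  # H-2 missing
  expect_error(peak_detect_assign(sp$ppm, sp$intensity),
               "beta window.*expected 2 peaks, found 1")
  expect_error(peak_detect_assign(seq(0, 10, 0.01), rep(1, 1001)),
               "resolution")
})

test_that("saturating binding produces detectable nonlinearity when K c_max > 1", {
  conc <- seq(0.05, 1.05, by = 0.1)
  lin <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.03,
                        excess = c("H-5" = -0.05), noise = 0, seed = 4)
  sat <- gen_nmr_series(salt = "custom", conc = conc, medium_slope = -0.03,
                        excess = c("H-5" = -0.05),
                        saturating = list(K = 3, dmax = 0.05),
                        noise = 0, seed = 4)
  r_lin <- differential_shift(lin$series)
  r_sat <- differential_shift(sat$series)
  expect_gt(r_lin$r2, 0.999)
  expect_lt(r_sat$r2, r_lin$r2 - 0.005)
})
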