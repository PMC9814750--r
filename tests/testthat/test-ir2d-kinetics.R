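test_that("peak volume is linear and matches the Gaussian closed form", {
  pump <- seq(1630, 1690, by = 0.25)
  sig <- -outer(exp(-(pump - 1660)^2 / (2 * 4^2)),
                exp(-(pump - 1660)^2 / (2 * 5^2)))
  sp <- twodir_spectrum(pump, pump, sig, 0)
  v <- peak_volume(sp, c(1630, 1690), c(1630, 1690))
  expect_equal(v, 2 * pi * 4 * 5, tolerance = 0.01)
  sp2 <- sp; sp2$signal <- 2 * sp$signal
  expect_equal(peak_volume(sp2, c(1630, 1690), c(1630, 1690)), 2 * v)
  # an ESA-like positive lobe inside the window triggers the contamination
  # warning; the pure bleach window stays silent
  mixed <- sp
  mixed$signal <- sig + 0.5 * outer(exp(-(pump - 1660)^2 / 32),
                                    exp(-(pump - 1645)^2 / 32))
  expect_warning(peak_volume(mixed, c(1630, 1690), c(1630, 1690)),
                 "contaminated")
  expect_silent(peak_volume(sp, c(1630, 1690), c(1630, 1690)))
  expect_error(peak_volume(sp, c(1800, 1900), c(1630, 1690)), "intersect")
})

test_that("bleach volumes decay with the configured population lifetime", {
  m <- amide_model()
  t2 <- c(0, 250, 500, 1000, 1500, 2500)
  sps <- lapply(t2, function(Tw) simulate_2dir(m, Tw))
  vols <- vapply(sps, function(s)
    suppressWarnings(peak_volume(s, c(1620, 1700), c(1650, 1720))),
    numeric(1))
  expect_lt(max(abs(vols / vols[1] - exp(-t2 / 1000 / 0.7))), 0.02)
  vf <- fit_ver(t2, vols, band = "amideI")
  expect_equal(vf$tau_VER_ps, 0.7, tolerance = 0.02)
  expect_true(vf$decaying)
})

test_that("lifetime fits recover generated decays, noiseless and under noise", {
  t2 <- c(0, 200, 400, 800, 1600)
  v <- 3 * exp(-(t2 / 1000) / 0.4)
  fit <- fit_ver(t2, v, band = "coo")
  expect_equal(fit$tau_VER_ps, 0.4, tolerance = 1e-6)
  rec <- vapply(1:100, function(s) {
    set.seed(200 + s)
    fit_ver(t2, v * (1 + stats::rnorm(length(t2), 0, 0.05)))$tau_VER_ps
  }, numeric(1))
  expect_lt(abs(stats::median(rec) - 0.4) / 0.4, 0.10)
  rising <- fit_ver(t2, rev(v))
  expect_false(rising$decaying)
})

test_that("carboxylate relaxes faster than the amide in the emulation fixture", {
  g <- gen_2dir_dataset(condition = "none",
                        T2_fs = c(0, 200, 400, 800, 1200), coupling = NULL,
                        noise = 0, seed = 3)
  tau <- vapply(c(amideI = 1660, coo = 1590), function(center) {
    vols <- vapply(g$spectra, function(sp)
      suppressWarnings(peak_volume(sp, center + c(-20, 20),
                                   center + c(-8, 20))), numeric(1))
    fit_ver(c(0, 200, 400, 800, 1200), vols)$tau_VER_ps
  }, numeric(1))
  expect_lt(tau[["coo"]], tau[["amideI"]])
  expect_equal(tau[["amideI"]], 0.7, tolerance = 0.05)
  expect_equal(tau[["coo"]], 0.4, tolerance = 0.05)
})

test_that("cross-peak kinetics: closed-form maximum and round trip", {
  # closed form: k_rise = 10 /ps, k_decay = 2.5 /ps -> t_max = ln(4)/7.5 ps
  t2 <- seq(0, 1200, by = 100)
  v <- 10 / 7.5 * (exp(-2.5 * t2 / 1000) - exp(-10 * t2 / 1000))
  sps <- lapply(seq_along(t2), function(i) {
    s <- gaussian_2dir(1660, 5, 5, 0, amplitude = 1e-9, T2_fs = t2[i])
    ip <- which.min(abs(s$pump - 1660))
    jp <- which.min(abs(s$probe - 1635))
    s$signal[ip, jp] <- -v[i] / (0.5^2)  # single-pixel volume carrier
    s
  })
  cp <- cross_peak_kinetics(sps, c(1655, 1665), c(1630, 1640),
                            threshold = 0)
  expect_true(cp$detected)
  expect_equal(cp$t_max_fs, 1000 * log(4) / 7.5, tolerance = 0.05)
  # uncoupled two-band simulation: nothing above threshold
  bands <- list(amide_model(),
                ffcf_model(1590, data.frame(Delta_cm = c(8, 12),
                                            tau_ps = c(0.04, 0.3)),
                           T1 = 0.4, anharmonicity = 18))
  sp0 <- lapply(c(0, 200, 400, 800), function(Tw) simulate_2dir(bands, Tw))
  cp0 <- cross_peak_kinetics(sp0, c(1650, 1670), c(1586, 1594),
                             threshold = 0.02)
  expect_false(cp0$detected)
})

test_that("simulated energy transfer reproduces the configured kinetics", {
  bands <- list(amide_model(),
                ffcf_model(1590, data.frame(Delta_cm = c(8, 12),
                                            tau_ps = c(0.04, 0.3)),
                           T1 = 0.4, anharmonicity = 18))
  t2 <- c(0, 100, 200, 400, 700, 1200)
  mk <- function(a) lapply(t2, function(Tw)
    simulate_2dir(bands, Tw,
                  coupling = list(amplitude = a, k_rise_per_ps = 10,
                                  k_decay_per_ps = 2.5)))
  sps <- mk(0.02)
  cp <- cross_peak_kinetics(sps, c(1650, 1670), c(1585, 1600))
  expect_true(cp$detected)
  expect_equal(cp$t_max_fs, 1000 * log(4) / 7.5, tolerance = 0.10)
  # doubling the coupling amplitude doubles the cross-peak signal increment
  # (signed sums: the transfer channel is linear in its amplitude)
  sps2 <- mk(0.04)
  base <- lapply(t2, function(Tw) simulate_2dir(bands, Tw))
  ssum <- function(l, i) {
    s <- l[[i]]
    sum(s$signal[s$pump >= 1650 & s$pump <= 1670,
                 s$probe >= 1585 & s$probe <= 1600])
  }
  i <- 3  # T2 = 200 fs, near the maximum
  d1 <- ssum(sps, i) - ssum(base, i)
  d2 <- ssum(sps2, i) - ssum(base, i)
  expect_equal(d2 / d1, 2, tolerance = 1e-6)
})
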