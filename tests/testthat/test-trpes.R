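test_that("the eKE relation reproduces its anchor values", {
  expect_equal(eke(e_neut = 0, e_anion = 0.45, hnu_probe = 1.55,
                   delta = 2.0), 0)
  # shape 1.53 eV above the shifted D0: eKE = 1.55 + 1.53
  expect_equal(eke(e_neut = -1.53 - 2.0 + 5, e_anion = 5), 3.08)
  # shape 0.75 eV above the shifted D0 at the relaxed geometry
  expect_equal(eke(e_neut = -0.75 - 2.0 + 5, e_anion = 5), 2.30)
  # the calibrated model produces exactly these values at FC and minimum
  m <- calibrated_model()
  fc <- evaluate_model(m, m$fc_offset, 0)
  expect_equal(eke(fc$e_d0, fc$energies[match("upper", fc$surface)]),
               3.08, tolerance = 1e-9)
})

test_that("raw spectrum weights follow norm times squared Dyson norm", {
  m <- calibrated_model()
  rec <- make_population_fixture(fixture_spec(n_tbf = 2, horizon_fs = 0.5,
                                              spacing_fs = 1, tau_fs = Inf,
                                              seed = 9), model = m)
  tb <- rec$frames[[1]]$tbfs
  # occupy one TBF on each pair adiabat, equal norms
  tb$surface <- c("upper", "lower")
  pt <- evaluate_model(m, m$fc_offset, 0)
  tb$state_index <- match(tb$surface, pt$surface)
  rec$frames[[1]]$tbfs <- tb
  pts <- raw_spectrum(rec)
  # FC point: pure diabats, so the ratio is (d_fesh / d_shape)^2
  w_shape <- pts$weight[pts$character == "shape"]
  w_fesh <- pts$weight[pts$character == "feshbach"]
  expect_equal(w_fesh / w_shape, (0.345 / 0.607)^2, tolerance = 1e-9)
  expect_equal(w_fesh / w_shape, 0.323, tolerance = 0.002)
  # dyson_power = 1 uses the plain norm
  pts1 <- raw_spectrum(rec, dyson_power = 1)
  expect_equal(pts1$weight[pts1$character == "feshbach"] /
                 pts1$weight[pts1$character == "shape"], 0.345 / 0.607,
               tolerance = 1e-9)
  # zero-norm TBF carries zero weight
  tb$norm_w <- c(1, 0)
  rec$frames[[1]]$tbfs <- tb
  expect_equal(raw_spectrum(rec)$weight[2], 0)
})

test_that("all-negative-eKE records yield an empty spectrum with a warning", {
  m <- calibrated_model()
  rec <- make_spectrum_fixture(fixture_spec(n_tbf = 2, horizon_fs = 1,
                                            spacing_fs = 0.5,
                                            eke0_ev = -5, seed = 2),
                               model = m)
  expect_warning(pts <- suppressMessages(raw_spectrum(rec)), "empty")
  expect_identical(nrow(pts), 0L)
  expect_gt(attr(pts, "n_dropped"), 0)
})

test_that("convolution conserves the integral and realizes the stated widths", {
  pts <- data.frame(delay_fs = 25, eke_ev = 2.75, weight = 1,
                    character = "shape")
  class(pts) <- c("spectrum_points", "data.frame")
  sp <- convolve_spectrum(pts, delay_grid = seq(-35, 85, 0.5),
                          eke_grid = seq(1.5, 4.0, 0.01))
  cell <- 0.5 * 0.01
  expect_equal(sum(sp$intensity) * cell, 1, tolerance = 0.01)
  # measured fwhm along eKE within one grid cell of 0.2 eV
  prof <- sp$intensity[which.min(abs(sp$delay_fs - 25)), ]
  above <- sp$eke_ev[prof >= max(prof) / 2]
  expect_lt(abs((max(above) - min(above)) - 0.2), 0.011)
  prof_t <- sp$intensity[, which.min(abs(sp$eke_ev - 2.75))]
  above_t <- sp$delay_fs[prof_t >= max(prof_t) / 2]
  expect_lt(abs((max(above_t) - min(above_t)) - 20), 0.5)
  # two distant points give two maxima at their coordinates
  two <- data.frame(delay_fs = c(0, 40), eke_ev = c(2.2, 3.2),
                    weight = 1, character = "shape")
  class(two) <- c("spectrum_points", "data.frame")
  sp2 <- convolve_spectrum(two, delay_grid = seq(-30, 70, 1),
                           eke_grid = seq(1.5, 4.0, 0.02))
  pk <- which(sp2$intensity == max(sp2$intensity), arr.ind = TRUE)
  expect_equal(sp2$eke_ev[pk[1, 2]], 2.2, tolerance = 0.03)
  # truncation raises a lost-mass warning
  expect_warning(
    convolve_spectrum(two, delay_grid = seq(0, 30, 1),
                      eke_grid = seq(2.1, 2.4, 0.02)), "lost mass")
  expect_error(convolve_spectrum(two, delay_grid = c(1, 1, 2),
                                 eke_grid = c(2, 3)), "increasing")
  expect_error(convolve_spectrum(two, fwhm_t = 0), "fwhm")
})

test_that("window decay constants are recovered within 5% across tau values", {
  for (tau in c(10, 30, 55)) {
    fs <- fixture_spec(n_tbf = 5, tau_fs = Inf, decay_tau_fs = tau,
                       spacing_fs = 1, seed = 12)
    rec <- make_spectrum_fixture(fs, model = calibrated_model())
    pts <- raw_spectrum(rec)
    sp <- suppressWarnings(
      convolve_spectrum(pts, delay_grid = seq(0, 50, 1),
                        eke_grid = seq(1.8, 3.5, 0.02)))
    wd <- window_decays(sp, windows = list(main = c(2.4, 2.8)))
    expect_identical(wd$flag, "ok")
    expect_lt(abs(wd$tau_fs - tau) / tau, 0.05)
  }
})

test_that("flat signals return the non-decaying sentinel", {
  fs <- fixture_spec(n_tbf = 3, tau_fs = Inf, decay_tau_fs = Inf,
                     spacing_fs = 1, seed = 13)
  rec <- make_spectrum_fixture(fs, model = calibrated_model())
  sp <- suppressWarnings(
    convolve_spectrum(raw_spectrum(rec), delay_grid = seq(0, 50, 1),
                      eke_grid = seq(1.8, 3.5, 0.02)))
  wd <- window_decays(sp, windows = list(main = c(2.4, 2.8)))
  expect_identical(wd$tau_fs, Inf)
  expect_identical(wd$flag, "non-decaying")
})

test_that("a prescribed spectral drift moves the convolved peak by rate times time", {
  fs <- fixture_spec(n_tbf = 5, tau_fs = Inf, drift_ev_fs = 0.5 / 30,
                     eke0_ev = 2.6, horizon_fs = 50, spacing_fs = 0.5,
                     seed = 14)
  rec <- make_spectrum_fixture(fs, model = calibrated_model())
  pts <- raw_spectrum(rec)
  # delay grid extends beyond the horizon so every point's temporal
  # kernel is fully resolved
  sp <- suppressWarnings(
    convolve_spectrum(pts, delay_grid = seq(-30, 80, 1),
                      eke_grid = seq(1.0, 3.5, 0.02)))
  peak_at <- function(t0) {
    sp$eke_ev[which.max(sp$intensity[which.min(abs(sp$delay_fs - t0)), ])]
  }
  # between two delays 30 fs apart the peak moves by 0.5 eV, within one
  # grid cell
  expect_lt(abs((peak_at(10) - peak_at(40)) - 0.5), 0.02 + 1e-9)
  # drifting out of the high window makes it decay faster than the low one
  wd <- window_decays(sp, windows = list(high = c(2.5, 3.0),
                                         low = c(2.0, 2.5)))
  expect_true(attr(wd, "tau_ordering_high_lt_low"))
})

test_that("character layers partition the spectrum exactly", {
  m <- calibrated_model()
  rec <- make_spectrum_fixture(fixture_spec(n_tbf = 4, tau_fs = Inf,
                                            spacing_fs = 1, seed = 15),
                               model = m)
  pts <- raw_spectrum(rec)
  sp <- suppressWarnings(
    decompose_by_character(pts, delay_grid = seq(0, 50, 1),
                           eke_grid = seq(1.8, 3.5, 0.02)))
  # all-shape record: feshbach and bright layers identically zero
  expect_true(all(sp$layers$feshbach == 0))
  expect_true(all(sp$layers$bright == 0))
  total <- sp$layers$bright + sp$layers$feshbach + sp$layers$shape
  expect_lt(max(abs(total - sp$intensity)), 1e-9)
})

test_that("a uniform downshift of the anion energies shifts the mean eKE equally", {
  m <- calibrated_model()
  rec <- make_spectrum_fixture(fixture_spec(n_tbf = 3, tau_fs = Inf,
                                            spacing_fs = 2, seed = 16),
                               model = m)
  pts0 <- raw_spectrum(rec)
  shifted <- rec
  for (i in seq_along(shifted$frames)) {
    tb <- shifted$frames[[i]]$tbfs
    tb[, c("e_1", "e_2", "e_3")] <- tb[, c("e_1", "e_2", "e_3")] - 0.3
    shifted$frames[[i]]$tbfs <- tb
  }
  pts1 <- raw_spectrum(shifted)
  expect_equal(mean_eke(pts0) - mean_eke(pts1), 0.3, tolerance = 1e-9)
})
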