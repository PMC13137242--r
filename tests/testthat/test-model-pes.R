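test_that("model construction validates its invariants field by field", {
  expect_error(build_model(list(c = 0)), "'c'")
  expect_error(build_model(list(k = -1)), "'k'")
  expect_error(build_model(list(e_s = 5, e_f = 5.5)), "'e_s'")
  expect_error(build_model(list(nonsense = 1)), "unknown parameter")
  pr <- default_state_properties(); pr$osc[2] <- -1
  expect_error(build_model(list(props = pr)), "nonnegative")
  # degenerate diabats at the origin are allowed (symmetric JT limit)
  expect_equal(evaluate_model(jt_model(), 0, 0)$gap, 0)
  # Table 1 properties attached by default
  m <- build_model()
  expect_equal(m$props["bright", "osc"], 1.540)
  expect_equal(m$props["feshbach", "dyson"], 0.345)
  expect_equal(m$props["shape", "osc"], 0.195)
})

test_that("the symmetric JT lower adiabat is the textbook Mexican hat", {
  lambda <- 2; k <- 14; e0 <- 5
  m <- jt_model(lambda, k, e0)
  # closed form E0 + k r^2/2 - lambda r, independent of the polar angle
  for (r in c(0.05, lambda / k, 0.4)) {
    for (phi in seq(0, 2 * pi, length.out = 7)) {
      pt <- evaluate_model(m, r * cos(phi), r * sin(phi))
      expect_equal(pt$energies[match("lower", pt$surface)],
                   e0 + k * r^2 / 2 - lambda * r, tolerance = 1e-12)
      expect_equal(pt$energies[match("upper", pt$surface)],
                   e0 + k * r^2 / 2 + lambda * r, tolerance = 1e-12)
    }
  }
})

test_that("the 2x2 gap identity and property-sum conservation hold at random points", {
  m <- calibrated_model()
  set.seed(42)
  for (i in 1:100) {
    x <- runif(1, -0.6, 0.7); y <- runif(1, -0.5, 0.5)
    pt <- evaluate_model(m, x, y)
    d <- hbidyn:::.diabats(m, x, y)
    # (gap/2)^2 - Delta^2 = W^2
    expect_equal((pt$gap / 2)^2 - d$delta^2, d$w^2, tolerance = 1e-9)
    # adiabats bracket the diabats: lower <= min, upper >= max
    i_lo <- match("lower", pt$surface); i_up <- match("upper", pt$surface)
    expect_lte(pt$energies[i_lo], min(d$vs, d$vf) + 1e-12)
    expect_gte(pt$energies[i_up], max(d$vs, d$vf) - 1e-12)
    # mixing conserves the pair sums of oscillator strength and Dyson norm
    expect_equal(pt$osc[i_lo] + pt$osc[i_up],
                 sum(m$props[c("feshbach", "shape"), "osc"]),
                 tolerance = 1e-12)
    expect_equal(pt$dyson[i_lo] + pt$dyson[i_up],
                 sum(m$props[c("feshbach", "shape"), "dyson"]),
                 tolerance = 1e-12)
  }
})

test_that("the mixing angle winds by pi around the intersection and 0 elsewhere", {
  m <- jt_model()
  expect_equal(abs(mixing_angle_winding(m, c(0, 0), 0.2)), pi,
               tolerance = 1e-6)
  expect_equal(mixing_angle_winding(m, c(0.4, 0.1), 0.05), 0,
               tolerance = 1e-6)
  # the calibrated (asymmetric) model winds around its MECI too
  mc <- calibrated_model()
  meci <- find_meci(mc)
  expect_equal(abs(mixing_angle_winding(mc, c(meci$x, meci$y), 0.1)), pi,
               tolerance = 1e-6)
})

test_that("exact degeneracy flags the NAC as singular instead of NaN", {
  pt <- evaluate_model(jt_model(), 0, 0)
  expect_true(pt$nac_singular)
  expect_false(any(is.nan(pt$energies)))
})

test_that("calibration reproduces every gap constraint on re-evaluation", {
  m <- calibrated_model()
  fc <- evaluate_model(m, m$fc_offset, 0)
  i_up <- match("upper", fc$surface)
  # shape-Feshbach vertical gap at FC
  expect_equal(fc$gap, 0.2, tolerance = 1e-9)
  # shape-D0 gap at FC on the shifted scale
  expect_equal(fc$energies[i_up] - (fc$e_d0 + m$delta_ev), 1.53,
               tolerance = 1e-9)
  # reorganization energy via the closed-form minimum x* = x0 - a_s/k
  xstar <- m$fc_offset - m$a_s / m$k
  mn <- evaluate_model(m, xstar, 0)
  i_lo <- match("lower", mn$surface)
  expect_equal(fc$energies[i_up] - mn$energies[i_lo], 0.66,
               tolerance = 1e-9)
  expect_equal(mn$energies[i_lo] - (mn$e_d0 + m$delta_ev), 0.75,
               tolerance = 1e-9)
  # a_s = sqrt(2 k reorg)
  expect_equal(m$a_s, sqrt(2 * m$k * 0.66), tolerance = 1e-12)
})

test_that("degenerate and infeasible calibrations are handled", {
  m0 <- calibrate_from_energies(list(reorg = 0, gap_sd0_min = 1.53))
  expect_equal(m0$a_s, 0)
  expect_equal(m0$a_d0, 0)
  expect_error(calibrate_from_energies(list(reorg = -0.1)), "reorg")
  expect_error(calibrate_from_energies(list(k = 0)), "k")
  expect_error(calibrate_from_energies(list(gap_sf_fc = -0.2)), "gap_sf_fc")
  expect_error(calibrate_from_energies(list(reorg = 0)), "gap_sd0_min")
})

test_that("models serialize to the versioned text block and back", {
  m <- calibrated_model()
  txt <- model_to_text(m)
  expect_true(any(grepl("^model_format = 1$", txt)))
  m2 <- model_from_text(txt)
  expect_identical(m2$hash, m$hash)
  expect_equal(m2$a_d0, m$a_d0, tolerance = 1e-15)
  expect_equal(m2$props, m$props)
  # a different model gets a different hash
  expect_false(identical(build_model(list(k = 15))$hash, m$hash))
})
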