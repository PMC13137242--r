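test_that("symmetric JT minima sit on the closed-form ring", {
  lambda <- 2; k <- 14
  m <- jt_model(lambda, k)
  cp <- minimize_surface(m, 2, start = c(0.3, 0.2))   # lower pair adiabat
  r <- sqrt(cp$x^2 + cp$y^2)
  expect_lt(abs(r - lambda / k), 1e-8)
  ci <- evaluate_model(m, 0, 0)
  depth <- ci$energies[match("lower", ci$surface)] - cp$energy
  expect_lt(abs(depth - lambda^2 / (2 * k)), 1e-8)
  expect_true(cp$curvature_ok)
  expect_lte(cp$grad_norm, 1e-6)
})

test_that("a purely harmonic surface minimizes at its analytic minimum", {
  m <- calibrated_model()
  # the spectator bright surface is an undisplaced paraboloid about FC
  cp <- minimize_surface(m, "bright", start = c(0.4, 0.3))
  expect_lt(abs(cp$x - m$fc_offset), 1e-8)
  expect_lt(abs(cp$y), 1e-8)
  # the shape diabat along y = 0 minimizes at x0 - a_s/k exactly
  cs <- minimize_surface(m, "shape", start = c(m$fc_offset, 0))
  expect_lt(abs(cs$x - (m$fc_offset - m$a_s / m$k)), 1e-8)
  expect_lt(abs(cs$y), 1e-8)
})

test_that("character tracking finds the shape minimum from the FC point", {
  m <- calibrated_model()
  cp <- minimize_surface(m, "shape", start = c(m$fc_offset, 0))
  expect_identical(cp$character, "shape")
  expect_identical(cp$surface, "lower")     # S2 at the solution
  fc <- evaluate_model(m, m$fc_offset, 0)
  reorg <- fc$energies[match("upper", fc$surface)] - cp$energy
  expect_lt(abs(reorg - 0.66), 1e-9)
})

test_that("the two lower-sheet wells carry opposite characters", {
  m <- calibrated_model()
  shape_well <- minimize_surface(m, "shape", start = c(m$fc_offset, 0))
  fesh_well <- minimize_surface(m, "feshbach", start = c(0.4, 0))
  expect_identical(shape_well$character, "shape")
  expect_identical(fesh_well$character, "feshbach")
  expect_identical(fesh_well$surface, "lower")
  expect_true(shape_well$x < 0 && fesh_well$x > 0)
  # determinism
  again <- minimize_surface(m, "shape", start = c(m$fc_offset, 0))
  expect_identical(c(again$x, again$y), c(shape_well$x, shape_well$y))
})

test_that("the MECI is found on the analytic seam with a closed gap", {
  m <- jt_model()
  mc <- find_meci(m)
  expect_lt(abs(mc$x), 1e-8)     # symmetric model: exactly the origin
  expect_lt(abs(mc$y), 1e-8)
  expect_lte(mc$gap, 1e-5)
  mcal <- calibrated_model()
  meci <- find_meci(mcal)
  # linear-in-y coupling vanishes on y = 0; 1D root of the diabat gap
  u_seam <- (mcal$e_f - mcal$e_s) / (mcal$a_s - mcal$a_f)
  expect_lt(abs(meci$y), 1e-8)
  expect_lt(abs(meci$x - (u_seam + mcal$fc_offset)), 1e-6)
  expect_lte(meci$gap, 1e-5)
  expect_lte(meci$grad_norm, 1e-5)
  # scaling the coupling does not move the seam
  m10 <- build_model(list(c = 10 * mcal$c, e_s = mcal$e_s, e_f = mcal$e_f,
                          a_s = mcal$a_s, a_f = mcal$a_f,
                          fc_offset = mcal$fc_offset))
  meci10 <- find_meci(m10)
  expect_lt(abs(meci10$x - meci$x), 1e-6)
})

test_that("the branching scan shows a peaked intersection inside the Mexican hat", {
  m <- jt_model()
  sc <- branching_scan(m, extents = c(0.3, 0.3), n_grid = 41)
  # upper sheet minimum at the grid center (the intersection)
  ctr <- which(sc$upper == min(sc$upper), arr.ind = TRUE)
  expect_equal(unname(ctr[1, ]), c(21, 21))
  # lower-sheet minimum ring is degenerate over the polar angle
  ring <- vapply(seq(0, 2 * pi, length.out = 37), function(phi) {
    pt <- evaluate_model(m, (2 / 14) * cos(phi), (2 / 14) * sin(phi))
    pt$energies[match("lower", pt$surface)]
  }, 0)
  expect_lt(diff(range(ring)), 1e-9)
  # grid values match pointwise evaluation
  pt <- evaluate_model(m, sc$x[5], sc$y[9])
  expect_equal(sc$lower[5, 9], pt$energies[match("lower", pt$surface)])
  expect_equal(sc$upper[5, 9], pt$energies[match("upper", pt$surface)])
  # the calibrated model's lower sheet has two inequivalent wells
  # the calibrated model's lower sheet has two inequivalent wells
  # (shape side at x < 0, feshbach side at x > 0), both below the seam
  mc <- calibrated_model()
  sc2 <- branching_scan(mc, center = c(mc$fc_offset, 0),
                        extents = c(0.5, 0.3), n_grid = 61)
  left <- min(sc2$lower[sc2$x < 0, ])
  right <- min(sc2$lower[sc2$x > 0.1, ])
  meci <- find_meci(mc)
  seam_e <- mean(evaluate_model(mc, meci$x, meci$y)$energies[2:3])
  expect_lt(left, seam_e)
  expect_lt(right, seam_e)
  expect_gt(abs(left - right), 0.1)      # inequivalent
  expect_error(branching_scan(mc, n_grid = 2), "n_grid")
})

test_that("gap bookkeeping reproduces the published 1.53 -> 0.75 eV span", {
  m <- calibrated_model()
  fc <- list(x = m$fc_offset, y = 0, type = "fc")
  mn <- minimize_surface(m, "shape", start = c(m$fc_offset, 0))
  rep <- gap_report(m, list(fc, mn))
  expect_equal(rep$gap_shape_d0[1], 1.53, tolerance = 1e-9)
  expect_equal(rep$gap_shape_d0[2], 0.75, tolerance = 1e-9)
  expect_equal(rep$gap_shape_feshbach[1], 0.2, tolerance = 1e-9)
  # parallel surfaces: a_D0 = a_s makes the gap constant everywhere
  mp <- build_model(list(a_d0 = m$a_s, a_s = m$a_s, a_f = m$a_f,
                         e_s = m$e_s, e_f = m$e_f, e_d0 = m$e_d0,
                         fc_offset = m$fc_offset))
  # on y = 0 the shape-character state is the pure shape diabat, so the
  # gap to the parallel D0 surface is constant
  pts <- list(list(x = 0, y = 0), list(x = -0.4, y = 0),
              list(x = 0.3, y = 0))
  rp <- gap_report(mp, pts)
  expect_lt(diff(range(rp$gap_shape_d0)), 1e-9)
})
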