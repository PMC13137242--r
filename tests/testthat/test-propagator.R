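jt_fms_run <- function() {
  cached("jtfms", {
    m <- jt_model()
    rec0 <- single_tbf_record(m, -0.25, 0.02, px = 0, py = 2)
    propagate(rec0, m, t_final_fs = 50)
  })
}

test_that("single-surface harmonic motion has the closed-form period", {
  m <- calibrated_model()
  xstar <- m$fc_offset - m$a_s / m$k
  rec0 <- single_tbf_record(m, xstar + 0.05, 0, surface = "lower")
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  out <- propagate(rec0, m, t_final_fs = 40, dt0_au = 20, thresholds = thr)
  x <- vapply(out$frames, function(f) f$tbfs$x, 0)
  t <- vapply(out$frames, function(f) f$time_fs, 0)
  mass <- hbi_constants$amu_me
  k_au <- ev_to_hartree(m$k) * hbi_constants$bohr_angstrom^2
  period <- au_time_to_fs(2 * pi * sqrt(mass / k_au))
  fit <- minpack.lm::nlsLM(x ~ x0 + a * cos(2 * pi * t / p),
                           start = list(x0 = xstar, a = 0.05, p = period))
  expect_lt(abs(coef(fit)[["p"]] - period) / period, 0.001)
})

test_that("energy-jump steps are rejected and the driver halves the step", {
  m <- calibrated_model()
  tbf <- list(x = m$fc_offset, y = 0, px = 60, py = 0, phase = 0,
              surface = "upper")
  full <- step_centroid(tbf, m, dt_au = 20)
  expect_false(full$diagnostics$accepted)
  expect_gt(full$diagnostics$e_disc_ev, 0.16)
  halved <- step_centroid(tbf, m, dt_au = 2)
  expect_true(halved$diagnostics$accepted)
  # the driver performs the halving and still finishes the trajectory
  rec0 <- single_tbf_record(m, m$fc_offset, 0, px = 60)
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  out <- propagate(rec0, m, t_final_fs = 5, thresholds = thr)
  expect_gt(out$diagnostics$rejections, 0)
  expect_equal(out$diagnostics$n_failed, 0)
  expect_equal(n_frames(out), 12L)      # full horizon reached
})

test_that("the adiabatic limit conserves energy and populations", {
  m <- calibrated_model()
  rec0 <- single_tbf_record(m, 0.45, 0.15, surface = "lower")
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  out <- propagate(rec0, m, t_final_fs = 50, thresholds = thr)
  en <- tbf_energies(out)
  expect_lt(max(abs(en$energy_ev - en$energy_ev[1])), 1e-5)
  pops <- adiabatic_populations(out)
  expect_true(all(pops$population[pops$state == "S2"] == 1))
  nrm <- out$diagnostics$family_norms
  expect_lt(max(abs(nrm$norm - 1)), 1e-12)
  expect_true(all(out$frames[[n_frames(out)]]$tbfs$surface == "lower"))
})

test_that("single-surface dynamics is time-reversible", {
  m <- calibrated_model()
  rec0 <- single_tbf_record(m, 0.35, 0.12, px = 3, py = -2,
                            surface = "lower")
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  fwd <- propagate(rec0, m, t_final_fs = 10, thresholds = thr)
  last <- fwd$frames[[n_frames(fwd)]]$tbfs
  t_run <- fwd$frames[[n_frames(fwd)]]$time_fs
  rev0 <- single_tbf_record(m, last$x, last$y, px = -last$px,
                            py = -last$py, surface = "lower")
  bck <- propagate(rev0, m, t_final_fs = t_run, thresholds = thr)
  final <- bck$frames[[n_frames(bck)]]$tbfs
  expect_lt(abs(final$x - 0.35), 1e-6)
  expect_lt(abs(final$y - 0.12), 1e-6)
  expect_lt(abs(final$px + 3), 1e-3)
})

test_that("spawning needs coupling: zero velocity or infinite threshold give none", {
  m <- jt_model()
  still <- list(x = -0.1, y = 0.02, px = 0, py = 0, phase = 0,
                surface = "upper")
  expect_null(spawn_check(still, m))
  # threshold = Inf disables spawning entirely: populations constant
  rec0 <- single_tbf_record(m, -0.25, 0.02, py = 2)
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  out <- propagate(rec0, m, t_final_fs = 15, thresholds = thr)
  expect_identical(nrow(out$events), 0L)
  pops <- adiabatic_populations(out)
  expect_true(all(pops$population[pops$state == "S3"] == 1))
})

test_that("a JT transit spawns at coupling maxima and transfers population", {
  out <- jt_fms_run()
  sp <- out$events[out$events$type == "spawn" &
                     out$events$outcome == "accepted", ]
  expect_gte(nrow(sp), 1)
  # brute-force Lambda(t) trace from the stored parent trajectory
  m <- jt_model()
  mass <- hbi_constants$amu_me
  lam <- vapply(out$frames, function(fr) {
    tb <- fr$tbfs[fr$tbfs$id == 1, ]
    if (!nrow(tb)) return(NA_real_)
    pt <- evaluate_model(m, tb$x, tb$y)
    if (pt$nac_singular) return(NA_real_)
    abs(sum(pt$nac * bohr_to_angstrom(c(tb$px, tb$py)) / mass)) /
      hbi_constants$au_time_fs
  }, 0)
  t <- vapply(out$frames, function(f) f$time_fs, 0)
  # every accepted parent spawn lies within 2 fs of a Lambda maximum
  thr <- default_thresholds()
  peaks <- t[which(diff(sign(diff(lam))) == -2) + 1]
  peaks <- peaks[is.finite(peaks)]
  for (ts in sp$time_fs[sp$parent_id == 1])
    expect_lt(min(abs(peaks - ts)), 2)
  # population reached the lower surface
  pops <- adiabatic_populations(out)
  final <- pops[pops$time_fs == max(pops$time_fs), ]
  expect_gt(final$population[final$state == "S2"], 0.05)
  nrm <- out$diagnostics$family_norms
  expect_lt(max(abs(nrm$norm - 1)), 1e-6)
})

test_that("energetically forbidden spawns are frustrated, not errors", {
  m <- jt_model()
  # near the seam on the lower sheet, moving along the coupling
  # direction: strong Lambda but far too little kinetic energy to reach
  # the upper sheet
  tbf <- list(x = 0.05, y = 0.002, px = 0, py = 2, phase = 0,
              surface = "lower")
  sp <- spawn_check(tbf, m)
  expect_false(is.null(sp))
  expect_identical(sp$outcome, "rejected-frustrated")
  expect_identical(sp$target_state, "upper")
})

test_that("single-TBF amplitudes keep unit magnitude; two-TBF exchange matches a fine-step oracle", {
  m <- calibrated_model()
  mk <- function(x, y, px, py, ph) data.frame(
    x = x, y = y, px = px, py = py, phase = ph,
    surface = "lower", stringsAsFactors = FALSE)
  one0 <- mk(0.2, 0.05, 3, 1, 0); one1 <- mk(0.21, 0.052, 2.8, 0.9, 0.4)
  a1 <- update_amplitudes(one0, one1, complex(real = 1), dt_au = 20,
                          model = m, width_au = 8.1)
  expect_equal(Mod(a1), 1, tolerance = 1e-12, ignore_attr = TRUE)
  # two overlapping TBFs on one surface
  st0 <- mk(c(0.20, 0.30), c(0.05, 0.00), c(3, -2), c(1, 0), c(0, 0.2))
  st1 <- mk(c(0.21, 0.29), c(0.052, 0.01), c(2.8, -2.1), c(0.9, 0.1),
            c(0.4, 0.5))
  amps <- complex(real = c(sqrt(0.7), sqrt(0.3)))
  got <- update_amplitudes(st0, st1, amps, dt_au = 20, model = m,
                           width_au = 8.1)
  # oracle: same matrix elements, direct RK integration at 100x smaller
  # steps with the same interpolation rule
  mau <- hbidyn:::.model_au(m)
  tost <- function(df) lapply(seq_len(nrow(df)), function(i) list(
    x = angstrom_to_bohr(c(df$x[i], df$y[i])), p = c(df$px[i], df$py[i]),
    phase = df$phase[i], surface = df$surface[i]))
  m0 <- hbidyn:::.family_matrices(tost(st0), mau, 8.1)
  m1 <- hbidyn:::.family_matrices(tost(st1), mau, 8.1)
  dt <- 20; nf <- 4000
  ds_half <- (m1$S - m0$S) / (2 * dt)
  rhs <- function(frac, c) {
    s <- m0$S + frac * (m1$S - m0$S)
    hh <- m0$H + frac * (m1$H - m0$H)
    sd <- m0$Sdot + frac * (m1$Sdot - m0$Sdot)
    sd <- (sd - Conj(t(sd))) / 2 + ds_half
    as.vector(solve(s, (-1i * hh - sd) %*% c))
  }
  cv <- amps; h <- dt / nf
  for (i in seq_len(nf)) {
    k1 <- rhs((i - 1) / nf, cv)
    k2 <- rhs((i - 0.5) / nf, cv + 0.5 * h * k1)
    k3 <- rhs((i - 0.5) / nf, cv + 0.5 * h * k2)
    k4 <- rhs(i / nf, cv + h * k3)
    cv <- cv + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(Mod(got - cv)), 1e-8)
  # norm in the overlap metric is conserved (the TBFs overlap, so the
  # initial S-metric norm is not 1; conservation is relative to it)
  tostv <- tost(st0)
  s0 <- hbidyn:::.family_matrices(tostv, mau, 8.1)$S
  n0 <- Re(sum(Conj(amps) * (s0 %*% amps)))
  expect_equal(attr(got, "norm"), n0, tolerance = 1e-8)
})

test_that("two stacked identical TBFs trigger basis-collapse handling", {
  m <- calibrated_model()
  rec0 <- single_tbf_record(m, 0.3, 0.1, surface = "lower")
  tb <- rec0$frames[[1]]$tbfs
  tb2 <- rbind(tb, tb)
  tb2$id <- c(1L, 2L); tb2$family <- 1L
  tb2$c_re <- c(1, 0); tb2$c_im <- 0
  tb2$norm_w <- c(1, 0)
  rec0$frames[[1]]$tbfs <- tb2
  rec0$header$family_weights <- 1
  thr <- default_thresholds(); thr$spawn_thresh_fs <- Inf
  out <- propagate(rec0, m, t_final_fs = 2, thresholds = thr)
  expect_true(any(out$events$type == "collapse"))
  expect_identical(nrow(out$frames[[n_frames(out)]]$tbfs), 1L)
  nrm <- out$diagnostics$family_norms
  expect_lt(max(abs(nrm$norm - 1)), 1e-6)
})

test_that("populations from a prescribed exponential fixture recover the rate", {
  fs <- fixture_spec(n_tbf = 200, tau_fs = 20, horizon_fs = 50,
                     spacing_fs = 0.5, seed = 31)
  rec <- make_population_fixture(fs, model = calibrated_model())
  pops <- adiabatic_populations(rec)
  up <- pops[pops$state == "S3", ]
  fit <- stats::nls(population ~ exp(-time_fs / tau), data = up,
                    start = list(tau = 15))
  tau_fit <- coef(fit)[["tau"]]
  # oracle: censored-exponential MLE on the drawn switch times; the
  # population curve must reproduce the drawn process, and the draw
  # itself scatters around the truth with se ~ tau/sqrt(n)
  sw <- attr(rec, "switch_times")
  tau_mle <- sum(pmin(sw, 50)) / sum(sw <= 50)
  expect_lt(abs(tau_fit - tau_mle) / tau_mle, 0.05)
  expect_lt(abs(tau_fit - 20), 3 * 20 / sqrt(length(sw)))
  tot <- as.numeric(tapply(pops$population, pops$time_fs, sum))
  expect_equal(tot, rep(1, length(tot)), tolerance = 1e-9)
})
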