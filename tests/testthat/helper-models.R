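# Shared fixtures and independent oracles for the test suite.

# Session cache so expensive runs (full pipelines) are shared between
# test blocks that probe different properties of the same run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

calibrated_model <- function() cached("calibrated", calibrate_from_energies())

# Full default pipeline (Wigner sampling -> window filter -> 20 TBFs ->
# 50 fs multiple spawning) for a given seed.
pipeline_run <- function(seed) {
  cached(paste0("pipeline", seed), {
    m <- calibrated_model()
    ics <- sample_wigner(m, 4000, seed = seed)
    fl <- filter_energy_window(ics)
    rec0 <- initialize_ensemble(fl, m, n_tbf = 20, seed = seed)
    propagate(rec0, m, t_final_fs = 50, seed = seed)
  })
}

# Classical total energy (eV) of every TBF at every frame.
tbf_energies <- function(record) {
  mass <- record$header$mass_me
  do.call(rbind, lapply(record$frames, function(fr) {
    tb <- fr$tbfs
    v <- as.matrix(tb[, c("e_1", "e_2", "e_3")])[
      cbind(seq_len(nrow(tb)), tb$state_index)]
    data.frame(time_fs = fr$time_fs, id = tb$id,
               energy_ev = hartree_to_ev((tb$px^2 + tb$py^2) / (2 * mass)) + v)
  }))
}

# Single-TBF starting record at a prescribed phase-space point.
single_tbf_record <- function(model, x, y, px = 0, py = 0,
                              surface = "upper") {
  ics <- data.frame(x = x, y = y, px = px, py = py, gap_ev = NA)
  rec <- initialize_ensemble(ics, model, n_tbf = 1, seed = 1)
  rec$frames[[1]]$tbfs$surface <- surface
  pt <- evaluate_model(model, x, y)
  rec$frames[[1]]$tbfs$state_index <- match(surface, pt$surface)
  rec
}

# Independent oracle for the nonadiabatic benchmark: exact wavepacket
# propagation of the same two-state 2D Hamiltonian on a grid
# (split-operator, diabatic representation, FFT kinetic step).
grid_oracle <- function(model, x0_ang, p0_au, surface = "upper",
                        t_final_fs = 50, dt_au = 1, n = 96, l_bohr = 1.7) {
  mau <- hbidyn:::.model_au(model)
  mass <- mau$mass
  xs <- seq(-l_bohr, l_bohr, length.out = n + 1)[1:n]
  dx <- xs[2] - xs[1]
  ks <- 2 * pi * c(0:(n / 2 - 1), (-n / 2):(-1)) / (n * dx)
  gx <- matrix(xs, n, n); gy <- matrix(xs, n, n, byrow = TRUE)
  u <- gx - mau$x0
  vs <- mau$es + mau$as * u + 0.5 * mau$k * (u^2 + gy^2)
  vf <- mau$ef + mau$af * u + 0.5 * mau$k * (u^2 + gy^2)
  w <- mau$cc * gy
  delta <- 0.5 * (vs - vf)
  mean_e <- 0.5 * (vs + vf)
  r <- sqrt(delta^2 + w^2)
  r_safe <- pmax(r, 1e-30)
  nrm_up <- sqrt((r_safe + delta)^2 + w^2)
  up1 <- ifelse(nrm_up > 1e-15, (r_safe + delta) / nrm_up, 0)
  up2 <- ifelse(nrm_up > 1e-15, w / nrm_up, 1)
  lo1 <- -up2; lo2 <- up1
  alpha <- mass * hbidyn:::.model_omega_au(model) / 2
  xc <- angstrom_to_bohr(x0_ang)
  g <- exp(-alpha * ((gx - xc[1])^2 + (gy - xc[2])^2)) *
    exp(1i * (p0_au[1] * (gx - xc[1]) + p0_au[2] * (gy - xc[2])))
  if (surface == "upper") { ps <- g * up1; pf <- g * up2 }
  else { ps <- g * lo1; pf <- g * lo2 }
  nrm <- sqrt(sum(Mod(ps)^2 + Mod(pf)^2) * dx^2)
  ps <- ps / nrm; pf <- pf / nrm
  ek <- exp(-1i * dt_au * outer(ks^2, ks^2, "+") / (2 * mass))
  ch <- cos(r * dt_au / 2); sh <- sin(r * dt_au / 2) / r_safe
  em <- exp(-1i * mean_e * dt_au / 2)
  v11 <- em * (ch - 1i * sh * delta)
  v22 <- em * (ch + 1i * sh * delta)
  v12 <- em * (-1i * sh * w)
  nsteps <- ceiling(fs_to_au_time(t_final_fs) / dt_au)
  for (s in seq_len(nsteps)) {
    t1 <- v11 * ps + v12 * pf; pf <- v12 * ps + v22 * pf; ps <- t1
    ps <- stats::fft(ek * stats::fft(ps), inverse = TRUE) / length(ps)
    pf <- stats::fft(ek * stats::fft(pf), inverse = TRUE) / length(pf)
    t1 <- v11 * ps + v12 * pf; pf <- v12 * ps + v22 * pf; ps <- t1
  }
  al <- lo1 * ps + lo2 * pf
  au_ <- up1 * ps + up2 * pf
  list(p_lower = sum(Mod(al)^2) * dx^2, p_upper = sum(Mod(au_)^2) * dx^2,
       time_fs = au_time_to_fs(nsteps * dt_au))
}

# Closed-form vertical gap (S0 -> upper pair adiabat, eV) for any model;
# independent of evaluate_model's code path.
gap_closed_form <- function(model, x, y) {
  u <- x - model$fc_offset
  delta <- 0.5 * (model$e_s - model$e_f) + 0.5 * (model$a_s - model$a_f) * u
  0.5 * (model$e_s + model$e_f) + 0.5 * (model$a_s + model$a_f) * u +
    sqrt(delta^2 + (model$c * y)^2)
}
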