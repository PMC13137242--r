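## ---- internal atomic-unit model -------------------------------------------
## The propagator works entirely in atomic units (bohr, hartree, au time,
## mass-weighted coordinates with the package mass convention); the public
## containers use angstrom/eV/fs and convert at the boundary.

.model_au <- function(model) {
  e <- function(v) ev_to_hartree(v)                       # eV -> hartree
  s <- function(v) ev_to_hartree(v) * hbi_constants$bohr_angstrom  # slope
  k_au <- ev_to_hartree(model$k) * hbi_constants$bohr_angstrom^2
  list(
    x0 = angstrom_to_bohr(model$fc_offset),
    k = k_au, cc = s(model$c),
    es = e(model$e_s), ef = e(model$e_f),
    as = s(model$a_s), af = s(model$a_f),
    de = 0.5 * e(model$e_s - model$e_f),
    da = 0.5 * s(model$a_s - model$a_f),
    me0 = 0.5 * e(model$e_s + model$e_f),
    sa = 0.5 * s(model$a_s + model$a_f),
    mass = .hbi_mass_au()
  )
}

## Coupled-pair surfaces at (x, y) bohr: energies, gradients, NAC, theta.
.pair_eval_au <- function(mau, x, y) {
  u <- x - mau$x0
  delta <- mau$de + mau$da * u
  w <- mau$cc * y
  r <- sqrt(delta^2 + w^2)
  mean_e <- mau$me0 + mau$sa * u + 0.5 * mau$k * (u^2 + y^2)
  gm <- c(mau$sa + mau$k * u, mau$k * y)
  if (r < 1e-300) {
    dr <- c(0, 0); nac <- c(NA_real_, NA_real_)
  } else {
    dr <- c(delta * mau$da, w * mau$cc) / r
    nac <- c(w * mau$da, -delta * mau$cc) / (2 * r^2)
  }
  list(e_lower = mean_e - r, e_upper = mean_e + r,
       g_lower = gm - dr, g_upper = gm + dr,
       nac = nac, theta = 0.5 * atan2(2 * w, -2 * delta), r = r,
       delta = delta, w = w)
}

## Hessian (2x2, au) of one pair adiabat at (x, y).
.pair_hessian_au <- function(mau, x, y, surface) {
  u <- x - mau$x0
  delta <- mau$de + mau$da * u
  w <- mau$cc * y
  r <- sqrt(delta^2 + w^2)
  hm <- diag(mau$k, 2)
  if (r < 1e-12) return(hm)        # cusp: fall back to the mean curvature
  dA <- c(mau$da, 0); dW <- c(0, mau$cc)
  v <- delta * dA + w * dW
  hr <- (outer(dA, dA) + outer(dW, dW)) / r - outer(v, v) / r^3
  if (surface == "upper") hm + hr else hm - hr
}

## Velocity-Verlet advance of one centroid over dt, using fixed substeps
## of at most dt_sub, accumulating the semiclassical phase (integral of
## T - V).  x, p are length-2 vectors in au.
.vv_advance <- function(mau, surface, x, p, phase, dt, dt_sub) {
  nsub <- max(1L, ceiling(dt / dt_sub))
  h <- dt / nsub
  ev <- .pair_eval_au(mau, x[1], x[2])
  v <- if (surface == "upper") ev$e_upper else ev$e_lower
  g <- if (surface == "upper") ev$g_upper else ev$g_lower
  for (i in seq_len(nsub)) {
    ## near an intersection the adiabat curvature grows like 1/gap;
    ## refine the substep there so the energy error stays flat
    ref <- if (ev$r < 0.004) 16L else if (ev$r < 0.01) 8L else
           if (ev$r < 0.02) 4L else if (ev$r < 0.04) 2L else 1L
    hh <- h / ref
    for (j in seq_len(ref)) {
      t0 <- sum(p^2) / (2 * mau$mass)
      lag0 <- t0 - v
      ph <- p - 0.5 * hh * g
      x <- x + hh * ph / mau$mass
      ev <- .pair_eval_au(mau, x[1], x[2])
      v <- if (surface == "upper") ev$e_upper else ev$e_lower
      g <- if (surface == "upper") ev$g_upper else ev$g_lower
      if (any(!is.finite(g)))
        return(list(failed = TRUE))
      p <- ph - 0.5 * hh * g
      lag1 <- sum(p^2) / (2 * mau$mass) - v
      phase <- phase + 0.5 * hh * (lag0 + lag1)
    }
  }
  list(failed = FALSE, x = x, p = p, phase = phase, ev = ev, v = v)
}

#' Default propagation thresholds and conventions
#'
#' @return Named list: `e_disc_ev` maximum allowed change of the occupied
#'   adiabat energy per attempted step (0.16 eV; larger changes reject the
#'   step and halve the time step); `overlap_min` minimum diagonal overlap
#'   of the frame-to-frame 2x2 adiabatic mixing matrix (0.7);
#'   `max_halvings` consecutive halvings before a TBF is declared failed
#'   (10); `dt_sub_au` velocity-Verlet substep length (0.25 au);
#'   `spawn_thresh_fs` effective-coupling threshold \eqn{|d \cdot v|} for
#'   spawning (0.2 fs^-1; `Inf` disables spawning);
#'   `spawn_cooldown_fs` minimum time between spawns of one TBF (2 fs);
#'   `max_family` maximum TBFs per family (12); `kappa_max` overlap-matrix
#'   condition number triggering basis-collapse handling (1e8).
#' @export
default_thresholds <- function() {
  list(e_disc_ev = 0.16, overlap_min = 0.7, max_halvings = 10L,
       dt_sub_au = 0.25, spawn_thresh_fs = 0.2, spawn_cooldown_fs = 2,
       max_family = 12L, kappa_max = 1e8)
}

#' Advance a single TBF centroid by one adaptive step
#'
#' Performs a velocity-Verlet update of the centroid on its occupied
#' adiabat over `dt_au` (internally substepped at `thresholds$dt_sub_au`)
#' and computes the step-acceptance diagnostics: the change of the
#' occupied adiabat energy across the step and the diagonal overlap of
#' the electronic mixing character between the step endpoints.  The step
#' is marked rejected when either diagnostic violates its threshold; the
#' caller (see [propagate()]) then repeats the step with half the time
#' step.
#'
#' @param tbf List with fields `x`, `y` (angstrom), `px`, `py` (au),
#'   `phase` (au) and `surface` (`"lower"` or `"upper"`).
#' @param model A `diabatic_model`.
#' @param dt_au Attempted time step (au).
#' @param thresholds See [default_thresholds()].
#' @return List with `tbf` (the candidate updated TBF; commit only if
#'   accepted) and `diagnostics`: `dt_au`, `accepted`, `e_disc_ev`,
#'   `char_overlap`, `failed` (non-finite force encountered).
#' @export
step_centroid <- function(tbf, model, dt_au, thresholds = default_thresholds()) {
  mau <- .model_au(model)
  x <- c(angstrom_to_bohr(tbf$x), angstrom_to_bohr(tbf$y))
  p <- c(tbf$px, tbf$py)
  ev0 <- .pair_eval_au(mau, x[1], x[2])
  v0 <- if (tbf$surface == "upper") ev0$e_upper else ev0$e_lower
  res <- .vv_advance(mau, tbf$surface, x, p, tbf$phase, dt_au,
                     thresholds$dt_sub_au)
  if (res$failed)
    return(list(tbf = tbf,
                diagnostics = list(dt_au = dt_au, accepted = FALSE,
                                   e_disc_ev = NA_real_,
                                   char_overlap = NA_real_, failed = TRUE)))
  e_disc <- hartree_to_ev(abs(res$v - v0))
  ov <- abs(cos(res$ev$theta - ev0$theta))
  accepted <- (e_disc <= thresholds$e_disc_ev) && (ov >= thresholds$overlap_min)
  out <- tbf
  out$x <- bohr_to_angstrom(res$x[1]); out$y <- bohr_to_angstrom(res$x[2])
  out$px <- res$p[1]; out$py <- res$p[2]; out$phase <- res$phase
  list(tbf = out,
       diagnostics = list(dt_au = dt_au, accepted = accepted,
                          e_disc_ev = e_disc, char_overlap = ov,
                          failed = FALSE))
}

## Momentum adjustment for a spawned child: rescale along the NAC unit
## vector to conserve the classical energy.  Returns adjusted p or NULL
## (frustrated).
.adjust_momentum <- function(p, nhat, dV, mass) {
  pn <- sum(p * nhat)
  disc <- pn^2 - 2 * mass * dV
  if (disc < 0) return(NULL)
  etas <- c(-pn + sqrt(disc), -pn - sqrt(disc))
  eta <- etas[which.min(abs(etas))]
  p + eta * nhat
}

#' Check a TBF for a spawning event
#'
#' Monitors the effective nonadiabatic coupling
#' \eqn{\Lambda = |d \cdot v|} (NAC vector dotted with the centroid
#' velocity, in fs^-1).  A spawn is proposed when \eqn{\Lambda} exceeds
#' `thresholds$spawn_thresh_fs` at a local maximum of its recent history;
#' when no history is supplied, exceeding the threshold alone proposes
#' the spawn.  The child is placed on the other pair adiabat at the
#' parent geometry with momentum rescaled along the NAC direction to
#' conserve total classical energy; when the kinetic energy along that
#' direction is insufficient, the event is recorded as frustrated and no
#' child is created.
#'
#' @param tbf Public TBF list (see [step_centroid()]).
#' @param model A `diabatic_model`.
#' @param thresholds See [default_thresholds()].
#' @param lambda_history Optional numeric vector of previous
#'   \eqn{\Lambda} values (fs^-1), most recent last.
#' @return `NULL` when no spawn is proposed, otherwise a list with
#'   `coupling_fs`, `source_state`, `target_state`, `outcome`
#'   (`"accepted"` or `"rejected-frustrated"`) and, if accepted, `child`
#'   (a public TBF list with zero amplitude implied).
#' @export
spawn_check <- function(tbf, model, thresholds = default_thresholds(),
                        lambda_history = NULL) {
  mau <- .model_au(model)
  x <- c(angstrom_to_bohr(tbf$x), angstrom_to_bohr(tbf$y))
  p <- c(tbf$px, tbf$py)
  ev <- .pair_eval_au(mau, x[1], x[2])
  if (any(!is.finite(ev$nac))) return(NULL)
  lam_au <- abs(sum(ev$nac * p / mau$mass))
  lam_fs <- lam_au / hbi_constants$au_time_fs
  if (lam_fs <= thresholds$spawn_thresh_fs) return(NULL)
  if (!is.null(lambda_history) && length(lambda_history) >= 1 &&
      lam_fs < max(lambda_history))
    return(NULL)                       # still climbing toward the peak
  target <- if (tbf$surface == "upper") "lower" else "upper"
  dV <- (if (target == "upper") ev$e_upper else ev$e_lower) -
        (if (tbf$surface == "upper") ev$e_upper else ev$e_lower)
  nhat <- ev$nac / sqrt(sum(ev$nac^2))
  padj <- .adjust_momentum(p, nhat, dV, mau$mass)
  if (is.null(padj))
    return(list(coupling_fs = lam_fs, source_state = tbf$surface,
                target_state = target, outcome = "rejected-frustrated"))
  child <- tbf
  child$surface <- target
  child$px <- padj[1]; child$py <- padj[2]
  list(coupling_fs = lam_fs, source_state = tbf$surface,
       target_state = target, outcome = "accepted", child = child)
}

## ---- amplitude propagation ------------------------------------------------

## Build S, H and Sdot for one family.  `states` is a list of internal
## TBF states: x (bohr, length 2), p (au), phase, surface.
.family_matrices <- function(states, mau, alpha) {
  n <- length(states)
  xm <- t(vapply(states, function(s) s$x, c(0, 0)))
  pm <- t(vapply(states, function(s) s$p, c(0, 0)))
  gm <- vapply(states, function(s) s$phase, 0)
  surf <- vapply(states, function(s) s$surface, "")
  s_sp <- .gauss_overlap(xm, pm, gm, alpha)          # no state mask
  mask <- outer(surf, surf, "==")
  s_el <- s_sp; s_el[!mask] <- 0 + 0i

  ## per-TBF force / potential / Lagrangian for Sdot
  evs <- lapply(states, function(s) .pair_eval_au(mau, s$x[1], s$x[2]))
  vocc <- vapply(seq_len(n), function(j)
    if (surf[j] == "upper") evs[[j]]$e_upper else evs[[j]]$e_lower, 0)
  focc <- t(vapply(seq_len(n), function(j)
    -(if (surf[j] == "upper") evs[[j]]$g_upper else evs[[j]]$g_lower),
    c(0, 0)))
  tkin <- rowSums(pm^2) / (2 * mau$mass)
  lagr <- tkin - vocc

  h <- matrix(0 + 0i, n, n)
  sd <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mask[i, j]) {
        ## kinetic
        kin <- .gauss_kinetic_dim(xm[i, 1], pm[i, 1], xm[j, 1], pm[j, 1], alpha) +
               .gauss_kinetic_dim(xm[i, 2], pm[i, 2], xm[j, 2], pm[j, 2], alpha)
        tij <- s_el[i, j] * kin / (2 * mau$mass)
        ## potential: bra-ket averaged second-order Taylor at the midpoint
        xb <- (xm[i, ] + xm[j, ]) / 2
        evb <- .pair_eval_au(mau, xb[1], xb[2])
        vb <- if (surf[j] == "upper") evb$e_upper else evb$e_lower
        gb <- if (surf[j] == "upper") evb$g_upper else evb$g_lower
        hb <- .pair_hessian_au(mau, xb[1], xb[2], surf[j])
        m1 <- c(.gauss_center(xm[i, 1], pm[i, 1], xm[j, 1], pm[j, 1], alpha),
                .gauss_center(xm[i, 2], pm[i, 2], xm[j, 2], pm[j, 2], alpha)) - xb
        m2 <- outer(m1, m1); diag(m2) <- diag(m2) + 1 / (4 * alpha)
        vij <- s_el[i, j] * (vb + sum(gb * m1) + 0.5 * sum(hb * m2))
        h[i, j] <- tij + vij
      } else {
        ## first-order nonadiabatic coupling at the midpoint
        xb <- (xm[i, ] + xm[j, ]) / 2
        evb <- .pair_eval_au(mau, xb[1], xb[2])
        if (all(is.finite(evb$nac))) {
          sgn <- if (surf[i] == "lower") 1 else -1   # d_{lower,upper} = +nac
          nac <- evb$nac
          ## regularize the 1/gap divergence: midpoints almost on top of
          ## the intersection would otherwise stiffen the amplitude ODE
          ## beyond any useful step size
          nn <- sqrt(sum(nac^2))
          if (nn > 300) nac <- nac * (300 / nn)
          ddx <- c(.gauss_ddx_dim(xm[i, 1], pm[i, 1], xm[j, 1], pm[j, 1], alpha),
                   .gauss_ddx_dim(xm[i, 2], pm[i, 2], xm[j, 2], pm[j, 2], alpha))
          h[i, j] <- -(sgn / mau$mass) * s_sp[i, j] * sum(nac * ddx)
        }
      }
      ## Sdot (state-masked): derivatives of the ket centroid
      if (mask[i, j]) {
        dx <- xm[i, ] - xm[j, ]
        term <- sum((alpha * dx - 1i * (pm[i, ] + pm[j, ]) / 2) * pm[j, ] / mau$mass) +
                sum(((pm[i, ] - pm[j, ]) / (4 * alpha) + 1i * dx / 2) * focc[j, ]) +
                1i * lagr[j]
        sd[i, j] <- s_el[i, j] * term
      }
    }
  }
  h <- (h + Conj(t(h))) / 2
  list(S = s_el, H = h, Sdot = sd)
}

## Advance family amplitudes over dt using matrices at the interval
## endpoints (linear interpolation in between).  Single-TBF families use
## the exact phase integral, which conserves the norm identically.
.advance_amplitudes <- function(amps, mat0, mat1, dt) {
  n <- length(amps)
  if (n == 1L) {
    g0 <- (-1i * mat0$H[1, 1] - mat0$Sdot[1, 1]) / mat0$S[1, 1]
    g1 <- (-1i * mat1$H[1, 1] - mat1$Sdot[1, 1]) / mat1$S[1, 1]
    g <- 0.5 * dt * (g0 + g1)
    return(amps * exp(1i * Im(g)))   # generator is purely imaginary up to
                                     # roundoff; keep the norm exact
  }
  ## Between the endpoints the matrices are interpolated linearly; the
  ## Hermitian part of Sdot is replaced by the exact derivative of the
  ## interpolated S, so the propagator stays unitary in the overlap
  ## metric and norm error is integration error only.
  ds_half <- (mat1$S - mat0$S) / (2 * dt)
  rhs <- function(frac, c) {
    s  <- mat0$S    + frac * (mat1$S    - mat0$S)
    hh <- mat0$H    + frac * (mat1$H    - mat0$H)
    sd <- mat0$Sdot + frac * (mat1$Sdot - mat0$Sdot)
    sd <- (sd - Conj(t(sd))) / 2 + ds_half
    solve(s, (-1i * hh - sd) %*% c)
  }
  g0 <- solve(mat0$S, (-1i * mat0$H - mat0$Sdot))
  g1 <- solve(mat1$S, (-1i * mat1$H - mat1$Sdot))
  gnorm <- max(rowSums(Mod(g0)), rowSums(Mod(g1)))
  nsub <- min(max(8L, ceiling(dt * gnorm / 0.01)), 40000L)
  hstep <- dt / nsub
  cvec <- amps
  for (i in seq_len(nsub)) {
    f0 <- (i - 1) / nsub; fh <- (i - 0.5) / nsub; f1 <- i / nsub
    k1 <- rhs(f0, cvec)
    k2 <- rhs(fh, cvec + 0.5 * hstep * k1)
    k3 <- rhs(fh, cvec + 0.5 * hstep * k2)
    k4 <- rhs(f1, cvec + hstep * k3)
    cvec <- cvec + (hstep / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(cvec)
}

#' Propagate family amplitudes over one time step
#'
#' Advances the complex amplitudes of one spawning family by the
#' time-dependent Schroedinger equation in the nonorthogonal frozen-
#' Gaussian basis, \eqn{i S \dot c = (H - i \dot S) c}: overlap, kinetic
#' (analytic) and potential (bra-ket averaged second-order Taylor)
#' matrix elements on the occupied adiabats, first-order NAC coupling
#' between states, and the basis time-derivative term.  The propagator
#' is unitary in the overlap metric, so the family norm
#' \eqn{c^\dagger S c} is conserved to integrator tolerance.
#'
#' @param family_start,family_end Data frames with one row per TBF and
#'   columns `x`, `y` (angstrom), `px`, `py`, `phase` (au) and `surface`,
#'   giving the centroids at the beginning and end of the step.
#' @param amps Complex amplitude vector at the start of the step.
#' @param dt_au Step length (au).
#' @param model A `diabatic_model`.
#' @param width_au Frozen-Gaussian width alpha (bohr^-2).
#' @return The amplitude vector at the end of the step, with attribute
#'   `norm` giving \eqn{\mathrm{Re}(c^\dagger S c)} at the end.
#' @export
update_amplitudes <- function(family_start, family_end, amps, dt_au,
                              model, width_au) {
  mau <- .model_au(model)
  tostates <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(x = c(angstrom_to_bohr(df$x[i]), angstrom_to_bohr(df$y[i])),
         p = c(df$px[i], df$py[i]), phase = df$phase[i],
         surface = df$surface[i]))
  m0 <- .family_matrices(tostates(family_start), mau, width_au)
  m1 <- .family_matrices(tostates(family_end), mau, width_au)
  out <- .advance_amplitudes(amps, m0, m1, dt_au)
  s1 <- m1$S
  attr(out, "norm") <- Re(Conj(out) %*% s1 %*% out)[1]
  out
}

## ---- full multiple-spawning driver ----------------------------------------

#' Propagate a TBF ensemble by full multiple spawning
#'
#' Starting from the t = 0 frame of `ensemble`, propagates every family
#' independently (independent first-generation approximation): classical
#' velocity-Verlet centroid dynamics on the occupied adiabat with
#' adaptive time steps and the step-rejection rules (energy
#' discontinuity above `thresholds$e_disc_ev`, or electronic mixing
#' character overlap below `thresholds$overlap_min`, repeat the step
#' with half the previous time step; after `max_halvings` consecutive
#' halvings the TBF is declared failed, removed, and counted — the rest
#' of the ensemble continues).  Spawning monitors the effective coupling
#' \eqn{|d \cdot v|} and places children on the coupled adiabat at
#' coupling maxima with energy-conserving momentum adjustment
#' (frustrated attempts are recorded, not errors); children may spawn
#' grandchildren back onto the original state.  Quantum amplitudes are
#' advanced within each family in the nonorthogonal Gaussian basis (see
#' [update_amplitudes()]); near-singular overlap matrices trigger
#' basis-collapse handling (offending child removed, amplitudes
#' renormalized, event logged).
#'
#' @param ensemble An `ensemble_record` with a valid t = 0 frame (see
#'   [initialize_ensemble()]).
#' @param model A `diabatic_model` (defaults to the model stored in the
#'   record header).
#' @param t_final_fs Propagation horizon (fs, default 50).
#' @param dt0_au Outer (frame) time step (au, default 20); rejection
#'   halves it transiently within a frame.
#' @param thresholds See [default_thresholds()].
#' @param seed Seed recorded in the header (the dynamics itself is
#'   deterministic).
#' @return An `ensemble_record` whose frames cover `[0, t_final_fs]`,
#'   with components `events` (data frame of spawn/frustrated/collapse/
#'   failure events) and `diagnostics` (list: `n_failed`, `rejections`,
#'   `family_norms` data frame of per-family norm time series).
#' @export
propagate <- function(ensemble, model = NULL, t_final_fs = 50,
                      dt0_au = 20, thresholds = default_thresholds(),
                      seed = NA_integer_) {
  validate_ensemble(ensemble)
  if (n_frames(ensemble) < 1)
    stop("propagate: ensemble has no t = 0 frame", call. = FALSE)
  if (dt0_au <= 0) stop("propagate: dt0_au must be > 0", call. = FALSE)
  if (is.null(model)) model <- record_model(ensemble)
  thr <- utils::modifyList(default_thresholds(), thresholds)
  mau <- .model_au(model)
  alpha <- ensemble$header$width_au
  if (!is.finite(alpha))
    alpha <- .hbi_mass_au() * .model_omega_au(model) / 2

  f0 <- ensemble$frames[[1]]
  tb0 <- f0$tbfs
  fam_w <- ensemble$header$family_weights
  next_id <- max(tb0$id) + 1L

  ## internal state: one entry per family
  families <- lapply(sort(unique(tb0$family)), function(fam) {
    rows <- tb0[tb0$family == fam, , drop = FALSE]
    states <- lapply(seq_len(nrow(rows)), function(i) list(
      id = rows$id[i], parent_id = rows$parent_id[i], family = fam,
      surface = rows$surface[i],
      x = c(angstrom_to_bohr(rows$x[i]), angstrom_to_bohr(rows$y[i])),
      p = c(rows$px[i], rows$py[i]), phase = rows$phase[i]))
    list(fam = fam, states = states,
         amps = complex(real = rows$c_re, imaginary = rows$c_im),
         lam_hist = stats::setNames(rep(list(numeric(0)), nrow(rows)),
                                    as.character(rows$id)),
         last_spawn = stats::setNames(rep(-Inf, nrow(rows)),
                                      as.character(rows$id)),
         alive = TRUE)
  })

  dt0_fs <- au_time_to_fs(dt0_au)
  nsteps <- ceiling(t_final_fs / dt0_fs)
  events <- list()
  n_failed <- 0L
  n_reject <- 0L
  norms_log <- list()

  snapshot_frame <- function(t_fs) {
    rows <- list()
    for (fm in families) {
      if (!fm$alive || !length(fm$states)) next
      for (i in seq_along(fm$states)) {
        st <- fm$states[[i]]
        rows[[length(rows) + 1L]] <-
          .tbf_row(model, st$id, st$parent_id, st$family, st$surface,
                   bohr_to_angstrom(st$x[1]), bohr_to_angstrom(st$x[2]),
                   st$p[1], st$p[2], alpha, st$phase, fm$amps[i],
                   norm_w = NA_real_)
      }
    }
    if (!length(rows)) {
      tb <- f0$tbfs[0, , drop = FALSE]
    } else {
      tb <- do.call(rbind, rows)
      tb$norm_w <- .frame_mulliken(tb, fam_w, mau$mass)
    }
    list(time_fs = t_fs, tbfs = tb)
  }

  frames <- list(snapshot_frame(f0$time_fs))
  t_fs <- f0$time_fs

  for (step in seq_len(nsteps)) {
    for (fi in seq_along(families)) {
      fm <- families[[fi]]
      if (!fm$alive || !length(fm$states)) next
      start_states <- fm$states
      dead <- logical(length(fm$states))

      ## --- centroid advance with rejection/halving -----------------------
      for (si in seq_along(fm$states)) {
        st <- fm$states[[si]]
        remaining <- dt0_au
        dt_try <- dt0_au
        halv <- 0L
        iters <- 0L
        repeat {
          if (remaining <= 1e-9) break
          iters <- iters + 1L
          if (iters > 3000L || dt_try < dt0_au * 2^-30) {
            ## dt underflow backstop: a centroid that cannot advance at
            ## any usable step (e.g. an exact conical-apex passage, where
            ## the mixing character is genuinely discontinuous) is
            ## discarded like any other hard failure
            dead[si] <- TRUE
            n_failed <- n_failed + 1L
            events[[length(events) + 1L]] <- data.frame(
              time_fs = t_fs, type = "hard-failure", parent_id = st$id,
              child_id = NA_integer_, source_state = st$surface,
              target_state = NA_character_, coupling_fs = NA_real_,
              outcome = "discarded", stringsAsFactors = FALSE)
            break
          }
          dt_use <- min(dt_try, remaining)
          ev0 <- .pair_eval_au(mau, st$x[1], st$x[2])
          v0 <- if (st$surface == "upper") ev0$e_upper else ev0$e_lower
          res <- .vv_advance(mau, st$surface, st$x, st$p, st$phase,
                             dt_use, thr$dt_sub_au)
          ok <- FALSE
          if (!res$failed) {
            e_disc <- hartree_to_ev(abs(res$v - v0))
            ov <- abs(cos(res$ev$theta - ev0$theta))
            ok <- (e_disc <= thr$e_disc_ev) && (ov >= thr$overlap_min)
          }
          if (ok) {
            st$x <- res$x; st$p <- res$p; st$phase <- res$phase
            remaining <- remaining - dt_use
            halv <- 0L
            dt_try <- min(2 * dt_try, dt0_au)   # adaptive regrowth
          } else {
            n_reject <- n_reject + 1L
            halv <- halv + 1L
            dt_try <- dt_try / 2
            if (res$failed || halv >= thr$max_halvings) {
              dead[si] <- TRUE
              n_failed <- n_failed + 1L
              events[[length(events) + 1L]] <- data.frame(
                time_fs = t_fs, type = "hard-failure", parent_id = st$id,
                child_id = NA_integer_, source_state = st$surface,
                target_state = NA_character_, coupling_fs = NA_real_,
                outcome = "discarded", stringsAsFactors = FALSE)
              break
            }
          }
        }
        fm$states[[si]] <- st
      }

      if (any(dead)) {
        keep <- !dead
        fm$states <- fm$states[keep]
        start_states <- start_states[keep]
        fm$amps <- fm$amps[keep]
        if (!length(fm$states)) { fm$alive <- FALSE; families[[fi]] <- fm; next }
        nrm <- Re(Conj(fm$amps) %*%
                    .family_matrices(fm$states, mau, alpha)$S %*% fm$amps)[1]
        if (nrm > 0) fm$amps <- fm$amps / sqrt(nrm)
      }

      ## --- amplitude propagation over the committed step -----------------
      m1 <- NULL
      if (length(fm$states) >= 1) {
        m0 <- .family_matrices(start_states, mau, alpha)
        m1 <- .family_matrices(fm$states, mau, alpha)
        ## an exactly singular overlap (stacked twins) makes the update
        ## unsolvable; keep the amplitudes and let the collapse guard
        ## below prune the basis
        fm$amps <- tryCatch(.advance_amplitudes(fm$amps, m0, m1, dt0_au),
                            error = function(e) fm$amps)
      }

      ## --- basis-collapse guard ------------------------------------------
      if (length(fm$states) > 1) {
        sv <- svd(m1$S)$d
        if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > thr$kappa_max) {
          off <- Mod(m1$S); diag(off) <- 0
          worst <- which(off == max(off), arr.ind = TRUE)[1, ]
          drop_i <- worst[which.max(c(fm$states[[worst[1]]]$id,
                                      fm$states[[worst[2]]]$id))]
          ev_id <- fm$states[[drop_i]]$id
          nrm0 <- Re(Conj(fm$amps) %*% m1$S %*% fm$amps)[1]
          fm$states <- fm$states[-drop_i]
          fm$amps <- fm$amps[-drop_i]
          m1 <- .family_matrices(fm$states, mau, alpha)
          nrm1 <- Re(Conj(fm$amps) %*% m1$S %*% fm$amps)[1]
          if (nrm1 > 0) fm$amps <- fm$amps * sqrt(max(nrm0, 0) / nrm1)
          events[[length(events) + 1L]] <- data.frame(
            time_fs = t_fs + dt0_fs, type = "collapse",
            parent_id = ev_id, child_id = NA_integer_,
            source_state = NA_character_, target_state = NA_character_,
            coupling_fs = NA_real_, outcome = "removed",
            stringsAsFactors = FALSE)
        }
      }

      ## family norm log (children appended below carry zero amplitude
      ## and do not change the norm)
      if (is.null(m1)) m1 <- .family_matrices(fm$states, mau, alpha)
      norms_log[[length(norms_log) + 1L]] <- data.frame(
        time_fs = t_fs + dt0_fs, family = fm$fam,
        norm = Re(Conj(fm$amps) %*% m1$S %*% fm$amps)[1])

      ## --- spawning -------------------------------------------------------
      if (is.finite(thr$spawn_thresh_fs)) {
        n_now <- length(fm$states)
        for (si in seq_len(n_now)) {
          st <- fm$states[[si]]
          key <- as.character(st$id)
          ev <- .pair_eval_au(mau, st$x[1], st$x[2])
          lam_fs <- if (any(!is.finite(ev$nac))) 0 else
            abs(sum(ev$nac * st$p / mau$mass)) / hbi_constants$au_time_fs
          hist <- fm$lam_hist[[key]]
          if (is.null(hist)) hist <- numeric(0)
          can_spawn <- length(fm$states) < thr$max_family &&
            (t_fs + dt0_fs - fm$last_spawn[key]) >= thr$spawn_cooldown_fs
          if (can_spawn && length(hist) >= 2) {
            l1 <- hist[length(hist)]; l2 <- hist[length(hist) - 1]
            if (l1 > thr$spawn_thresh_fs && l1 >= l2 && l1 >= lam_fs) {
              pub <- list(x = bohr_to_angstrom(st$x[1]),
                          y = bohr_to_angstrom(st$x[2]),
                          px = st$p[1], py = st$p[2],
                          phase = st$phase, surface = st$surface)
              sp <- spawn_check(pub, model, thr)
              if (!is.null(sp)) {
                child_id <- NA_integer_
                if (identical(sp$outcome, "accepted")) {
                  child_id <- next_id; next_id <- next_id + 1L
                  ch <- list(id = child_id, parent_id = st$id,
                             family = fm$fam, surface = sp$child$surface,
                             x = st$x, p = c(sp$child$px, sp$child$py),
                             phase = st$phase)
                  fm$states[[length(fm$states) + 1L]] <- ch
                  fm$amps <- c(fm$amps, 0 + 0i)
                  fm$lam_hist[[as.character(child_id)]] <- numeric(0)
                  fm$last_spawn[as.character(child_id)] <- t_fs + dt0_fs
                }
                fm$last_spawn[key] <- t_fs + dt0_fs
                events[[length(events) + 1L]] <- data.frame(
                  time_fs = t_fs + dt0_fs, type = "spawn",
                  parent_id = st$id, child_id = child_id,
                  source_state = sp$source_state,
                  target_state = sp$target_state,
                  coupling_fs = sp$coupling_fs, outcome = sp$outcome,
                  stringsAsFactors = FALSE)
              }
            }
          }
          fm$lam_hist[[key]] <- c(utils::tail(hist, 2), lam_fs)
        }
      }

      families[[fi]] <- fm
    }

    t_fs <- t_fs + dt0_fs
    frames[[length(frames) + 1L]] <- snapshot_frame(t_fs)
  }

  out <- ensemble_record(model, frames, seed = seed,
                         family_weights = fam_w,
                         dt_policy = list(dt0_au = dt0_au,
                                          dt_sub_au = thr$dt_sub_au,
                                          e_disc_ev = thr$e_disc_ev,
                                          overlap_min = thr$overlap_min,
                                          max_halvings = thr$max_halvings),
                         width_au = alpha)
  out$events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_fs = numeric(0), type = character(0),
               parent_id = integer(0), child_id = integer(0),
               source_state = character(0), target_state = character(0),
               coupling_fs = numeric(0), outcome = character(0))
  out$diagnostics <- list(
    n_failed = n_failed, rejections = n_reject,
    family_norms = do.call(rbind, norms_log))
  validate_ensemble(out)
  out
}

#' Adiabatic population dynamics of a record
#'
#' Recomputes, at every frame, the Mulliken-partitioned norm of each TBF
#' (\eqn{\mathrm{Re}[c^*_j (S c)_j]} within its family, scaled by the
#' family weight) and sums it per occupied adiabatic state, normalizing
#' by the total so populations sum to 1 at every frame.  States are
#' labeled `"S1"` (the spectator bright surface), `"S2"` (the lower
#' adiabat of the coupled pair) and `"S3"` (the upper adiabat) — the
#' adiabatic ordering at the Franck-Condon point, followed by surface
#' identity so that the curves are continuous even where a relaxing pair
#' adiabat transiently crosses the spectator.
#'
#' @param record An `ensemble_record` with at least one frame.
#' @return A long-format data frame with columns `time_fs`, `state` and
#'   `population` (summing to 1 at each frame).
#' @export
adiabatic_populations <- function(record) {
  validate_ensemble(record)
  if (n_frames(record) < 1)
    stop("adiabatic_populations: record has no frames", call. = FALSE)
  fw <- record$header$family_weights
  mass <- record$header$mass_me
  lab <- c(bright = "S1", lower = "S2", upper = "S3")
  out <- lapply(record$frames, function(fr) {
    nw <- .frame_mulliken(fr$tbfs, fw, mass)
    tot <- sum(nw)
    pops <- vapply(names(lab), function(s)
      sum(nw[fr$tbfs$surface == s]), 0)
    if (tot > 0) pops <- pops / tot
    data.frame(time_fs = fr$time_fs, state = unname(lab),
               population = unname(pops), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
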