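#' Specification for a synthetic fixture ensemble
#'
#' Fixtures are schema-valid ensemble records with known ground truth,
#' generated without running any dynamics: state occupations switch by a
#' prescribed stochastic process and spectral quantities drift by
#' prescribed rates, so every analysis stage (populations, character
#' relabeling, TRPES synthesis, decay fitting) can be tested in
#' isolation from the propagator.
#'
#' @param n_tbf Number of TBFs (one per family).
#' @param horizon_fs Time horizon (fs).
#' @param spacing_fs Frame spacing (fs), > 0.
#' @param tau_fs Population-transfer time constant (fs), > 0 (may be
#'   `Inf` for no transfer).
#' @param drift_ev_fs Linear drift rate of the anion-neutral gap
#'   (eV/fs); positive values move the eKE peak down.
#' @param eke0_ev Initial eKE of the spectrum fixture (eV) under the
#'   default probe energy and shift.
#' @param decay_tau_fs Deterministic intensity-decay constant (fs) of
#'   the spectrum fixture, realized by modulating the per-frame Dyson
#'   norms; `Inf` for constant intensity.
#' @param props Per-diabat property table (defaults to
#'   [default_state_properties()]).
#' @param seed Integer seed.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_tbf = 20, horizon_fs = 50, spacing_fs = 0.5,
                         tau_fs = 20, drift_ev_fs = 0, eke0_ev = 2.6,
                         decay_tau_fs = Inf,
                         props = default_state_properties(), seed = 1) {
  if (spacing_fs <= 0) stop("fixture_spec: spacing_fs must be > 0",
                            call. = FALSE)
  if (is.na(tau_fs) || tau_fs <= 0)
    stop("fixture_spec: tau_fs must be > 0", call. = FALSE)
  if (decay_tau_fs <= 0)
    stop("fixture_spec: decay_tau_fs must be > 0", call. = FALSE)
  if (n_tbf < 1) stop("fixture_spec: n_tbf must be >= 1", call. = FALSE)
  out <- list(n_tbf = as.integer(n_tbf), horizon_fs = horizon_fs,
              spacing_fs = spacing_fs, tau_fs = tau_fs,
              drift_ev_fs = drift_ev_fs, eke0_ev = eke0_ev,
              decay_tau_fs = decay_tau_fs, props = props,
              seed = as.integer(seed))
  class(out) <- "fixture_spec"
  out
}

## Shared scaffolding: all TBFs frozen at the FC point of `model`,
## one family each, equal weights.
.fixture_base <- function(spec, model) {
  times <- seq(0, spec$horizon_fs, by = spec$spacing_fs)
  w <- rep(1 / spec$n_tbf, spec$n_tbf)
  pt <- evaluate_model(model, model$fc_offset, 0)
  list(times = times, w = w, pt = pt,
       i_up = match("upper", pt$surface),
       i_lo = match("lower", pt$surface))
}

#' Population fixture: exponential state transfer with known rate
#'
#' Every TBF starts on the upper adiabat (shape character at the FC
#' point); each switches to the lower adiabat at an independent
#' exponentially distributed time with mean `tau_fs`, so the
#' ensemble-average upper-state population equals \eqn{e^{-t/\tau}} in
#' expectation.  Total norm is exactly 1 at every frame and the record
#' passes full schema validation.  The drawn switch times are attached
#' as attribute `switch_times` for oracle comparisons.
#'
#' @param spec A [fixture_spec()].
#' @param model Optional `diabatic_model` supplying geometry, energies
#'   and property mixing (default [calibrate_from_energies()] with the
#'   spec's property table).
#' @return A validated `ensemble_record`.
#' @export
make_population_fixture <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(model)) {
    model <- calibrate_from_energies()
    model <- build_model(utils::modifyList(
      unclass(model)[setdiff(names(unclass(model)), "hash")],
      list(props = spec$props)))
  }
  fb <- .fixture_base(spec, model)
  switch_times <- .with_seed(spec$seed, {
    if (is.finite(spec$tau_fs)) stats::rexp(spec$n_tbf, 1 / spec$tau_fs)
    else rep(Inf, spec$n_tbf)
  })
  frames <- lapply(fb$times, function(t) {
    rows <- lapply(seq_len(spec$n_tbf), function(i) {
      surf <- if (t < switch_times[i]) "upper" else "lower"
      .tbf_row(model, id = i, parent_id = NA_integer_, family = i,
               surface = surf, x = model$fc_offset, y = 0,
               px = 0, py = 0, width = 8, phase = 0,
               camp = complex(real = 1, imaginary = 0),
               norm_w = fb$w[i])
    })
    list(time_fs = t, tbfs = do.call(rbind, rows))
  })
  rec <- ensemble_record(model, frames, seed = spec$seed,
                         family_weights = fb$w, width_au = 8)
  validate_ensemble(rec)
  attr(rec, "switch_times") <- switch_times
  rec
}

#' Spectrum fixture: linear eKE drift and deterministic intensity decay
#'
#' All TBFs occupy the upper (shape-character) adiabat at the frozen FC
#' geometry.  The anion-neutral gap of each TBF drifts linearly at
#' `drift_ev_fs`, so under the default probe energy (1.55 eV) and shift
#' (+2.0 eV) the pre-convolution eKE peak moves from `eke0_ev` by
#' `-drift_ev_fs * t` — the synthetic analogue of vibrational-energy
#' redistribution lowering the ionization energy.  A finite
#' `decay_tau_fs` additionally scales all per-frame Dyson norms by
#' \eqn{e^{-t/(2\tau)}}, giving photoelectron intensity
#' \eqn{\propto e^{-t/\tau}} while keeping the total norm at exactly 1.
#' The generating parameters are attached as attribute `truth`.
#'
#' @inheritParams make_population_fixture
#' @return A validated `ensemble_record`.
#' @export
make_spectrum_fixture <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(model)) {
    model <- calibrate_from_energies()
    model <- build_model(utils::modifyList(
      unclass(model)[setdiff(names(unclass(model)), "hash")],
      list(props = spec$props)))
  }
  fb <- .fixture_base(spec, model)
  e_occ <- fb$pt$energies[fb$i_up]
  frames <- lapply(fb$times, function(t) {
    dy_scale <- if (is.finite(spec$decay_tau_fs))
      exp(-t / (2 * spec$decay_tau_fs)) else 1
    rows <- lapply(seq_len(spec$n_tbf), function(i) {
      .tbf_row(model, id = i, parent_id = NA_integer_, family = i,
               surface = "upper", x = model$fc_offset, y = 0,
               px = 0, py = 0, width = 8, phase = 0,
               camp = complex(real = 1, imaginary = 0),
               norm_w = fb$w[i])
    })
    tb <- do.call(rbind, rows)
    ## linear anion-neutral gap drift: eKE(t) = eke0 - drift * t under
    ## the default hnu = 1.55 eV, delta = 2.0 eV
    tb$e_d0 <- e_occ - 0.45 - spec$eke0_ev + spec$drift_ev_fs * t
    ## uniform Dyson scaling keeps the classification labels unchanged
    for (f in c("dyson_1", "dyson_2", "dyson_3"))
      tb[[f]] <- tb[[f]] * dy_scale
    list(time_fs = t, tbfs = tb)
  })
  rec <- ensemble_record(model, frames, seed = spec$seed,
                         family_weights = fb$w, width_au = 8)
  validate_ensemble(rec)
  attr(rec, "truth") <- list(eke0_ev = spec$eke0_ev,
                             drift_ev_fs = spec$drift_ev_fs,
                             decay_tau_fs = spec$decay_tau_fs)
  rec
}
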