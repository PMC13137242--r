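## Run expr with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Harmonic mode frequency (au) of the model: omega = sqrt(k / m) with k
## converted to hartree/bohr^2 and the mass convention from the header.
.model_omega_au <- function(model) {
  k_au <- ev_to_hartree(model$k) * hbi_constants$bohr_angstrom^2
  sqrt(k_au / .hbi_mass_au())
}

#' Sample initial conditions from the ground-state Wigner distribution
#'
#' Draws positions and momenta from the Wigner quasi-probability of the
#' harmonic anion ground state of the model, centered on the
#' Franck-Condon reference point.  In mass-weighted coordinates
#' (effective mass 1 amu, recorded in trajectory headers) each mode of
#' frequency \eqn{\omega} gives \eqn{q \sim N(0, 1/(2\omega))} and
#' \eqn{p \sim N(0, \omega/2)} in atomic units, the exact ground-state
#' Wigner moments.  Draws are deterministic under a fixed seed and do
#' not disturb the caller's RNG stream.
#'
#' @param model A `diabatic_model`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A data frame of class `initial_conditions` with columns `x`,
#'   `y` (angstrom), `px`, `py` (au, mass-weighted) and `gap_ev`, the
#'   vertical energy gap from the anion ground state to the upper
#'   adiabat of the coupled pair at the sampled geometry.
#' @export
#' @examples
#' ics <- sample_wigner(build_model(), 5, seed = 1)
#' ics$gap_ev
sample_wigner <- function(model, n, seed) {
  stopifnot(inherits(model, "diabatic_model"))
  if (!is.numeric(n) || n < 1) stop("sample_wigner: n must be >= 1",
                                    call. = FALSE)
  n <- as.integer(n)
  m <- .hbi_mass_au()
  omega <- .model_omega_au(model)
  sd_x_bohr <- sqrt(1 / (2 * m * omega))
  sd_p <- sqrt(m * omega / 2)
  draws <- .with_seed(seed, {
    cbind(stats::rnorm(n, 0, sd_x_bohr), stats::rnorm(n, 0, sd_x_bohr),
          stats::rnorm(n, 0, sd_p), stats::rnorm(n, 0, sd_p))
  })
  x <- model$fc_offset + bohr_to_angstrom(draws[, 1])
  y <- bohr_to_angstrom(draws[, 2])
  gap <- vapply(seq_len(n), function(i) {
    pt <- evaluate_model(model, x[i], y[i])
    pt$energies[match("upper", pt$surface)] - pt$e_ground
  }, 0)
  out <- data.frame(x = x, y = y, px = draws[, 3], py = draws[, 4],
                    gap_ev = gap)
  class(out) <- c("initial_conditions", "data.frame")
  out
}

#' Filter sampled initial conditions by vertical energy gap
#'
#' Retains exactly those samples whose ground-to-upper-adiabat vertical
#' gap lies within `center +/- halfwidth`, preserving order.  This
#' mimics pumping slightly blue of the Franck-Condon absorption maximum
#' with a narrow pump bandwidth; the defaults used by the calibrated
#' pipeline are the pump-window values on the model's energy scale
#' (center 0.216 hartree in eV, halfwidth 0.0005 hartree in eV).
#'
#' @param samples An `initial_conditions` data frame from
#'   [sample_wigner()].
#' @param center Window center (eV).
#' @param halfwidth Window half-width (eV), > 0 (may be `Inf`).
#' @param model Optional `diabatic_model`; when supplied, gaps are
#'   recomputed from the model rather than trusted from `samples`.
#' @return The retained subsequence, with attribute `retention` giving
#'   the retained fraction.  A warning is raised when nothing survives.
#' @export
filter_energy_window <- function(samples, center = hartree_to_ev(0.216),
                                 halfwidth = hartree_to_ev(0.0005),
                                 model = NULL) {
  if (!is.numeric(halfwidth) || is.na(halfwidth) || halfwidth <= 0)
    stop("filter_energy_window: halfwidth must be > 0", call. = FALSE)
  gaps <- samples$gap_ev
  if (!is.null(model)) {
    gaps <- vapply(seq_len(nrow(samples)), function(i) {
      pt <- evaluate_model(model, samples$x[i], samples$y[i])
      pt$energies[match("upper", pt$surface)] - pt$e_ground
    }, 0)
  }
  keep <- gaps >= center - halfwidth & gaps <= center + halfwidth
  out <- samples[keep, , drop = FALSE]
  attr(out, "retention") <- mean(keep)
  if (nrow(out) == 0L)
    warning("filter_energy_window: no samples retained in [",
            center - halfwidth, ", ", center + halfwidth, "] eV")
  out
}

#' Build the t = 0 TBF ensemble from retained initial conditions
#'
#' The first `n_tbf` retained samples become frozen-Gaussian TBFs.  Each
#' occupies the upper adiabat of the coupled pair at its geometry — the
#' wavepacket is promoted to the pump-selected state, so TBFs sampled
#' where the shape/Feshbach ordering is reversed start with Feshbach
#' character (`initial_state = "max_f"` instead occupies whichever pair
#' adiabat carries the larger mixed oscillator strength).  Amplitude
#' magnitudes are proportional to the square root of the occupied
#' adiabat's oscillator strength and the ensemble is normalized so the
#' total population is exactly 1.  TBFs are mutually uncoupled: each is
#' the founder of its own spawning family (independent first-generation
#' approximation), carrying its squared amplitude as the family weight.
#'
#' @param retained `initial_conditions` rows surviving the gap filter.
#' @param model A `diabatic_model`.
#' @param n_tbf Number of TBFs (default 20).
#' @param seed Seed recorded in the output header.
#' @param width_au Frozen-Gaussian width alpha (bohr^-2); default is the
#'   coherent-state width of the model's harmonic modes,
#'   \eqn{m\omega/2}.
#' @param initial_state `"upper"` (default) or `"max_f"`; see above.
#' @return An `ensemble_record` with a single t = 0 frame.
#' @export
initialize_ensemble <- function(retained, model, n_tbf = 20,
                                seed = NA_integer_, width_au = NULL,
                                initial_state = c("upper", "max_f")) {
  stopifnot(inherits(model, "diabatic_model"))
  initial_state <- match.arg(initial_state)
  if (nrow(retained) < n_tbf)
    stop("initialize_ensemble: only ", nrow(retained),
         " retained sample(s) for n_tbf = ", n_tbf, call. = FALSE)
  if (is.null(width_au))
    width_au <- .hbi_mass_au() * .model_omega_au(model) / 2
  sel <- retained[seq_len(n_tbf), , drop = FALSE]

  surface <- character(n_tbf)
  fosc <- numeric(n_tbf)
  for (i in seq_len(n_tbf)) {
    pt <- evaluate_model(model, sel$x[i], sel$y[i])
    i_up <- match("upper", pt$surface)
    i_lo <- match("lower", pt$surface)
    surface[i] <- if (initial_state == "upper") "upper"
                  else if (pt$osc[i_up] >= pt$osc[i_lo]) "upper" else "lower"
    fosc[i] <- pt$osc[match(surface[i], pt$surface)]
  }
  w <- fosc / sum(fosc)          # family weights: |c|^2 proportional to f

  rows <- lapply(seq_len(n_tbf), function(i) {
    .tbf_row(model, id = i, parent_id = NA_integer_, family = i,
             surface = surface[i], x = sel$x[i], y = sel$y[i],
             px = sel$px[i], py = sel$py[i], width = width_au,
             phase = 0, camp = complex(real = 1, imaginary = 0),
             norm_w = w[i])
  })
  frame <- list(time_fs = 0, tbfs = do.call(rbind, rows))
  rec <- ensemble_record(model, list(frame), seed = seed,
                         family_weights = w, width_au = width_au)
  validate_ensemble(rec)
  rec
}
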