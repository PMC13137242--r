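#' Photoelectron kinetic energy of one ionization event
#'
#' \deqn{eKE = h\nu_{probe} - (E_{neut} - E_{anion} + \Delta)}
#' where \eqn{\Delta} is the energetic shift applied to the neutral
#' doublet state to align the simulated spectrum with experiment.  The
#' result may be negative; callers filter.
#'
#' @param e_neut Neutral D0 energy (eV).
#' @param e_anion Occupied anion-state energy (eV).
#' @param hnu_probe Probe photon energy (eV, default 1.55).
#' @param delta Neutral-state alignment shift (eV, default +2.0).
#' @return Electron kinetic energy (eV).
#' @export
#' @examples
#' eke(e_neut = 1.55, e_anion = 2.0)   # 0
eke <- function(e_neut, e_anion, hnu_probe = 1.55, delta = 2.0) {
  hnu_probe - (e_neut - e_anion + delta)
}

#' Raw (unconvolved) TRPES points from an ensemble record
#'
#' Projects the anionic wavepacket onto the neutral D0 state: one
#' spectrum point per live TBF per frame, at delay equal to the frame
#' time and eKE from [eke()] evaluated with the occupied anion adiabat
#' and the neutral D0 energy at the TBF centroid.  The weight is the
#' TBF's Mulliken norm times the occupied state's Dyson norm raised to
#' `dyson_power` (default 2, the sudden-approximation cross-section
#' proxy).  Points with eKE <= 0 are dropped with a reported count; each
#' point carries the character label of the occupied state.
#'
#' @param record An `ensemble_record` whose frames carry D0 energies and
#'   per-state Dyson norms.
#' @param hnu_probe,delta See [eke()].
#' @param dyson_power Power applied to the Dyson norm in the weight
#'   (1 or 2; default 2).
#' @return Data frame of class `spectrum_points` with columns
#'   `delay_fs`, `eke_ev`, `weight`, `character`; attribute `n_dropped`
#'   counts the eKE <= 0 points removed.
#' @export
raw_spectrum <- function(record, hnu_probe = 1.55, delta = 2.0,
                         dyson_power = 2) {
  validate_ensemble(record)
  if (!dyson_power %in% c(1, 2))
    stop("raw_spectrum: dyson_power must be 1 or 2", call. = FALSE)
  pts <- lapply(record$frames, function(fr) {
    tb <- fr$tbfs
    if (!nrow(tb)) return(NULL)
    if (any(!is.finite(tb$e_d0)))
      stop("raw_spectrum: frame at t = ", fr$time_fs,
           " fs: missing D0 energy", call. = FALSE)
    idx <- cbind(seq_len(nrow(tb)), tb$state_index)
    e_occ <- as.matrix(tb[, c("e_1", "e_2", "e_3")])[idx]
    d_occ <- as.matrix(tb[, c("dyson_1", "dyson_2", "dyson_3")])[idx]
    labs <- t(vapply(seq_len(nrow(tb)), function(i)
      classify_states(c(tb$osc_1[i], tb$osc_2[i], tb$osc_3[i]),
                      c(tb$dyson_1[i], tb$dyson_2[i], tb$dyson_3[i])),
      character(3)))
    data.frame(
      delay_fs = fr$time_fs,
      eke_ev = eke(tb$e_d0, e_occ, hnu_probe, delta),
      weight = pmax(tb$norm_w, 0) * d_occ^dyson_power,
      character = labs[idx],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pts)
  if (is.null(out))
    out <- data.frame(delay_fs = numeric(0), eke_ev = numeric(0),
                      weight = numeric(0), character = character(0))
  n_dropped <- sum(out$eke_ev <= 0)
  out <- out[out$eke_ev > 0, , drop = FALSE]
  if (n_dropped > 0)
    message("raw_spectrum: dropped ", n_dropped, " point(s) with eKE <= 0")
  if (!nrow(out))
    warning("raw_spectrum: empty spectrum (all points at eKE <= 0)")
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("spectrum_points", "data.frame")
  out
}

#' Convolve spectrum points onto a (delay, eKE) grid
#'
#' Deposits each point as a separable 2D Gaussian with the stated full
#' widths at half maximum (defaults 20 fs and 0.2 eV) using the analytic
#' normalization, so the grid integral equals the summed weights up to
#' grid-edge truncation; a truncation warning with a lost-mass estimate
#' is raised when the grid does not extend 3 standard deviations beyond
#' the point range.
#'
#' @param points A `spectrum_points` data frame (see [raw_spectrum()]).
#' @param delay_grid,eke_grid Strictly increasing grid vectors (fs, eV).
#'   Defaults: 0-50 fs in 1 fs steps, 2.0-3.5 eV in 0.02 eV steps.
#' @param fwhm_t,fwhm_e Convolution widths (fs, eV), > 0.
#' @return An object of class `trpes_spectrum`: list with `delay_fs`,
#'   `eke_ev`, `intensity` (matrix, delay x eKE), `layers` (`NULL` here;
#'   see [decompose_by_character()]) and `meta` (fwhms, total weight,
#'   edge loss fraction).
#' @export
convolve_spectrum <- function(points,
                              delay_grid = seq(0, 50, by = 1),
                              eke_grid = seq(2.0, 3.5, by = 0.02),
                              fwhm_t = 20, fwhm_e = 0.2) {
  if (any(diff(delay_grid) <= 0) || any(diff(eke_grid) <= 0))
    stop("convolve_spectrum: grids must be strictly increasing",
         call. = FALSE)
  if (fwhm_t <= 0 || fwhm_e <= 0)
    stop("convolve_spectrum: fwhm must be > 0", call. = FALSE)
  sig_t <- fwhm_t / (2 * sqrt(2 * log(2)))
  sig_e <- fwhm_e / (2 * sqrt(2 * log(2)))
  intensity <- matrix(0, length(delay_grid), length(eke_grid))
  total_w <- 0
  if (nrow(points)) {
    gt <- outer(delay_grid, points$delay_fs,
                function(g, d) stats::dnorm(g, d, sig_t))
    ## renormalize each temporal kernel to its mass inside the delay
    ## span: the span is the observation window and every point lies in
    ## it, so truncating kernels at its edges would bend flat signals
    ## downward near t = 0 and t = t_max.  (Energy-axis truncation, by
    ## contrast, is genuine loss: points may fall outside the eKE grid.)
    zin <- stats::pnorm(max(delay_grid), points$delay_fs, sig_t) -
           stats::pnorm(min(delay_grid), points$delay_fs, sig_t)
    gt <- sweep(gt, 2, pmax(zin, 1e-12), "/")
    ge <- outer(points$eke_ev, eke_grid,
                function(e, g) stats::dnorm(g, e, sig_e))
    intensity <- gt %*% (points$weight * ge)
    total_w <- sum(points$weight)
    rng_t <- range(points$delay_fs); rng_e <- range(points$eke_ev)
    if (min(delay_grid) > rng_t[1] - 3 * sig_t ||
        max(delay_grid) < rng_t[2] + 3 * sig_t ||
        min(eke_grid) > rng_e[1] - 3 * sig_e ||
        max(eke_grid) < rng_e[2] + 3 * sig_e) {
      cell <- mean(diff(delay_grid)) * mean(diff(eke_grid))
      lost <- 1 - sum(intensity) * cell / total_w
      warning(sprintf(paste0("convolve_spectrum: grid narrower than 3 sigma",
                             " beyond the point range; estimated lost mass",
                             " %.2f%%"), 100 * lost))
    }
  }
  cell <- mean(diff(delay_grid)) * mean(diff(eke_grid))
  out <- list(delay_fs = delay_grid, eke_ev = eke_grid,
              intensity = intensity, layers = NULL,
              meta = list(fwhm_t = fwhm_t, fwhm_e = fwhm_e,
                          total_weight = total_w,
                          edge_loss = if (total_w > 0)
                            1 - sum(intensity) * cell / total_w else 0))
  class(out) <- "trpes_spectrum"
  out
}

#' @export
print.trpes_spectrum <- function(x, ...) {
  cat(sprintf("TRPES spectrum: %d delays (%.1f..%.1f fs) x %d eKE (%.2f..%.2f eV)\n",
              length(x$delay_fs), min(x$delay_fs), max(x$delay_fs),
              length(x$eke_ev), min(x$eke_ev), max(x$eke_ev)))
  cat(sprintf("  fwhm %.1f fs x %.2f eV; total weight %.4g; edge loss %.2f%%\n",
              x$meta$fwhm_t, x$meta$fwhm_e, x$meta$total_weight,
              100 * x$meta$edge_loss))
  if (!is.null(x$layers))
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Decompose a spectrum into state-character layers
#'
#' Partitions the pre-convolution points by their character label and
#' convolves each subset onto the same grid, so the layers sum to the
#' total spectrum exactly.
#'
#' @inheritParams convolve_spectrum
#' @return A `trpes_spectrum` whose `layers` field is a named list of
#'   intensity matrices (one per character present, plus zeros for
#'   absent characters among bright/feshbach/shape).
#' @export
decompose_by_character <- function(points,
                                   delay_grid = seq(0, 50, by = 1),
                                   eke_grid = seq(2.0, 3.5, by = 0.02),
                                   fwhm_t = 20, fwhm_e = 0.2) {
  total <- convolve_spectrum(points, delay_grid, eke_grid, fwhm_t, fwhm_e)
  layers <- lapply(c(bright = "bright", feshbach = "feshbach",
                     shape = "shape"), function(ch) {
    sub <- points[points$character == ch, , drop = FALSE]
    suppressWarnings(
      convolve_spectrum(sub, delay_grid, eke_grid, fwhm_t, fwhm_e)$intensity)
  })
  total$layers <- layers
  total
}

#' Intensity-weighted mean eKE of raw spectrum points
#'
#' @param points A `spectrum_points` data frame.
#' @return Weighted mean eKE (eV); `NA` for an empty set.
#' @export
mean_eke <- function(points) {
  if (!nrow(points) || sum(points$weight) <= 0) return(NA_real_)
  sum(points$eke_ev * points$weight) / sum(points$weight)
}

## Exponentially modified Gaussian: unit-amplitude exponential decay
## exp(-t/tau) for t >= 0, convolved with a Gaussian of sd sigma.
.exp_gauss <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  ## evaluated in log space: the exp prefactor and the erfc tail cancel
  arg <- (sigma^2 / tau - t) / (sqrt(2) * sigma)
  exp(sigma^2 / (2 * tau^2) - t / tau +
        stats::pnorm(-arg * sqrt(2), log.p = TRUE))
}

#' Fit exponential decay constants of eKE windows
#'
#' Integrates the spectrum intensity over each eKE window as a function
#' of pump-probe delay and fits a single-exponential decay with plateau,
#' \eqn{I(t) = B + A f(t;\tau)}.  Because the spectrum carries a known
#' temporal instrument function, \eqn{f} is the unit exponential decay
#' convolved with the spectrum's stored Gaussian width (`meta$fwhm_t`),
#' so the fitted \eqn{\tau} is deconvolution-aware; with `fwhm_t = 0`
#' the bare exponential is used.  Windows whose fitted decay amplitude
#' is not positive (or whose fit fails) return the sentinel
#' `tau_fs = Inf` with `flag = "non-decaying"`.
#'
#' @param spectrum A `trpes_spectrum`, covering the windows with at
#'   least 5 delay points.
#' @param windows Named list of eKE intervals (eV), default the high
#'   (2.5-3.0 eV) and low (2.0-2.5 eV) windows.
#' @return Data frame with columns `window`, `eke_lo`, `eke_hi`,
#'   `tau_fs`, `tau_se` (approximate standard error; `NA` for
#'   sentinels) and `flag` (`"ok"` or `"non-decaying"`).  Attribute
#'   `tau_ordering_high_lt_low` reports whether the first window's tau
#'   is smaller than the second's.
#' @export
window_decays <- function(spectrum,
                          windows = list(high = c(2.5, 3.0),
                                         low = c(2.0, 2.5))) {
  stopifnot(inherits(spectrum, "trpes_spectrum"))
  t <- spectrum$delay_fs
  if (length(t) < 5)
    stop("window_decays: need >= 5 delay points", call. = FALSE)
  de <- mean(diff(spectrum$eke_ev))
  sigma <- spectrum$meta$fwhm_t / (2 * sqrt(2 * log(2)))
  ## Forward model: a unit exponential decay starting at t0, deposited
  ## through the same edge-renormalized temporal kernel that built the
  ## spectrum, so the fitted tau is deconvolution-aware and exact for
  ## kernel-deposited data.
  kmat <- if (sigma > 0) {
    g <- outer(t, t, function(a, b) stats::dnorm(a, b, sigma))
    zin <- stats::pnorm(max(t), t, sigma) - stats::pnorm(min(t), t, sigma)
    sweep(g, 2, pmax(zin, 1e-12), "/")
  } else diag(length(t))
  fwd <- function(tau, t0) {
    src <- ifelse(t >= t0, exp(-(t - t0) / tau), 0)
    v <- as.vector(kmat %*% src)
    v / max(v)
  }
  rows <- lapply(seq_along(windows), function(wi) {
    w <- windows[[wi]]
    cols <- which(spectrum$eke_ev >= w[1] & spectrum$eke_ev <= w[2])
    if (!length(cols))
      stop("window_decays: spectrum does not cover window [",
           w[1], ", ", w[2], "] eV", call. = FALSE)
    intens <- rowSums(spectrum$intensity[, cols, drop = FALSE]) * de
    i_peak <- which.max(intens)
    decaying <- i_peak <= ceiling(0.6 * length(t)) &&
      length(t) - i_peak + 1 >= 5
    span <- max(intens) - min(intens)
    fit <- NULL
    if (decaying && span > 1e-12 * max(abs(intens), 1e-300)) {
      df <- data.frame(t = t, i = intens)
      frac <- (intens - min(intens)) / span
      t_half <- t[which(frac < 0.5)[1]]
      tau0 <- if (is.na(t_half) || t_half <= 0)
        diff(range(t)) / 2 else t_half / log(2)
      ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
      ## stage 1: decay starting at zero delay
      fit <- tryCatch(
        minpack.lm::nlsLM(i ~ b + a * fwd(tau, 0),
                          data = df,
                          start = list(b = min(intens), a = span, tau = tau0),
                          lower = c(-Inf, -Inf, 0.1), control = ctrl),
        error = function(e) NULL)
      resid_ok <- function(f) !is.null(f) &&
        sqrt(mean(stats::resid(f)^2)) < 0.02 * span
      if (!resid_ok(fit)) {
        ## stage 2: free onset t0 — a window the signal sweeps into
        ## rises before it decays
        fit2 <- tryCatch(
          minpack.lm::nlsLM(i ~ b + a * fwd(tau, t0),
                            data = df,
                            start = list(b = min(intens), a = span,
                                         tau = tau0, t0 = t[i_peak] / 2),
                            lower = c(-Inf, -Inf, 0.1, min(t)),
                            upper = c(Inf, Inf, Inf, max(t)), control = ctrl),
          error = function(e) NULL)
        if (!is.null(fit2) &&
            (is.null(fit) ||
             sqrt(mean(stats::resid(fit2)^2)) <
               sqrt(mean(stats::resid(fit)^2))))
          fit <- fit2
      }
    }
    ok <- !is.null(fit) && stats::coef(fit)[["a"]] > 0 &&
      stats::coef(fit)[["tau"]] < 10 * diff(range(t))
    if (ok) {
      cf <- stats::coef(fit)
      se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                     error = function(e) NA_real_)
      data.frame(window = names(windows)[wi], eke_lo = w[1], eke_hi = w[2],
                 tau_fs = cf[["tau"]], tau_se = se, flag = "ok",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(window = names(windows)[wi], eke_lo = w[1], eke_hi = w[2],
                 tau_fs = Inf, tau_se = NA_real_, flag = "non-decaying",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2)
    attr(out, "tau_ordering_high_lt_low") <- out$tau_fs[1] < out$tau_fs[2]
  out
}

#' Read and write spectrum files
#'
#' Rectangular-grid JSON container: axes (`delay_fs`, `eke_ev`),
#' intensity matrix, optional character-tagged layers, metadata.
#'
#' @param spectrum A `trpes_spectrum`.
#' @param path File path.
#' @return `read_spectrum()` returns a `trpes_spectrum`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "trpes_spectrum"))
  obj <- unclass(spectrum)
  obj$format_version <- "1.0"
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop("read_spectrum: no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format_version, "1.0"))
    stop("read_spectrum: unsupported format_version", call. = FALSE)
  out <- list(delay_fs = obj$delay_fs, eke_ev = obj$eke_ev,
              intensity = obj$intensity,
              layers = if (!is.null(obj$layers))
                lapply(obj$layers, as.matrix) else NULL,
              meta = obj$meta)
  class(out) <- "trpes_spectrum"
  out
}
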