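#' Default diabat electronic properties
#'
#' Oscillator strengths (au) and Dyson norms for the three lowest excited
#' states of the HBI anion: the bright pi-pi* state, the Feshbach
#' resonance and the shape resonance.  These are the fixed per-diabat
#' properties carried by every model unless overridden.
#'
#' @return A data frame with columns `diabat`, `osc`, `dyson`.
#' @export
#' @examples
#' default_state_properties()
default_state_properties <- function() {
  data.frame(
    diabat = c("bright", "feshbach", "shape"),
    osc    = c(1.540, 0.0874, 0.195),
    dyson  = c(0.721, 0.345, 0.607),
    stringsAsFactors = FALSE
  )
}

## Tiny deterministic polynomial rolling hash of a character scalar
## (model fingerprint for trajectory headers; no cryptographic intent).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h1 <- 17; h2 <- 257
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

.model_hash <- function(m) {
  keys <- c("k", "e_s", "e_f", "e_b", "e_d0", "a_s", "a_f", "a_d0", "c",
            "fc_offset", "delta_ev")
  s <- paste(sprintf("%s=%.12g", keys, unlist(m[keys])), collapse = ";")
  s <- paste0(s, ";props=",
              paste(sprintf("%.6g", unlist(m$props[, c("osc", "dyson")])),
                    collapse = ","))
  .fnv1a(s)
}

#' Build and validate a two-coordinate diabatic vibronic model
#'
#' The model spans the branching plane of the shape/Feshbach conical
#' intersection of the HBI anion: a gradient-difference coordinate `x`
#' and a coupling coordinate `y`, both in angstrom relative to the
#' Franck-Condon (FC) reference at `x = fc_offset`, `y = 0`.  Writing
#' `u = x - fc_offset`, the diabatic surfaces (eV) are
#' \deqn{V_i(u, y) = E_i + a_i u + (k/2)(u^2 + y^2)}
#' for the shape, Feshbach, bright and neutral-D0 diabats (the bright
#' state carries no slope), the anion ground state is
#' \eqn{V_0 = (k/2)(u^2 + y^2)}, and the shape/Feshbach diabatic
#' coupling is linear in the coupling coordinate, \eqn{W = c\,y} — the
#' lowest-order realization of a peaked, Mexican-hat-type intersection.
#'
#' @param params Named list of model parameters.  Recognised fields (with
#'   defaults): `k` (14 eV/A^2, shared harmonic force constant), `e_s`,
#'   `e_f`, `e_b`, `e_d0` (diabat energies at the FC point, eV), `a_s`,
#'   `a_f`, `a_d0` (linear slopes along `x`, eV/A), `c` (diabatic coupling
#'   slope along `y`, eV/A), `fc_offset` (FC displacement along `x`, A,
#'   default 0.05), `delta_ev` (energetic shift applied to the neutral D0
#'   state when reporting experiment-aligned gaps and photoelectron
#'   energies, default 2.0 eV), `props` (per-diabat oscillator strengths
#'   and Dyson norms; defaults to [default_state_properties()]).
#' @return An object of class `diabatic_model`.
#' @seealso [calibrate_from_energies()] for building the model from the
#'   published gap constraints, [evaluate_model()] for adiabatic surfaces.
#' @export
#' @examples
#' m <- build_model(list(e_s = 5.9, e_f = 5.7, a_s = 4.3, a_f = -4.3))
#' m$k
build_model <- function(params = list()) {
  defaults <- list(
    k = 14, e_s = 5.8777, e_f = 5.6777, e_b = 4.3777, e_d0 = 2.3477,
    a_s = 4.2988, a_f = -4.2988, a_d0 = 1.7586, c = 2.0,
    fc_offset = 0.05, delta_ev = 2.0,
    props = default_state_properties()
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("build_model: unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- utils::modifyList(defaults, params)

  num <- c("k", "e_s", "e_f", "e_b", "e_d0", "a_s", "a_f", "a_d0", "c",
           "fc_offset", "delta_ev")
  for (f in num) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || !is.finite(m[[f]]))
      stop("build_model: field '", f, "' must be a finite scalar",
           call. = FALSE)
  }
  if (m$k <= 0)
    stop("build_model: field 'k' must be > 0", call. = FALSE)
  if (m$c == 0)
    stop("build_model: field 'c' must be nonzero (coupled pair required)",
         call. = FALSE)
  p <- m$props
  if (!is.data.frame(p) ||
      !all(c("diabat", "osc", "dyson") %in% names(p)) ||
      !setequal(p$diabat, c("bright", "feshbach", "shape")))
    stop("build_model: field 'props' must tabulate osc/dyson for ",
         "bright, feshbach and shape", call. = FALSE)
  if (any(p$osc < 0) || any(p$dyson < 0))
    stop("build_model: field 'props' must be nonnegative", call. = FALSE)
  m$props <- p[match(c("bright", "feshbach", "shape"), p$diabat), ]
  rownames(m$props) <- m$props$diabat
  if (m$e_s < m$e_f)
    stop("build_model: field 'e_s' must not be below 'e_f' ",
         "(shape above Feshbach at the FC point)", call. = FALSE)
  m$hash <- .model_hash(m)
  class(m) <- "diabatic_model"
  m
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat("Two-coordinate diabatic vibronic model (branching plane)\n")
  cat(sprintf("  k = %g eV/A^2, coupling c = %g eV/A, FC offset = %g A\n",
              x$k, x$c, x$fc_offset))
  cat(sprintf("  diabats at FC (eV): shape %.4f, feshbach %.4f, bright %.4f, D0 %.4f\n",
              x$e_s, x$e_f, x$e_b, x$e_d0))
  cat(sprintf("  slopes (eV/A): a_s %.4f, a_f %.4f, a_D0 %.4f; D0 shift %.2f eV\n",
              x$a_s, x$a_f, x$a_d0, x$delta_ev))
  cat(sprintf("  model hash: %s\n", x$hash))
  invisible(x)
}

## Diabatic surfaces and derivatives at (x, y) in model units (eV, A).
## Returns the pieces needed by both the public evaluator and the
## propagator; vectorized over x/y.
.diabats <- function(model, x, y) {
  u  <- x - model$fc_offset
  h  <- 0.5 * model$k * (u^2 + y^2)
  vs <- model$e_s + model$a_s * u + h
  vf <- model$e_f + model$a_f * u + h
  list(
    u = u, h = h,
    v0 = h,
    vs = vs, vf = vf,
    vb = model$e_b + h,
    vd0 = model$e_d0 + model$a_d0 * u + h,
    w = model$c * y,
    delta = 0.5 * (vs - vf),
    ddelta_dx = 0.5 * (model$a_s - model$a_f),
    dw_dy = model$c,
    dmean_dx = 0.5 * (model$a_s + model$a_f) + model$k * u,
    dmean_dy = model$k * y
  )
}

#' Evaluate the model at a geometry
#'
#' Diagonalizes the 2x2 shape/Feshbach diabatic block analytically and
#' assembles the full electronic point: adiabatic energies (sorted
#' ascending together with the spectator bright state), mixing angle,
#' per-adiabat gradients, the nonadiabatic coupling (NAC) vector of the
#' coupled pair, population-mixed oscillator strengths and Dyson norms,
#' and the neutral D0 energy.
#'
#' With \eqn{\Delta} half the shape-Feshbach diabat difference and
#' \eqn{W = c y} the coupling, the pair adiabats are
#' \eqn{M \pm \sqrt{\Delta^2 + W^2}}, the mixing angle is
#' \eqn{\theta = \tfrac12 \mathrm{atan2}(2W, V_f - V_s)} and the NAC
#' vector is \eqn{d = (W \nabla\Delta - \Delta \nabla W)/(2(\Delta^2+W^2))},
#' which diverges as 1/gap at the intersection.  Adiabatic properties are
#' population-weighted mixtures of the diabatic ones,
#' \eqn{p^{adia}_j = \sum_i |U_{ij}|^2 p^{dia}_i}, so their pairwise sums
#' are conserved at every geometry.
#'
#' @param model A `diabatic_model`.
#' @param x,y Geometry in angstrom (scalars).
#' @return An object of class `electronic_point` with fields `x`, `y`,
#'   `energies` (ascending, eV), `surface` (labels `"bright"`, `"lower"`,
#'   `"upper"` aligned with `energies`), `osc`, `dyson` (mixed properties
#'   aligned with `energies`), `theta` (rad), `gap` (pair gap, eV),
#'   `gradients` (3x2 matrix, eV/A, rows aligned with `energies`), `nac`
#'   (length-2 vector, 1/A), `nac_singular` (logical), `e_d0` (eV),
#'   `e_ground` (anion ground state, eV), and `w_shape` (named weights of
#'   the shape diabat in the lower/upper adiabats).
#' @export
#' @examples
#' m <- build_model()
#' pt <- evaluate_model(m, m$fc_offset, 0)
#' pt$energies
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "diabatic_model"))
  if (!is.finite(x) || !is.finite(y))
    stop("evaluate_model: geometry must be finite", call. = FALSE)
  d <- .diabats(model, x, y)
  mean_e <- 0.5 * (d$vs + d$vf)
  r <- sqrt(d$delta^2 + d$w^2)
  e_lower <- mean_e - r
  e_upper <- mean_e + r
  theta <- 0.5 * atan2(2 * d$w, d$vf - d$vs)

  singular <- (2 * r) < 1e-12
  if (singular) {
    w_upper_s <- 0.5
    nac <- c(NA_real_, NA_real_)
  } else {
    ## |<shape|upper>|^2 = (r + Delta) / (2 r)
    w_upper_s <- (r + d$delta) / (2 * r)
    nac <- c(d$w * d$ddelta_dx, -d$delta * d$dw_dy) / (2 * r^2)
  }
  w_lower_s <- 1 - w_upper_s

  p <- model$props
  osc_pair   <- c(lower = w_lower_s * p["shape", "osc"] + w_upper_s * p["feshbach", "osc"],
                  upper = w_upper_s * p["shape", "osc"] + w_lower_s * p["feshbach", "osc"])
  dyson_pair <- c(lower = w_lower_s * p["shape", "dyson"] + w_upper_s * p["feshbach", "dyson"],
                  upper = w_upper_s * p["shape", "dyson"] + w_lower_s * p["feshbach", "dyson"])

  ## Gradients: mean +/- grad(r); bright is purely harmonic.
  if (singular) {
    dr <- c(NA_real_, NA_real_)
  } else {
    dr <- c(d$delta * d$ddelta_dx, d$w * d$dw_dy) / r
  }
  g_lower  <- c(d$dmean_dx, d$dmean_dy) - dr
  g_upper  <- c(d$dmean_dx, d$dmean_dy) + dr
  g_bright <- c(model$k * d$u, model$k * y)

  energies <- c(bright = d$vb, lower = e_lower, upper = e_upper)
  grads <- rbind(bright = g_bright, lower = g_lower, upper = g_upper)
  osc   <- c(bright = p["bright", "osc"], osc_pair)
  dyson <- c(bright = p["bright", "dyson"], dyson_pair)

  ord <- order(energies)
  pt <- list(
    x = x, y = y,
    energies = unname(energies[ord]),
    surface  = names(energies)[ord],
    osc      = unname(osc[ord]),
    dyson    = unname(dyson[ord]),
    theta    = theta,
    gap      = 2 * r,
    gradients = grads[ord, , drop = FALSE],
    nac      = nac,
    nac_singular = singular,
    e_d0     = d$vd0,
    e_ground = d$v0,
    w_shape  = c(lower = unname(w_lower_s), upper = unname(w_upper_s))
  )
  class(pt) <- "electronic_point"
  pt
}

#' @export
print.electronic_point <- function(x, ...) {
  cat(sprintf("Electronic point at (%.4f, %.4f) A\n", x$x, x$y))
  df <- data.frame(surface = x$surface, energy_ev = x$energies,
                   osc = x$osc, dyson = x$dyson)
  print(df, row.names = FALSE)
  cat(sprintf("  pair gap %.6f eV, theta %.4f rad, D0 %.4f eV\n",
              x$gap, x$theta, x$e_d0))
  invisible(x)
}

#' Calibrate the model from published energy gaps
#'
#' Solves the closed-form linear-vibronic-coupling relations that tie the
#' model parameters to the energy differences quoted in the source
#' analysis of HBI's critical points: the shape-Feshbach vertical gap at
#' the Franck-Condon (FC) point, the shape reorganization energy (FC
#' vertical shape energy minus the shape-minimum energy), and the
#' experiment-aligned shape-to-D0 gaps at the FC point and at the shape
#' minimum.  The shape slope follows from the reorganization energy,
#' \eqn{a_s = \sqrt{2 k \lambda}}, placing the shape-diabat minimum at
#' \eqn{x^* = \mathrm{fc\_offset} - a_s/k}; the D0 slope is then fixed by
#' the gap at \eqn{x^*} and the D0 origin by the FC gap.  Re-evaluating
#' the returned model reproduces every constraint to better than 1e-9 eV.
#'
#' @param constraints Named list. Fields (defaults in parentheses):
#'   `gap_sf_fc` shape-Feshbach gap at FC (0.2 eV); `gap_sd0_fc`
#'   shape-D0 gap at FC on the shifted scale (1.53 eV); `gap_sd0_min`
#'   shape-D0 gap at the shape minimum (0.75 eV); `reorg` shape
#'   reorganization energy (0.66 eV); `e_vert_fc` absolute FC vertical
#'   shape energy above the anion ground state (0.216 hartree in eV);
#'   `k` force-constant convention (14 eV/A^2); `fc_offset` (0.05 A);
#'   `c` coupling slope convention (2 eV/A); `delta_ev` D0 alignment
#'   shift (2.0 eV); `e_b_below` bright-state offset below the Feshbach
#'   diabat at FC (1.3 eV).
#' @return A calibrated `diabatic_model`.
#' @export
#' @examples
#' m <- calibrate_from_energies()
#' evaluate_model(m, m$fc_offset, 0)$gap   # = gap_sf_fc
calibrate_from_energies <- function(constraints = list()) {
  defaults <- list(
    gap_sf_fc = 0.2, gap_sd0_fc = 1.53, gap_sd0_min = 0.75,
    reorg = 0.66, e_vert_fc = hartree_to_ev(0.216),
    k = 14, fc_offset = 0.05, c = 2.0, delta_ev = 2.0, e_b_below = 1.3
  )
  unknown <- setdiff(names(constraints), names(defaults))
  if (length(unknown))
    stop("calibrate_from_energies: unknown constraint(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cs <- utils::modifyList(defaults, constraints)
  if (cs$k <= 0)
    stop("calibrate_from_energies: infeasible constraint 'k' ",
         "(need k > 0 in a_s = sqrt(2 k reorg))", call. = FALSE)
  if (cs$reorg < 0)
    stop("calibrate_from_energies: infeasible constraint 'reorg' ",
         "(need reorg >= 0 in a_s = sqrt(2 k reorg))", call. = FALSE)
  if (cs$gap_sf_fc <= 0)
    stop("calibrate_from_energies: infeasible constraint 'gap_sf_fc' ",
         "(shape must lie above Feshbach at FC)", call. = FALSE)

  a_s <- sqrt(2 * cs$k * cs$reorg)
  e_s <- cs$e_vert_fc
  e_f <- e_s - cs$gap_sf_fc
  e_d0 <- e_s - cs$gap_sd0_fc - cs$delta_ev
  u_star <- -a_s / cs$k
  if (cs$reorg == 0) {
    ## Degenerate case: flat shape displacement; D0 slope unconstrained
    ## by the minimum gap (same point as FC) — require consistency.
    if (abs(cs$gap_sd0_min - cs$gap_sd0_fc) > 1e-12)
      stop("calibrate_from_energies: infeasible constraints ",
           "'gap_sd0_min' vs 'gap_sd0_fc' (zero reorganization makes ",
           "the FC point and the minimum coincide)", call. = FALSE)
    a_d0 <- 0
  } else {
    a_d0 <- (cs$gap_sd0_fc - 2 * cs$reorg - cs$gap_sd0_min) / u_star
  }
  build_model(list(
    k = cs$k, c = cs$c, fc_offset = cs$fc_offset, delta_ev = cs$delta_ev,
    e_s = e_s, e_f = e_f, e_b = e_f - cs$e_b_below, e_d0 = e_d0,
    a_s = a_s, a_f = -a_s, a_d0 = a_d0
  ))
}

#' Symmetric Jahn-Teller test model
#'
#' The symmetric limit of the branching-plane model: degenerate diabats
#' at the origin with opposite slopes \eqn{\pm\lambda} along `x` and
#' coupling slope \eqn{\lambda} along `y`, giving the textbook Mexican
#' hat: adiabats \eqn{E_0 + k r^2/2 \pm \lambda r}, a conical
#' intersection at the origin and a degenerate lower-sheet minimum ring
#' of radius \eqn{\lambda/k} at depth \eqn{\lambda^2/(2k)} below the
#' intersection.  Used throughout the test suite as the closed-form
#' reference.
#'
#' @param lambda Jahn-Teller slope (eV/A).
#' @param k Force constant (eV/A^2).
#' @param e0 Diabat energy at the intersection (eV).
#' @return A `diabatic_model` with `fc_offset = 0`.
#' @export
#' @examples
#' m <- jt_model()
#' evaluate_model(m, 0, 0)$gap   # 0 at the intersection
jt_model <- function(lambda = 2, k = 14, e0 = 5) {
  build_model(list(
    k = k, c = lambda, fc_offset = 0,
    e_s = e0, e_f = e0, e_b = e0 - 1.5, e_d0 = e0 - 3.5,
    a_s = lambda, a_f = -lambda, a_d0 = 0
  ))
}

#' Serialize / parse a model as a plain-text config block
#'
#' Versioned key/value representation embedded in trajectory headers.
#'
#' @param model A `diabatic_model`.
#' @param text Character vector of `key = value` lines.
#' @return `model_to_text()` returns a character vector;
#'   `model_from_text()` returns a `diabatic_model`.
#' @export
#' @examples
#' txt <- model_to_text(build_model())
#' m2 <- model_from_text(txt)
model_to_text <- function(model) {
  stopifnot(inherits(model, "diabatic_model"))
  num <- c("k", "e_s", "e_f", "e_b", "e_d0", "a_s", "a_f", "a_d0", "c",
           "fc_offset", "delta_ev")
  c("model_format = 1",
    sprintf("%s = %.17g", num, unlist(model[num])),
    sprintf("props_%s = %.17g %.17g", model$props$diabat,
            model$props$osc, model$props$dyson),
    sprintf("hash = %s", model$hash))
}

#' @rdname model_to_text
#' @export
model_from_text <- function(text) {
  kv <- strsplit(text, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  if (!identical(vals[keys == "model_format"], "1"))
    stop("model_from_text: unsupported model_format", call. = FALSE)
  num <- c("k", "e_s", "e_f", "e_b", "e_d0", "a_s", "a_f", "a_d0", "c",
           "fc_offset", "delta_ev")
  params <- as.list(as.numeric(vals[match(num, keys)]))
  names(params) <- num
  pr <- do.call(rbind, lapply(c("bright", "feshbach", "shape"), function(s) {
    v <- as.numeric(strsplit(vals[keys == paste0("props_", s)], "\\s+")[[1]])
    data.frame(diabat = s, osc = v[1], dyson = v[2],
               stringsAsFactors = FALSE)
  }))
  params$props <- pr
  m <- build_model(params)
  stored <- vals[keys == "hash"]
  if (length(stored) == 1L && !identical(stored, m$hash))
    warning("model_from_text: stored hash does not match recomputed hash")
  m
}
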