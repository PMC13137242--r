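## Objective/gradient of one selected surface.  `selector` is either an
## adiabatic index (1..3, ascending energy) or a character label
## ("bright", "feshbach", "shape"); character selection re-classifies the
## three states at every iterate (character tracking).
.surface_objective <- function(model, selector) {
  if (is.character(selector) &&
      selector %in% c("bright", "feshbach", "shape")) {
    function(z) {
      pt <- evaluate_model(model, z[1], z[2])
      labs <- classify_states(pt$osc, pt$dyson)
      k <- match(selector, labs)
      list(value = pt$energies[k], grad = pt$gradients[k, ])
    }
  } else if (is.numeric(selector) && selector %in% 1:3) {
    function(z) {
      pt <- evaluate_model(model, z[1], z[2])
      list(value = pt$energies[selector], grad = pt$gradients[selector, ])
    }
  } else stop("minimize_surface: selector must be a state index 1..3 or ",
              "one of 'bright', 'feshbach', 'shape'", call. = FALSE)
}

#' Locate a minimum on one surface
#'
#' Local minimization of the selected adiabat (by ascending-energy index)
#' or of the character-tracked surface (by label: at every iterate the
#' three states are re-classified and the one carrying the requested
#' character is followed — this is how the shape-character S2 minimum is
#' located from the Franck-Condon point, where the shape state is still
#' the upper adiabat).  BFGS with analytic gradients, polished until the
#' gradient norm is at most `tol_grad`.
#'
#' @param model A `diabatic_model`.
#' @param selector State index (1..3) or character label.
#' @param start Length-2 start geometry (angstrom); default the FC point.
#' @param tol_grad Gradient-norm tolerance (eV/A, default 1e-6).
#' @param max_restarts BFGS restarts before giving up.
#' @return An object of class `critical_point`: list with `x`, `y`,
#'   `type = "minimum"`, `energies` (ascending, eV), `energy` (of the
#'   tracked surface), `character` (label of the tracked state at the
#'   solution), `surface` (its adiabatic label), `grad_norm`,
#'   `curvature_ok` (positive-definite numerical Hessian).
#' @export
#' @examples
#' m <- calibrate_from_energies()
#' cp <- minimize_surface(m, "shape", c(m$fc_offset, 0))
#' cp$energy
minimize_surface <- function(model, selector, start = NULL,
                             tol_grad = 1e-6, max_restarts = 5) {
  stopifnot(inherits(model, "diabatic_model"))
  if (is.null(start)) start <- c(model$fc_offset, 0)
  if (any(!is.finite(start)))
    stop("minimize_surface: start must be finite", call. = FALSE)
  obj <- .surface_objective(model, selector)
  z <- start
  for (r in seq_len(max_restarts)) {
    res <- stats::optim(z, fn = function(z) obj(z)$value,
                        gr = function(z) obj(z)$grad, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    z <- res$par
    if (sqrt(sum(obj(z)$grad^2)) <= tol_grad) break
  }
  o <- obj(z)
  gnorm <- sqrt(sum(o$grad^2))
  if (gnorm > tol_grad)
    stop("minimize_surface: no convergence (gradient norm ",
         format(gnorm), " eV/A at x = ", format(z[1]), ", y = ",
         format(z[2]), ")", call. = FALSE)
  ## numerical curvature check on the tracked surface
  h <- 1e-4
  hess <- matrix(0, 2, 2)
  for (d in 1:2) {
    e <- c(0, 0); e[d] <- h
    hess[, d] <- (obj(z + e)$grad - obj(z - e)$grad) / (2 * h)
  }
  hess <- (hess + t(hess)) / 2
  pt <- evaluate_model(model, z[1], z[2])
  labs <- classify_states(pt$osc, pt$dyson)
  k <- if (is.character(selector)) match(selector, labs) else selector
  out <- list(x = z[1], y = z[2], type = "minimum",
              energies = pt$energies, energy = pt$energies[k],
              character = labs[k], surface = pt$surface[k],
              grad_norm = gnorm,
              ## semidefinite tolerance: a degenerate minimum ring (the
              ## symmetric JT limit) has an exactly flat direction
              curvature_ok = all(eigen(hess, symmetric = TRUE,
                                       only.values = TRUE)$values > -1e-6))
  class(out) <- "critical_point"
  out
}

#' Locate the minimal-energy conical intersection of the coupled pair
#'
#' Minimizes the pair mean energy subject to zero gap by an increasing
#' quadratic-penalty sequence on the squared gap,
#' \eqn{F_\sigma = \bar E + \sigma\, \mathrm{gap}^2}.  For this model
#' both terms are exactly quadratic in the geometry, so each penalty
#' subproblem is solved by one Newton step; \eqn{\sigma} is increased
#' until the gap falls below `tol_gap` and the projected mean-energy
#' gradient below `tol_grad`.
#'
#' @param model A `diabatic_model`.
#' @param start Length-2 start geometry (angstrom); default the FC point.
#' @param tol_gap Gap tolerance at the solution (eV, default 1e-5).
#' @param tol_grad Projected mean-gradient tolerance (eV/A, default 1e-5).
#' @return A `critical_point` with `type = "meci"`, the geometry, the
#'   three state energies, the residual `gap`, and `grad_norm` (the
#'   projected mean-energy gradient norm).
#' @export
#' @examples
#' find_meci(jt_model())$x   # the symmetric intersection sits at the origin
find_meci <- function(model, start = NULL, tol_gap = 1e-5,
                      tol_grad = 1e-5) {
  stopifnot(inherits(model, "diabatic_model"))
  if (is.null(start)) start <- c(model$fc_offset, 0)
  z <- start
  k <- model$k
  da <- 0.5 * (model$a_s - model$a_f)
  de <- 0.5 * (model$e_s - model$e_f)
  sa <- 0.5 * (model$a_s + model$a_f)
  pieces <- function(z) {
    u <- z[1] - model$fc_offset
    delta <- de + da * u
    w <- model$c * z[2]
    list(delta = delta, w = w,
         gmean = c(sa + k * u, k * z[2]),
         ggap2 = 8 * c(delta * da, w * model$c))
  }
  sigma <- 1
  done <- FALSE
  for (iter in 1:60) {
    p <- pieces(z)
    grad <- p$gmean + sigma * p$ggap2
    hess <- diag(k, 2) + 8 * sigma * (outer(c(da, 0), c(da, 0)) +
                                        outer(c(0, model$c), c(0, model$c)))
    z <- z - solve(hess, grad)
    p <- pieces(z)
    gap <- 2 * sqrt(p$delta^2 + p$w^2)
    ## projected mean gradient: remove the component along the gap^2
    ## gradient (the direction constrained by the penalty)
    gg <- p$ggap2
    gproj <- if (sum(gg^2) > 1e-30)
      p$gmean - sum(p$gmean * gg) / sum(gg^2) * gg else p$gmean
    if (gap <= tol_gap && sqrt(sum(gproj^2)) <= tol_grad) { done <- TRUE; break }
    sigma <- sigma * 10
    if (!is.finite(sigma) || sigma > 1e30)
      stop("find_meci: penalty divergence (gap ", format(gap),
           " eV at sigma = ", format(sigma), ")", call. = FALSE)
  }
  if (!done)
    stop("find_meci: penalty sequence did not converge", call. = FALSE)
  pt <- evaluate_model(model, z[1], z[2])
  out <- list(x = z[1], y = z[2], type = "meci",
              energies = pt$energies, energy = mean(pt$energies[2:3]),
              character = NA_character_, surface = "pair",
              gap = pt$gap, grad_norm = sqrt(sum(gproj^2)))
  class(out) <- "critical_point"
  out
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("Critical point (%s) at (%.6f, %.6f) A\n", x$type, x$x, x$y))
  cat(sprintf("  energies (eV): %s\n",
              paste(sprintf("%.6f", x$energies), collapse = ", ")))
  if (x$type == "minimum")
    cat(sprintf("  tracked: %s (%s), grad norm %.2e eV/A, curvature ok: %s\n",
                x$character, x$surface, x$grad_norm, x$curvature_ok))
  else
    cat(sprintf("  gap %.2e eV, projected grad %.2e eV/A\n",
                x$gap, x$grad_norm))
  invisible(x)
}

#' Scan the branching plane around a center point
#'
#' Rectangular grid of the adiabatic energies (the Mexican-hat figure:
#' the peaked intersection sits at the upper-sheet minimum, with the
#' lower sheet forming the surrounding ring).
#'
#' @param model A `diabatic_model`.
#' @param center Length-2 center (angstrom); default the MECI.
#' @param extents Half-widths of the scan along x and y (angstrom).
#' @param n_grid Points per axis (>= 3).
#' @return List of class `branching_scan`: `x`, `y` (axis vectors),
#'   `lower`, `upper`, `bright` (energy matrices, x by y, eV) and
#'   `center`.
#' @export
branching_scan <- function(model, center = NULL, extents = c(0.4, 0.4),
                           n_grid = 61) {
  stopifnot(inherits(model, "diabatic_model"))
  if (n_grid < 3) stop("branching_scan: n_grid must be >= 3", call. = FALSE)
  if (is.null(center)) {
    mc <- find_meci(model)
    center <- c(mc$x, mc$y)
  }
  xs <- seq(center[1] - extents[1], center[1] + extents[1], length.out = n_grid)
  ys <- seq(center[2] - extents[2], center[2] + extents[2], length.out = n_grid)
  lower <- upper <- bright <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      pt <- evaluate_model(model, xs[i], ys[j])
      lower[i, j]  <- pt$energies[match("lower", pt$surface)]
      upper[i, j]  <- pt$energies[match("upper", pt$surface)]
      bright[i, j] <- pt$energies[match("bright", pt$surface)]
    }
  }
  out <- list(x = xs, y = ys, lower = lower, upper = upper,
              bright = bright, center = center)
  class(out) <- "branching_scan"
  out
}

#' Energy-gap bookkeeping at critical points
#'
#' For each supplied point, evaluates the shape- and Feshbach-character
#' state energies and the neutral D0 energy at that geometry and reports
#' the experiment-aligned shape-to-D0 gap (D0 shifted by the model's
#' `delta_ev`) and the shape-to-Feshbach gap.
#'
#' @param model A `diabatic_model`.
#' @param points List of `critical_point` objects (or lists with `x`,
#'   `y`).
#' @return Data frame with one row per point: `x`, `y`, `type`,
#'   `e_shape`, `e_feshbach`, `e_d0_shifted` (all eV),
#'   `gap_shape_d0`, `gap_shape_feshbach` (eV).
#' @export
gap_report <- function(model, points) {
  stopifnot(inherits(model, "diabatic_model"))
  if (inherits(points, "critical_point")) points <- list(points)
  rows <- lapply(points, function(p) {
    pt <- evaluate_model(model, p$x, p$y)
    labs <- classify_states(pt$osc, pt$dyson)
    e_shape <- pt$energies[match("shape", labs)]
    e_fesh <- pt$energies[match("feshbach", labs)]
    e_d0s <- pt$e_d0 + model$delta_ev
    data.frame(x = p$x, y = p$y,
               type = if (!is.null(p$type)) p$type else NA_character_,
               e_shape = e_shape, e_feshbach = e_fesh,
               e_d0_shifted = e_d0s,
               gap_shape_d0 = e_shape - e_d0s,
               gap_shape_feshbach = e_shape - e_fesh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Winding of the mixing angle around a loop
#'
#' Accumulates the (half-period-wrapped) increments of the 2x2 mixing
#' angle along a closed circle; a loop enclosing the conical
#' intersection returns (+/-) pi — the geometric-phase signature — and a
#' loop that does not encloses it returns 0.
#'
#' @param model A `diabatic_model`.
#' @param center Length-2 loop center (angstrom).
#' @param radius Loop radius (angstrom).
#' @param n Number of quadrature points (default 3600).
#' @return Accumulated winding (rad).
#' @export
mixing_angle_winding <- function(model, center, radius, n = 3600) {
  phis <- seq(0, 2 * pi, length.out = n + 1)
  thetas <- vapply(phis, function(phi)
    evaluate_model(model, center[1] + radius * cos(phi),
                   center[2] + radius * sin(phi))$theta, 0)
  d <- diff(thetas)
  ## theta is defined modulo pi: wrap increments into (-pi/2, pi/2]
  d <- d - pi * round(d / pi)
  sum(d)
}
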