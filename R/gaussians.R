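## Frozen-Gaussian matrix elements (internal).
##
## A trajectory basis function (TBF) in 2D is the product of 1D frozen
## Gaussians with common width alpha (bohr^-2),
##   g(x) = (2a/pi)^(1/4) exp(-a (x - xc)^2 + i pc (x - xc)) * exp(i gamma)
## with centroid (xc, pc) in atomic units and semiclassical phase gamma
## (action integral of T - V).  All closed forms below are standard
## coherent-state results; positions/momenta here are ALWAYS in atomic
## units (the public containers store angstrom and convert on entry).

## Complex overlap <g1|g2> for matrices of centroids: x, p are n x 2,
## gamma length n.  Basis functions on different electronic states are
## orthogonal; pass `state` to zero those blocks.
.gauss_overlap <- function(x, p, gamma, alpha, state = NULL) {
  n <- nrow(x)
  dx1 <- outer(x[, 1], x[, 1], "-"); dx2 <- outer(x[, 2], x[, 2], "-")
  dp1 <- outer(p[, 1], p[, 1], "-"); dp2 <- outer(p[, 2], p[, 2], "-")
  sp1 <- outer(p[, 1], p[, 1], "+"); sp2 <- outer(p[, 2], p[, 2], "+")
  logmod <- -alpha * (dx1^2 + dx2^2) / 2 - (dp1^2 + dp2^2) / (8 * alpha)
  phase  <- (sp1 * dx1 + sp2 * dx2) / 2 + outer(gamma, gamma, function(a, b) b - a)
  s <- exp(logmod) * complex(real = cos(phase), imaginary = sin(phase))
  if (!is.null(state)) s[outer(state, state, "!=")] <- 0 + 0i
  s
}

## First and second centered moments of the bra-ket Gaussian product:
## <g1|(x - x0)|g2> / <g1|g2> etc. have the complex center
##   zc = (x1 + x2)/2 + i (p2 - p1) / (4 alpha)
## and variance 1/(4 alpha) per dimension.
.gauss_center <- function(x1, p1, x2, p2, alpha) {
  (x1 + x2) / 2 + 1i * (p2 - p1) / (4 * alpha)
}

## <g1| -d^2/dx_d^2 |g2> / <g1|g2> for one dimension d:
##   = 2 alpha - <(ip2 - 2 alpha (x - x2))^2>
.gauss_kinetic_dim <- function(x1d, p1d, x2d, p2d, alpha) {
  zc <- .gauss_center(x1d, p1d, x2d, p2d, alpha)
  m1 <- zc - x2d                    # <x - x2>
  m2 <- m1^2 + 1 / (4 * alpha)      # <(x - x2)^2>
  2 * alpha - ((1i * p2d)^2 + 2 * (1i * p2d) * (-2 * alpha) * m1 +
                 4 * alpha^2 * m2)
}

## <g1| d/dx_d |g2> / <g1|g2>  =  i p2 - 2 alpha (<x> - x2)
.gauss_ddx_dim <- function(x1d, p1d, x2d, p2d, alpha) {
  zc <- .gauss_center(x1d, p1d, x2d, p2d, alpha)
  1i * p2d - 2 * alpha * (zc - x2d)
}
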