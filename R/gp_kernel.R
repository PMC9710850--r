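#' Squared-exponential kernel hyperparameters
#'
#' @param sigma_f signal standard deviation (density units).
#' @param sigma_n observation-noise standard deviation (density units).
#' @param ell1 spatial length-scale on the unit-interval coordinate.
#' @param ell2 temporal length-scale on the unit-interval coordinate.
#' @return An object of class `gp_hyper`.
#' @export
gp_hyperparameters <- function(sigma_f, sigma_n, ell1, ell2) {
  vals <- c(sigma_f = sigma_f, sigma_n = sigma_n, ell1 = ell1, ell2 = ell2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("parameter error: all hyperparameters must be strictly positive")
  structure(as.list(vals), class = "gp_hyper")
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat(sprintf("gp_hyper: sigma_f = %.6g, sigma_n = %.6g, ell1 = %.6g, ell2 = %.6g\n",
              x$sigma_f, x$sigma_n, x$ell1, x$ell2))
  invisible(x)
}

#' Squared-exponential covariance between two points
#'
#' `k(p, q) = sigma_f^2 exp(-(p1-q1)^2 / (2 ell1^2) - (p2-q2)^2 / (2 ell2^2))`
#' with inputs on the unit-interval (xi, tau) scale.
#'
#' @param p,q length-2 numeric vectors `(xi, tau)`.
#' @param hyper a [gp_hyperparameters()] object.
#' @return Covariance value.
#' @export
se_kernel <- function(p, q, hyper) {
  stopifnot(inherits(hyper, "gp_hyper"))
  hyper$sigma_f^2 *
    exp(-0.5 * ((p[1] - q[1]) / hyper$ell1)^2 -
         0.5 * ((p[2] - q[2]) / hyper$ell2)^2)
}

# d^ord/ds^ord exp(-s^2 / (2 ell^2)), closed forms up to fourth order.
# Kept explicit (not autodiff) so finite differences are an independent check.
.se_deriv_1d <- function(s, ord, ell) {
  e <- exp(-0.5 * (s / ell)^2)
  l2 <- ell^2
  switch(as.character(ord),
    "0" = e,
    "1" = -(s / l2) * e,
    "2" = (s^2 / l2^2 - 1 / l2) * e,
    "3" = (-s^3 / l2^3 + 3 * s / l2^2) * e,
    "4" = (s^4 / l2^4 - 6 * s^2 / l2^3 + 3 / l2^2) * e,
    stop("capability error: unsupported 1-d derivative order ", ord))
}

#' Analytic mixed partial derivatives of the squared-exponential kernel
#'
#' Computes `d^order k(p, q)` where `order = c(a_xi, a_tau, b_xi, b_tau)`
#' counts derivatives with respect to the spatial and temporal components of
#' `p` (first two entries) and of `q` (last two). Spatial orders up to 2 per
#' argument and temporal orders up to 1 per argument are supported, covering
#' every cross-covariance between the field and its first time, first space,
#' and second space derivatives.
#'
#' @inheritParams se_kernel
#' @param order length-4 non-negative integer multi-index.
#' @return Derivative value.
#' @export
se_kernel_derivatives <- function(p, q, hyper, order) {
  stopifnot(inherits(hyper, "gp_hyper"))
  order <- as.integer(order)
  if (length(order) != 4L || any(order < 0L))
    stop("capability error: order must be 4 non-negative integers")
  if (any(order[c(1, 3)] > 2L) || any(order[c(2, 4)] > 1L))
    stop("capability error: unsupported derivative order")
  sx <- p[1] - q[1]
  st <- p[2] - q[2]
  # For f(p - q), d/dq contributes a sign flip per derivative order.
  sign_q <- (-1)^(order[3] + order[4])
  hyper$sigma_f^2 * sign_q *
    .se_deriv_1d(sx, order[1] + order[3], hyper$ell1) *
    .se_deriv_1d(st, order[2] + order[4], hyper$ell2)
}

# Derivative operators indexing the joint posterior blocks:
# identity, d/dtau, d/dxi, d2/dxi2 (unit-interval scale).
.block_orders <- list(
  id  = c(0L, 0L),
  dt  = c(0L, 1L),
  dx  = c(1L, 0L),
  dxx = c(2L, 0L))

# Cross-covariance matrix between L_p u(P) and L_q u(Q) for the separable SE
# kernel. P, Q are 2 x np / 2 x nq matrices with rows (xi, tau).
se_cov_matrix <- function(P, Q, hyper, op_p = "id", op_q = "id") {
  ox <- .block_orders[[op_p]]
  oq <- .block_orders[[op_q]]
  if (is.null(ox) || is.null(oq)) stop("unknown block operator")
  sx <- outer(P[1, ], Q[1, ], "-")
  st <- outer(P[2, ], Q[2, ], "-")
  sign_q <- (-1)^(oq[1] + oq[2])
  hyper$sigma_f^2 * sign_q *
    .se_deriv_1d(sx, ox[1] + oq[1], hyper$ell1) *
    .se_deriv_1d(st, ox[2] + oq[2], hyper$ell2)
}
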