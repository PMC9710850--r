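#' Gaussian-process surrogate for the density field and its derivatives
#'
#' The surrogate models the de-noised density field `u*(xi, tau)` on the
#' unit square with a zero-mean GP and squared-exponential kernel, observed
#' through additive Gaussian noise `u = u* + sigma_n z`. Because
#' differentiation is a linear operator, the field and its first time, first
#' space, and second space derivatives are jointly Gaussian on any test
#' grid; the joint posterior mean and covariance are assembled blockwise
#' from analytic kernel derivatives, and draws from the joint posterior are
#' obtained through a Cholesky factor.
#'
#' @name gp_surrogate
NULL

# Training inputs on the unit square, canonical layout (space fastest within
# each time block, replicates appended): 2 x (N M Rep) matrix plus response.
training_matrix <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  flat <- flatten_densities(data)
  x_span <- range(data$positions)
  t_span <- range(data$times)
  X <- rbind(to_unit_interval(flat$position, x_span),
             to_unit_interval(flat$time, t_span))
  list(X = X, u = flat$density, x_span = x_span, t_span = t_span)
}

# Negative marginal log-likelihood and its gradient on log-hyperparameters.
# D2x, D2t are squared coordinate-difference matrices of the training inputs.
gp_nll <- function(log_par, u, D2x, D2t, want_grad = FALSE) {
  sf <- exp(log_par[1]); sn <- exp(log_par[2])
  l1 <- exp(log_par[3]); l2 <- exp(log_par[4])
  K0 <- exp(-0.5 * D2x / l1^2 - 0.5 * D2t / l2^2)
  A <- sf^2 * K0
  diag(A) <- diag(A) + sn^2
  ch <- try(chol(A), silent = TRUE)
  if (inherits(ch, "try-error")) {
    if (want_grad) return(list(value = 1e10, grad = rep(0, 4)))
    return(1e10)
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), u))
  nll <- sum(log(diag(ch))) + 0.5 * sum(u * alpha) +
    0.5 * length(u) * log(2 * pi)
  if (!want_grad) return(nll)
  Ainv <- chol2inv(ch)
  # dA/d(log theta) for each of the four log-parameters
  grads <- vapply(list(
    2 * sf^2 * K0,
    {dA <- matrix(0, nrow(A), ncol(A)); diag(dA) <- 2 * sn^2; dA},
    sf^2 * K0 * (D2x / l1^2),
    sf^2 * K0 * (D2t / l2^2)),
    function(dA) -0.5 * sum(alpha * (dA %*% alpha)) + 0.5 * sum(Ainv * dA),
    numeric(1))
  list(value = nll, grad = grads)
}

#' Fit GP hyperparameters by multistart maximum likelihood
#'
#' Maximises the Gaussian marginal likelihood of the rescaled observations
#' over `(sigma_f, sigma_n, ell1, ell2)` using BFGS on log-transformed
#' parameters (positivity enforced by the transform; the optimisation itself
#' is unconstrained, so optima may leave the sampling box). Starting points
#' are drawn by Latin hypercube over per-parameter boxes, by default
#' `ell in [1e-6, 1]` and `sigma in [1e-6, 7 SD(u)]`.
#'
#' @param data a rescaled [density_dataset()].
#' @param restarts number of Latin-hypercube starts (>= 1).
#' @param bounds optional list with elements `ell1`, `ell2`, `sigma_f`,
#'   `sigma_n`, each a length-2 interval for the start box.
#' @param seed integer seed for the start draw.
#' @return A [gp_hyperparameters()] object with attributes `loglik` (the
#'   best marginal log-likelihood) and `restart_logliks`.
#' @export
fit_hyperparameters <- function(data, restarts = 250L, bounds = NULL,
                                seed = 1L) {
  stopifnot(inherits(data, "density_dataset"))
  if (data$units_state != "rescaled")
    stop("fit on rescaled data (see rescale_units)")
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be >= 1")
  tr <- training_matrix(data)
  sd_u <- stats::sd(tr$u)
  if (is.null(bounds)) bounds <- list()
  box <- list(
    sigma_f = bounds$sigma_f %||% c(1e-6, 7 * sd_u),
    sigma_n = bounds$sigma_n %||% c(1e-6, 7 * sd_u),
    ell1 = bounds$ell1 %||% c(1e-6, 1),
    ell2 = bounds$ell2 %||% c(1e-6, 1))
  D2x <- outer(tr$X[1, ], tr$X[1, ], "-")^2
  D2t <- outer(tr$X[2, ], tr$X[2, ], "-")^2
  set.seed(seed)
  unit <- lhs::randomLHS(restarts, 4L)
  starts <- cbind(
    box$sigma_f[1] + unit[, 1] * diff(box$sigma_f),
    box$sigma_n[1] + unit[, 2] * diff(box$sigma_n),
    box$ell1[1] + unit[, 3] * diff(box$ell1),
    box$ell2[1] + unit[, 4] * diff(box$ell2))
  fn <- function(lp) gp_nll(lp, tr$u, D2x, D2t)
  gr <- function(lp) gp_nll(lp, tr$u, D2x, D2t, want_grad = TRUE)$grad
  fits <- vector("list", restarts)
  for (w in seq_len(restarts)) {
    fits[[w]] <- try(stats::optim(log(starts[w, ]), fn, gr, method = "BFGS",
                                  control = list(maxit = 200)), silent = TRUE)
  }
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  values <- rep(Inf, restarts)
  values[ok] <- vapply(fits[ok], `[[`, numeric(1), "value")
  if (all(!is.finite(values)))
    stop("fit error: no hyperparameter restart converged (",
         sum(!ok), " of ", restarts, " raised errors)")
  best <- which.min(values)
  p <- exp(fits[[best]]$par)
  hyper <- gp_hyperparameters(sigma_f = p[1], sigma_n = p[2],
                              ell1 = p[3], ell2 = p[4])
  attr(hyper, "loglik") <- -values[best]
  attr(hyper, "restart_logliks") <- -values
  hyper
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marginal log-likelihood of a hyperparameter set
#'
#' @param hyper a [gp_hyperparameters()] object.
#' @param data a rescaled [density_dataset()].
#' @return The Gaussian marginal log-likelihood.
#' @export
gp_marginal_loglik <- function(hyper, data) {
  stopifnot(inherits(hyper, "gp_hyper"))
  tr <- training_matrix(data)
  D2x <- outer(tr$X[1, ], tr$X[1, ], "-")^2
  D2t <- outer(tr$X[2, ], tr$X[2, ], "-")^2
  -gp_nll(log(c(hyper$sigma_f, hyper$sigma_n, hyper$ell1, hyper$ell2)),
          tr$u, D2x, D2t)
}

# Test-grid inputs in canonical order (xi fastest within each tau block).
test_matrix <- function(grid) {
  stopifnot(inherits(grid, "unit_grid"))
  rbind(rep(grid$xi, times = grid$m), rep(grid$tau, each = grid$n))
}

#' Joint posterior over the field and its derivatives
#'
#' Assembles the joint posterior mean and covariance of
#' `(u*, du*/dtau, du*/dxi, d2u*/dxi2)` on the test grid, conditional on the
#' observations. The covariance deliberately omits the observation-noise
#' term: the surrogate targets the underlying function, not the noisy data.
#' The covariance is stabilised with block-scaled nuggets
#' (see [regularize_covariance()]) and Cholesky-factorised for sampling.
#'
#' @param data a rescaled [density_dataset()].
#' @param hyper fitted [gp_hyperparameters()].
#' @param grid a [unit_interval_grid()].
#' @param eta base nugget magnitude.
#' @return An object of class `gp_surrogate` with `mu` (length `4 n m`),
#'   `Sigma`, `chol_L`, `hyper`, `grid`, and the training arrays.
#' @export
joint_mean_cov <- function(data, hyper, grid, eta = 1e-5) {
  stopifnot(inherits(data, "density_dataset"), inherits(hyper, "gp_hyper"),
            inherits(grid, "unit_grid"))
  tr <- training_matrix(data)
  Xs <- test_matrix(grid)
  nm <- ncol(Xs)
  ops <- c("id", "dt", "dx", "dxx")
  A <- se_cov_matrix(tr$X, tr$X, hyper, "id", "id")
  diag(A) <- diag(A) + hyper$sigma_n^2
  ch <- try(chol(A), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("numerical error: training covariance is not positive definite")
  Ainv <- chol2inv(ch)
  M <- do.call(rbind, lapply(ops, function(op)
    se_cov_matrix(Xs, tr$X, hyper, op, "id")))
  mu <- as.vector(M %*% (Ainv %*% tr$u))
  Kss <- matrix(0, 4 * nm, 4 * nm)
  for (i in seq_along(ops)) {
    for (j in seq_along(ops)) {
      Kss[(i - 1) * nm + seq_len(nm), (j - 1) * nm + seq_len(nm)] <-
        se_cov_matrix(Xs, Xs, hyper, ops[i], ops[j])
    }
  }
  Sigma <- Kss - M %*% Ainv %*% t(M)
  Sigma <- (Sigma + t(Sigma)) / 2
  Sigma <- regularize_covariance(Sigma, eta)
  L <- NULL
  eta_k <- eta
  for (k in 1:6) {
    L <- try(t(chol(Sigma)), silent = TRUE)
    if (!inherits(L, "try-error")) break
    eta_k <- eta_k * 10
    warning("joint covariance required a larger nugget (eta = ", eta_k, ")")
    Sigma <- regularize_covariance(Sigma, eta_k)
  }
  if (inherits(L, "try-error"))
    stop("numerical error: joint covariance could not be factorised")
  structure(
    list(hyper = hyper, train_X = tr$X, train_u = tr$u, grid = grid,
         mu = mu, Sigma = Sigma, chol_L = L, nm = nm,
         n = grid$n, m = grid$m),
    class = "gp_surrogate")
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf("gp_surrogate: %d x %d grid (joint dimension %d), %d observations\n",
              x$n, x$m, 4 * x$nm, length(x$train_u)))
  invisible(x)
}

#' Block-scaled nugget regularisation
#'
#' Adds a diagonal nugget to each of the four equal blocks of the joint
#' covariance, scaled by the trace of that block's prior variance relative
#' to the function-value block: `eta_i = eta * tr(Sigma_ii) / tr(Sigma_11)`.
#' Derivative blocks live on much larger scales than the function block, and
#' the trace scaling keeps the relative perturbation comparable across
#' blocks.
#'
#' @param Sigma a `4 nm x 4 nm` covariance matrix.
#' @param eta base nugget magnitude (default 1e-5).
#' @return The regularised covariance.
#' @export
regularize_covariance <- function(Sigma, eta = 1e-5) {
  d <- nrow(Sigma)
  if (is.null(d) || d != ncol(Sigma) || d %% 4L != 0L)
    stop("Sigma must be square with four equal blocks")
  nm <- d %/% 4L
  traces <- vapply(0:3, function(b)
    sum(diag(Sigma)[b * nm + seq_len(nm)]), numeric(1))
  if (traces[1] <= 0)
    stop("degenerate-surrogate error: function block has zero trace")
  etas <- eta * traces / traces[1]
  Sigma + diag(rep(etas, each = nm), d)
}

#' Draw a joint function-and-derivative sample
#'
#' Computes `U = mu + L z` and splits it into the four blocks, mapping the
#' unit-interval derivatives back to physical scales: time derivatives are
#' divided by the time span, first space derivatives by the space span, and
#' second space derivatives by the squared space span.
#'
#' @param surrogate a [joint_mean_cov()] surrogate.
#' @param z length-`4 n m` standard-normal vector (`z = 0` returns the
#'   posterior mean).
#' @return An object of class `function_sample` with `n x m` matrices `u`,
#'   `du_dt`, `du_dx`, `d2u_dx2`, the draw `z`, and the grid.
#' @export
sample_joint <- function(surrogate, z) {
  stopifnot(inherits(surrogate, "gp_surrogate"))
  nm <- surrogate$nm
  if (length(z) != 4 * nm)
    stop("dimension error: z must have length ", 4 * nm)
  U <- surrogate$mu + as.vector(surrogate$chol_L %*% z)
  grid <- surrogate$grid
  dxs <- diff(grid$x_span)
  dts <- diff(grid$t_span)
  shape <- function(b) matrix(U[(b - 1) * nm + seq_len(nm)],
                              surrogate$n, surrogate$m)
  structure(
    list(u = shape(1),
         du_dt = shape(2) / dts,
         du_dx = shape(3) / dxs,
         d2u_dx2 = shape(4) / dxs^2,
         z = z, grid = grid),
    class = "function_sample")
}

#' Standard-normal draw registry for shared bootstrap samples
#'
#' Generates the `B` standard-normal vectors that drive a bootstrap run.
#' Candidate models compared on the same registry consume identical draws,
#' which is what makes per-draw information-criterion comparisons paired.
#'
#' @param surrogate a [joint_mean_cov()] surrogate.
#' @param B number of draws.
#' @param seed integer seed.
#' @return A `4 n m x B` matrix whose columns are the draws.
#' @export
draw_registry <- function(surrogate, B, seed) {
  stopifnot(inherits(surrogate, "gp_surrogate"))
  set.seed(seed)
  matrix(stats::rnorm(4 * surrogate$nm * B), nrow = 4 * surrogate$nm, ncol = B)
}

#' Save / load a fitted surrogate
#'
#' Stores the hyperparameters, grid, posterior mean, and Cholesky factor so
#' one fitted surrogate can be reused across candidate-model fits.
#'
#' @param surrogate a `gp_surrogate`.
#' @param path file path.
#' @return `read_surrogate` returns the surrogate.
#' @export
write_surrogate <- function(surrogate, path) {
  stopifnot(inherits(surrogate, "gp_surrogate"))
  saveRDS(surrogate, path)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "gp_surrogate"))
  s
}
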