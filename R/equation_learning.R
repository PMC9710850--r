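#' Loss functions and parameter estimation
#'
#' Parameters are estimated per bootstrap draw by minimising the combined
#' loss `log(L_PDE) + log(L_GLS)`: the PDE-residual loss ties the sampled
#' field and derivatives to the proposed mechanisms, while the
#' generalised-least-squares loss ties the numerical PDE solution to the
#' observed data. Physically infeasible parameter vectors (negative delay or
#' diffusivity values, or a negative integrated reaction) receive an
#' infinite loss.
#'
#' @name equation_learning
NULL

#' PDE-residual loss
#'
#' Mean squared residual of the expanded invasion model over the sampled
#' grid:
#' `du*/dt - T(t) [ dD/du (du*/dx)^2 + D d2u*/dx2 + R(u*) ]`,
#' with all derivatives on physical scales.
#'
#' @param theta parameter vector (working scale).
#' @param model a [mechanism_model()].
#' @param sample a [sample_joint()] function sample.
#' @param mask optional logical `n x m` matrix restricting the sum (see
#'   [threshold_data()]).
#' @return Mean squared residual; `Inf` when residuals are non-finite.
#' @export
loss_pde <- function(theta, model, sample, mask = NULL) {
  stopifnot(inherits(sample, "function_sample"))
  res <- try(pde_residuals(theta, model, sample), silent = TRUE)
  if (inherits(res, "try-error")) return(Inf)
  if (!is.null(mask)) res <- res[mask]
  out <- mean(res^2)
  if (!is.finite(out)) Inf else out
}

# Residual matrix of the expanded model over the n x m sample grid.
# Mechanisms are evaluated at densities clipped to zero, matching the
# convention used for sampled initial conditions: slightly negative sampled
# densities are surrogate artifacts, and fractional-power diffusivities are
# undefined there.
pde_residuals <- function(theta, model, sample) {
  fns <- model_functions(model, theta)
  Tt <- fns$Tf(sample$grid$ts)          # length m, one value per time column
  u_eval <- pmax(sample$u, 0)
  Dd <- fns$Df(u_eval)
  R <- fns$Rf(u_eval)
  rhs <- sweep(Dd$dD * sample$du_dx^2 + Dd$D * sample$d2u_dx2 + R,
               2, Tt, "*")
  sample$du_dt - rhs
}

#' Generalised-least-squares data loss
#'
#' Weighted mean of squared standardised residuals between the PDE solution
#' extracted at the data coordinates and the replicate-averaged data:
#' `sum_j w_j ((uhat_ij - u_ij) / sigma_n)^2 / (N M)`. The first time point
#' receives extra weight (default 10) because the initial profile need not
#' satisfy the governing model.
#'
#' @param model a [mechanism_model()] (unused directly; kept for a uniform
#'   signature).
#' @param data a rescaled [density_dataset()].
#' @param solution a [solve_pde()] result covering the data times.
#' @param sigma_n observation-noise standard deviation (> 0).
#' @param weights per-time weights, default `c(10, 1, 1, ...)`.
#' @return Weighted mean squared standardised residual.
#' @export
loss_gls <- function(model, data, solution, sigma_n, weights = NULL) {
  stopifnot(inherits(data, "density_dataset"),
            inherits(solution, "pde_solution"))
  if (!is.numeric(sigma_n) || sigma_n <= 0)
    stop("parameter error: sigma_n must be positive")
  M <- length(data$times)
  if (is.null(weights)) weights <- c(10, rep(1, M - 1))
  if (length(weights) != M) stop("weights must have one entry per time")
  if (!solution$ok) return(Inf)
  uhat <- extract_solution(solution, data$positions, data$times)
  ubar <- average_replicates(data)
  res2 <- ((uhat - ubar) / sigma_n)^2
  out <- sum(sweep(res2, 2, weights, "*")) / length(ubar)
  if (!is.finite(out)) Inf else out
}

# Combine the two losses on the log scale; non-finite or non-positive pieces
# collapse to +Inf / the machine floor so the optimiser sees a barrier.
combine_losses <- function(l_pde, l_gls, feasible = TRUE) {
  if (!feasible || !is.finite(l_pde) || !is.finite(l_gls)) return(Inf)
  log(max(l_pde, 1e-300)) + log(max(l_gls, 1e-300))
}

#' Fitting configuration
#'
#' Bundles the fixed ingredients of a loss evaluation: the finite-volume
#' mesh, the initial condition, the noise level used to standardise the GLS
#' residuals, time weights, integrator tolerances, and an optional
#' threshold mask.
#'
#' @param mesh a [build_mesh()] mesh on the data's spatial range.
#' @param ic length-`Np` initial condition (typically [sampled_ic()]).
#' @param sigma_n observation-noise SD (typically the fitted GP value).
#' @param weights per-time GLS weights (default `c(10, 1, ...)`).
#' @param rtol,atol integrator tolerances.
#' @param maxsteps integrator step cap per output interval; keeps
#'   pathological trial parameters from consuming unbounded solver effort
#'   (well-behaved solves need a few hundred steps).
#' @param mask optional logical matrix for the PDE-residual sum.
#' @param feasibility_points number of evaluation points for the
#'   delay/diffusivity positivity checks.
#' @param quadrature_order Gauss-Legendre order for the reaction integral.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(mesh, ic, sigma_n, weights = NULL,
                       rtol = 1e-6, atol = 1e-8, maxsteps = 1000L,
                       mask = NULL,
                       feasibility_points = 100L, quadrature_order = 64L) {
  structure(list(mesh = mesh, ic = ic, sigma_n = sigma_n, weights = weights,
                 rtol = rtol, atol = atol, maxsteps = maxsteps, mask = mask,
                 feasibility_points = feasibility_points,
                 quadrature_order = quadrature_order),
            class = "fit_config")
}

# Gauss-Legendre nodes/weights on [0, 1], cached per order (the reaction
# integral is evaluated thousands of times per bootstrap draw).
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_unit <- function(order) {
  key <- as.character(order)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(order, 0, 1)
  }
  .gl_cache[[key]]
}

# Physical feasibility: the delay must be non-negative on the time grid, the
# diffusivity non-negative over the sampled density range, and the reaction
# integral over [0, u_M] non-negative (Gauss-Legendre quadrature).
check_feasibility <- function(theta, model, sample, config) {
  fns <- try(model_functions(model, theta), silent = TRUE)
  if (inherits(fns, "try-error")) return(FALSE)
  Tt <- fns$Tf(sample$grid$ts)
  if (any(!is.finite(Tt)) || any(Tt < 0)) return(FALSE)
  u_max <- max(sample$u)
  if (!is.finite(u_max) || u_max <= 0) return(FALSE)
  u_lo <- max(0, min(sample$u))
  u_eval <- seq(u_lo, u_max, length.out = config$feasibility_points)
  D <- try(fns$Df(u_eval)$D, silent = TRUE)
  if (inherits(D, "try-error") || any(!is.finite(D)) || any(D < 0))
    return(FALSE)
  gl <- gauss_legendre_unit(config$quadrature_order)
  Rint <- try(sum(u_max * gl$w * fns$Rf(u_max * gl$x)), silent = TRUE)
  if (inherits(Rint, "try-error") || !is.finite(Rint) || Rint < 0)
    return(FALSE)
  TRUE
}

#' Combined loss with feasibility barrier
#'
#' Checks physical feasibility, evaluates the PDE-residual loss, solves the
#' PDE, evaluates the GLS loss, and combines the two on the log scale.
#' Any infeasibility, integration failure, or non-finite loss yields
#' `combined = Inf`.
#'
#' @param theta parameter vector (working scale).
#' @param model a [mechanism_model()].
#' @param sample a [sample_joint()] function sample.
#' @param data a rescaled [density_dataset()].
#' @param config a [fit_config()].
#' @return A list of class `loss_breakdown` with `l_pde`, `l_gls`,
#'   `combined`, `feasible`, and `solution` (NULL when infeasible).
#' @export
combined_loss <- function(theta, model, sample, data, config) {
  stopifnot(inherits(config, "fit_config"))
  feasible <- check_feasibility(theta, model, sample, config)
  if (!feasible) {
    return(structure(list(l_pde = Inf, l_gls = Inf, combined = Inf,
                          feasible = FALSE, solution = NULL),
                     class = "loss_breakdown"))
  }
  l_pde <- loss_pde(theta, model, sample, mask = config$mask)
  solution <- solve_pde(model, theta, config$ic, data$times, config$mesh,
                        rtol = config$rtol, atol = config$atol,
                        maxsteps = config$maxsteps %||% 5000L)
  l_gls <- loss_gls(model, data, solution, config$sigma_n, config$weights)
  combined <- combine_losses(l_pde, l_gls)
  structure(list(l_pde = l_pde, l_gls = l_gls, combined = combined,
                 feasible = is.finite(combined), solution = solution),
            class = "loss_breakdown")
}

# Default Latin-hypercube start box on the working scale: log-uniform over
# [1e-3, 1e3] for positive-kind parameters (rates, diffusivities), uniform
# over [-10, 10] for sign-free parameters (delay intercepts, exponents).
default_start_box <- function(model) {
  lapply(model$par_kinds, function(kind) {
    if (kind == "plain") list(range = c(-10, 10), log = FALSE)
    else list(range = c(1e-3, 1e3), log = TRUE)
  })
}

# Draw `n_starts` starting parameter vectors by Latin hypercube.
lhs_starts <- function(model, n_starts, seed, box = NULL) {
  if (is.null(box)) box <- default_start_box(model)
  p <- n_parameters(model)
  set.seed(seed)
  unit <- lhs::randomLHS(n_starts, p)
  starts <- matrix(NA_real_, n_starts, p)
  for (k in seq_len(p)) {
    b <- box[[k]]
    starts[, k] <- if (isTRUE(b$log)) {
      exp(log(b$range[1]) + unit[, k] * diff(log(b$range)))
    } else {
      b$range[1] + unit[, k] * diff(b$range)
    }
  }
  starts
}

#' Estimate mechanism parameters for one surrogate draw
#'
#' Minimises the combined loss by Nelder-Mead over parameters rescaled by
#' `scales` so the search runs on O(1) quantities. Starting points either
#' come from a Latin hypercube over rough per-parameter boxes (`strategy =
#' "lhs"`, the pilot-phase default) or from the scale vector itself
#' (`strategy = "scaled"`, i.e. every scaled parameter starts at 1, the
#' post-pilot default). Infeasible starts are discarded; the best feasible
#' optimisation result is returned.
#'
#' @param model a [mechanism_model()].
#' @param sample a [sample_joint()] function sample.
#' @param data a rescaled [density_dataset()].
#' @param config a [fit_config()].
#' @param scales non-zero per-parameter scale factors (default 1), signed
#'   so the scaled search starts in the correct orthant.
#' @param strategy `"lhs"` or `"scaled"`.
#' @param n_starts number of Latin-hypercube starts for `"lhs"`.
#' @param seed integer seed for the start draw.
#' @param start_box optional per-parameter start box (list of
#'   `list(range, log)`), overriding the defaults.
#' @param maxit Nelder-Mead iteration cap.
#' @return A list with `theta` (working scale), `loss` (a `loss_breakdown`),
#'   `start`, and `n_feasible_starts`.
#' @export
estimate_parameters <- function(model, sample, data, config,
                                scales = NULL,
                                strategy = c("lhs", "scaled"),
                                n_starts = 5L, seed = 1L,
                                start_box = NULL, maxit = 400L) {
  strategy <- match.arg(strategy)
  p <- n_parameters(model)
  if (is.null(scales)) scales <- rep(1, p)
  if (length(scales) != p || any(scales == 0) || any(!is.finite(scales)))
    stop("scales must be ", p, " non-zero values")
  starts <- if (strategy == "lhs") {
    lhs_starts(model, n_starts, seed, box = start_box)
  } else {
    matrix(scales, nrow = 1)
  }
  objective <- function(theta_scaled) {
    combined_loss(theta_scaled * scales, model, sample, data, config)$combined
  }
  start_losses <- apply(starts, 1, function(th) objective(th / scales))
  feasible <- which(is.finite(start_losses))
  if (!length(feasible)) {
    if (strategy == "scaled") {
      # fall back to a fresh hypercube rather than failing the draw
      starts <- lhs_starts(model, n_starts, seed, box = start_box)
      start_losses <- apply(starts, 1, function(th) objective(th / scales))
      feasible <- which(is.finite(start_losses))
    }
    if (!length(feasible))
      stop("estimation error: no feasible starting point (",
           nrow(starts), " tried)")
  }
  best <- NULL
  for (i in feasible) {
    fit <- try(stats::optim(starts[i, ] / scales, objective,
                            method = "Nelder-Mead",
                            control = list(maxit = maxit)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    # chained restart: re-run the simplex once from its solution
    # (fresh simplices escape the collapse NM suffers in narrow valleys)
    refit <- try(stats::optim(fit$par, objective, method = "Nelder-Mead",
                              control = list(maxit = maxit)),
                 silent = TRUE)
    if (!inherits(refit, "try-error") && refit$value <= fit$value)
      fit <- refit
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("estimation error: all feasible starts failed to optimise")
  theta <- best$par * scales
  list(theta = theta,
       loss = combined_loss(theta, model, sample, data, config),
       start = starts[feasible[1], ],
       n_feasible_starts = length(feasible))
}

#' Fast linear least-squares fit (basis-function approach)
#'
#' For delay-free models whose diffusivity and reaction are linear in the
#' parameters, the expanded model residual is linear in `theta`, so the
#' parameters solve a plain least-squares problem over the sampled grid.
#' No PDE is solved and the data loss plays no role, which makes this
#' orders of magnitude faster but less accurate in PDE-solution error; it
#' is chiefly useful for obtaining parameter scales.
#'
#' @param model a delay-free [mechanism_model()] with `constant` or
#'   `porous` diffusivity and `logistic` or `gompertz` reaction.
#' @param sample a [sample_joint()] function sample.
#' @return A list with `theta` (named, working scale) and `rank_deficient`.
#' @export
linear_basis_fit <- function(model, sample) {
  stopifnot(inherits(model, "mechanism_model"),
            inherits(sample, "function_sample"))
  if (model$delay_form != "none")
    stop("basis-function fit requires a delay-free model")
  if (!model$diffusivity_form %in% c("constant", "porous"))
    stop("basis-function fit requires a diffusivity linear in its parameters")
  if (!model$reaction_form %in% c("logistic", "gompertz"))
    stop("basis-function fit requires a reaction linear in its parameters")
  u <- as.vector(sample$u)
  ux <- as.vector(sample$du_dx)
  uxx <- as.vector(sample$d2u_dx2)
  K <- model$K
  d_col <- switch(model$diffusivity_form,
    constant = uxx,
    porous = (ux^2 + u * uxx) / K)
  r_col <- switch(model$reaction_form,
    logistic = u * (1 - u / K),
    gompertz = ifelse(u == 0, 0, u * log(K / u)))
  A <- cbind(d_col, r_col)
  y <- as.vector(sample$du_dt)
  qrA <- qr(A)
  rank_deficient <- qrA$rank < ncol(A)
  theta <- if (rank_deficient) {
    warning("rank-deficient basis design; using the pseudoinverse")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    as.vector(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
  } else {
    as.vector(qr.coef(qrA, y))
  }
  names(theta) <- model$par_names
  list(theta = theta, rank_deficient = rank_deficient)
}

#' Threshold the sampled grid by density and rate
#'
#' Keeps grid points whose sampled density lies within
#' `[low, high] * max(u)` and whose absolute time derivative lies within
#' `[low, high] * max(|du/dt|)`. The resulting mask restricts the
#' PDE-residual sum only; the data loss is unaffected.
#'
#' @param sample a [sample_joint()] function sample.
#' @param delta_u length-2 density fractions `(low, high)` in \[0, 1\].
#' @param delta_t length-2 rate fractions `(low, high)` in \[0, 1\].
#' @return A logical `n x m` mask.
#' @export
threshold_data <- function(sample, delta_u = c(0, 1), delta_t = c(0, 1)) {
  stopifnot(inherits(sample, "function_sample"))
  check_frac <- function(d, nm) {
    if (length(d) != 2 || any(d < 0) || any(d > 1) || d[1] >= d[2])
      stop(nm, " must be (low, high) fractions in [0, 1] with low < high")
  }
  check_frac(delta_u, "delta_u")
  check_frac(delta_t, "delta_t")
  u_max <- max(sample$u)
  r_max <- max(abs(sample$du_dt))
  # a flat-in-time sample makes every point "too slow" for a positive lower
  # rate threshold; likewise a zero field for a positive density threshold
  if ((delta_t[1] > 0 && r_max == 0) || (delta_u[1] > 0 && u_max == 0))
    stop("thresholding error: mask removes every grid point")
  mask <- sample$u >= delta_u[1] * u_max & sample$u <= delta_u[2] * u_max &
    abs(sample$du_dt) >= delta_t[1] * r_max &
    abs(sample$du_dt) <= delta_t[2] * r_max
  if (!any(mask))
    stop("thresholding error: mask removes every grid point")
  mask
}
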