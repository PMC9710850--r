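#' Parametric bootstrap over surrogate draws
#'
#' Each bootstrap draw samples the joint field-and-derivative posterior,
#' estimates the mechanism parameters for that draw, and solves the PDE with
#' the draw's sampled initial condition. The ensemble of draws yields
#' sampling distributions for parameters, functional forms, PDE solutions,
#' and information criteria. All randomness flows through the standard
#' normal draw registry, so identical seeds give identical ensembles and
#' different candidate models can consume identical draws.
#'
#' @name bootstrap_uq
NULL

#' Run a parametric bootstrap for one candidate model
#'
#' A pilot phase (`pilot` draws, Latin-hypercube multistart) establishes
#' signed per-parameter scale factors whose magnitude is the geometric mean
#' of the pilot estimates (floored at 1e-8) and whose sign follows the pilot
#' median; the main `B` draws then start each scaled parameter at 1, i.e. at
#' the pilot estimate. Draws whose estimation fails are recorded and dropped from summaries;
#' more than 50% failures aborts with diagnostics.
#'
#' @param surrogate a [joint_mean_cov()] surrogate.
#' @param model a [mechanism_model()] with `K` on the working scale.
#' @param data the rescaled [density_dataset()] the surrogate was fitted to.
#' @param B number of bootstrap draws.
#' @param seed integer seed (drives the draw registry and start sampling).
#' @param Np finite-volume nodes for the PDE solves.
#' @param pilot number of pilot draws used for scale estimation (0 skips
#'   the pilot; `scales` must then be supplied).
#' @param starts Latin-hypercube starts per pilot draw.
#' @param scales optional known scale factors (skips the pilot).
#' @param level confidence level for interval summaries.
#' @param z_draws optional `4 n m x (pilot + B)` registry of standard-normal
#'   draws, shared across models for paired model selection.
#' @param delta_u,delta_t optional thresholding fractions (see
#'   [threshold_data()]).
#' @param weights GLS time weights (default `c(10, 1, ...)`).
#' @param rtol,atol integrator tolerances.
#' @param workers number of worker processes (draws are deterministic given
#'   the registry, so the result is identical for any worker count).
#' @return An object of class `bootstrap_ensemble`.
#' @export
run_bootstrap <- function(surrogate, model, data, B = 100L, seed = 1L,
                          Np = 500L, pilot = 10L, starts = 5L,
                          scales = NULL, level = 0.95, z_draws = NULL,
                          delta_u = NULL, delta_t = NULL, weights = NULL,
                          rtol = 1e-6, atol = 1e-8, workers = 1L) {
  stopifnot(inherits(surrogate, "gp_surrogate"),
            inherits(model, "mechanism_model"),
            inherits(data, "density_dataset"))
  B <- as.integer(B)
  pilot <- if (is.null(scales)) as.integer(pilot) else 0L
  if (is.null(z_draws)) {
    z_draws <- draw_registry(surrogate, pilot + B, seed)
  } else if (ncol(z_draws) < pilot + B) {
    stop("z_draws must supply at least pilot + B columns")
  }
  mesh <- build_mesh(min(data$positions), max(data$positions), Np)
  sigma_n <- surrogate$hyper$sigma_n

  draw_config <- function(sample) {
    mask <- if (!is.null(delta_u) || !is.null(delta_t)) {
      threshold_data(sample, delta_u %||% c(0, 1), delta_t %||% c(0, 1))
    } else NULL
    fit_config(mesh = mesh, ic = sampled_ic(sample, mesh), sigma_n = sigma_n,
               weights = weights, rtol = rtol, atol = atol, mask = mask)
  }

  run_draw <- function(b, z_col, strategy, scl) {
    sample <- sample_joint(surrogate, z_draws[, z_col])
    config <- draw_config(sample)
    est <- estimate_parameters(model, sample, data, config,
                               scales = scl, strategy = strategy,
                               n_starts = starts, seed = seed + 1000L + b)
    uhat <- extract_solution(est$loss$solution, data$positions, data$times)
    list(z_id = z_col, theta = est$theta,
         theta_phys = physical_parameters(model, est$theta),
         l_pde = est$loss$l_pde, l_gls = est$loss$l_gls,
         combined = est$loss$combined, uhat = uhat,
         aicc = aicc(uhat - average_replicates(data),
                     model$a, model$d, model$r),
         ok = TRUE)
  }
  safe_draw <- function(b, z_col, strategy, scl) {
    out <- try(run_draw(b, z_col, strategy, scl), silent = TRUE)
    if (inherits(out, "try-error")) {
      list(z_id = z_col, ok = FALSE, error = attr(out, "condition")$message %||%
             as.character(out))
    } else out
  }

  if (is.null(scales)) {
    pilot_draws <- lapply(seq_len(pilot), function(b)
      safe_draw(b, b, "lhs", NULL))
    thetas <- lapply(Filter(function(d) isTRUE(d$ok), pilot_draws),
                     `[[`, "theta")
    if (!length(thetas)) {
      first <- Filter(function(d) !isTRUE(d$ok), pilot_draws)[[1]]$error
      stop("ensemble error: every pilot draw failed; first: ", first)
    }
    mat <- do.call(rbind, thetas)
    mag <- pmax(exp(colMeans(log(pmax(abs(mat), 1e-12)))), 1e-8)
    # scales are signed so that the post-pilot start (every scaled
    # parameter at 1) sits at the pilot estimate, sign included
    sgn <- sign(apply(mat, 2, stats::median))
    sgn[sgn == 0] <- 1
    scales <- sgn * mag
  }

  apply_fun <- if (workers > 1L) {
    function(idx, f) parallel::mclapply(idx, f, mc.cores = workers)
  } else {
    function(idx, f) lapply(idx, f)
  }
  draws <- apply_fun(seq_len(B), function(b)
    safe_draw(b, pilot + b, "scaled", scales))
  n_fail <- sum(!vapply(draws, function(d) isTRUE(d$ok), logical(1)))
  if (n_fail > B / 2) {
    msgs <- unlist(lapply(draws, function(d) if (!isTRUE(d$ok)) d$error))
    stop("ensemble error: ", n_fail, " of ", B, " draws failed; first: ",
         msgs[1])
  }
  structure(
    list(draws = draws, model = model, level = level, B = B,
         scales = scales, sigma_n = sigma_n,
         positions = data$positions, times = data$times,
         ubar = average_replicates(data), n_failed = n_fail,
         seed = seed, Np = Np),
    class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble: %s; B = %d (%d failed), level = %.0f%%\n",
              x$model$label, x$B, x$n_failed, 100 * x$level))
  invisible(x)
}

ok_draws <- function(ensemble) {
  Filter(function(d) isTRUE(d$ok), ensemble$draws)
}

#' Per-parameter bootstrap samples
#'
#' @param ensemble a [run_bootstrap()] ensemble.
#' @param parameter parameter name (see the model's `par_names`).
#' @param physical report in physical units (default) or the working scale.
#' @return Numeric vector over successful draws.
#' @export
parameter_samples <- function(ensemble, parameter, physical = TRUE) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  idx <- match(parameter, ensemble$model$par_names)
  if (is.na(idx)) stop("unknown parameter: ", parameter)
  field <- if (physical) "theta_phys" else "theta"
  vapply(ok_draws(ensemble), function(d) d[[field]][idx], numeric(1))
}

#' Percentile confidence interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` using the
#' standard linear-interpolation definition (quantile type 7), so intervals
#' are bit-reproducible.
#'
#' @param samples numeric vector.
#' @param level confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
confidence_interval <- function(samples, level = 0.95) {
  if (!length(samples)) stop("empty sample")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Kernel density estimate and its mode
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' 512-point grid; the mode is the grid argmax (ties broken toward the
#' lower value).
#'
#' @param samples numeric vector (length >= 5).
#' @return A list with `x`, `y` (the density curve) and `mode`.
#' @export
kde_mode <- function(samples) {
  if (length(samples) < 5L) stop("kde_mode needs at least 5 samples")
  if (stats::sd(samples) == 0) {
    warning("zero-variance sample; density is degenerate")
    return(list(x = samples[1], y = Inf, mode = samples[1]))
  }
  den <- stats::density(samples, n = 512L)
  list(x = den$x, y = den$y, mode = den$x[which.max(den$y)])
}

#' Pointwise ribbon for a mechanism's functional form
#'
#' Evaluates the delay, diffusivity, or reaction curve for every bootstrap
#' draw over an evaluation range and returns the pointwise mean and
#' percentile band.
#'
#' @param ensemble a [run_bootstrap()] ensemble.
#' @param mechanism `"delay"`, `"diffusivity"`, or `"reaction"`.
#' @param eval_range length-2 range of `t` (delay) or `u` (others), on the
#'   working scale; defaults to `[0, K]` for density mechanisms and the
#'   data's time range for the delay.
#' @param n_points evaluation points.
#' @param level confidence level.
#' @return A list with `x`, `mean`, `lo`, `hi`.
#' @export
functional_ribbon <- function(ensemble,
                              mechanism = c("delay", "diffusivity",
                                            "reaction"),
                              eval_range = NULL, n_points = 100L,
                              level = ensemble$level) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  mechanism <- match.arg(mechanism)
  model <- ensemble$model
  if (is.null(eval_range)) {
    eval_range <- if (mechanism == "delay") range(ensemble$times)
                  else c(0, model$K)
  }
  if (diff(eval_range) <= 0) stop("eval_range must be non-degenerate")
  x <- seq(eval_range[1], eval_range[2], length.out = n_points)
  draws <- ok_draws(ensemble)
  if (!length(draws)) stop("empty ensemble")
  curves <- vapply(draws, function(d) {
    fns <- model_functions(model, d$theta)
    switch(mechanism,
      delay = fns$Tf(x),
      diffusivity = fns$Df(x)$D,
      reaction = fns$Rf(x))
  }, numeric(n_points))
  curves <- matrix(curves, nrow = n_points)
  a <- (1 - level) / 2
  list(x = x,
       mean = rowMeans(curves),
       lo = apply(curves, 1, stats::quantile, probs = a, names = FALSE),
       hi = apply(curves, 1, stats::quantile, probs = 1 - a, names = FALSE))
}

#' Median absolute percentage error of one solution against the data
#'
#' `e_ij = 100 |uhat_ij - u_ij| / max(zeta, u_ij)` with `u_ij` the
#' replicate-averaged density and `zeta` machine precision guarding
#' zero-density cells; the summary is the median over the grid.
#'
#' @param uhat `N x M` matrix of PDE-solution values at the data grid.
#' @param ubar `N x M` replicate-averaged densities.
#' @return Median absolute percentage error (in percent).
#' @export
mape <- function(uhat, ubar) {
  zeta <- .Machine$double.eps
  stats::median(100 * abs(uhat - ubar) / pmax(zeta, ubar))
}

#' Bootstrap confidence interval for the MAPE
#'
#' Computes the per-draw median absolute percentage error of the sampled-IC
#' PDE solutions against the replicate-averaged data and returns its
#' percentile interval across draws.
#'
#' @param ensemble a [run_bootstrap()] ensemble.
#' @param level confidence level.
#' @return A list with `interval` (`c(lo, hi)`, percent) and the per-draw
#'   `mapes`.
#' @export
mape_interval <- function(ensemble, level = ensemble$level) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  mapes <- vapply(ok_draws(ensemble), function(d)
    mape(d$uhat, ensemble$ubar), numeric(1))
  list(interval = confidence_interval(mapes, level), mapes = mapes)
}

#' Confidence-interval hypothesis test for a parameter
#'
#' Rejects the point null iff the null value lies outside the closed
#' percentile interval (a null exactly at an endpoint is not rejected).
#'
#' @param ensemble a [run_bootstrap()] ensemble.
#' @param parameter parameter name.
#' @param null null value (physical units), default 0.
#' @param level confidence level.
#' @return A list with `parameter`, `null`, `interval`, `level`, `reject`.
#' @export
ci_hypothesis_test <- function(ensemble, parameter, null = 0,
                               level = ensemble$level) {
  samples <- parameter_samples(ensemble, parameter, physical = TRUE)
  ci <- confidence_interval(samples, level)
  list(parameter = parameter, null = null, interval = ci, level = level,
       reject = null < ci["lo"] || null > ci["hi"])
}

#' Summarise an ensemble's parameters
#'
#' @param ensemble a [run_bootstrap()] ensemble.
#' @param level confidence level.
#' @return A data frame with one row per parameter: `lo`, `hi`, `mode`
#'   (physical units).
#' @export
ensemble_summary <- function(ensemble, level = ensemble$level) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  rows <- lapply(ensemble$model$par_names, function(p) {
    s <- parameter_samples(ensemble, p, physical = TRUE)
    ci <- confidence_interval(s, level)
    mode <- if (length(s) >= 5 && stats::sd(s) > 0) kde_mode(s)$mode
            else stats::median(s)
    data.frame(parameter = p, lo = ci[["lo"]], hi = ci[["hi"]],
               mode = mode)
  })
  do.call(rbind, rows)
}
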