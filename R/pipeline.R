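#' End-to-end mechanism discovery pipeline
#'
#' Convenience wrappers tying the stages together: rescale the data, fit
#' the GP surrogate, bootstrap one or several candidate models, and
#' summarise. Every stage is also available individually.
#'
#' @name pipeline
NULL

#' Fit the GP surrogate to a dataset
#'
#' Rescales raw data if needed, fits hyperparameters by multistart maximum
#' likelihood, and assembles the joint derivative posterior on an `n x m`
#' unit-interval grid.
#'
#' @param data a [density_dataset()] (raw or rescaled).
#' @param n,m surrogate grid size.
#' @param restarts hyperparameter restarts.
#' @param seed integer seed.
#' @param eta nugget magnitude.
#' @param bounds optional hyperparameter start boxes
#'   (see [fit_hyperparameters()]).
#' @return A list with `data` (rescaled), `hyper`, `grid`, `surrogate`.
#' @export
fit_surrogate <- function(data, n = 50L, m = 50L, restarts = 250L,
                          seed = 1L, eta = 1e-5, bounds = NULL) {
  stopifnot(inherits(data, "density_dataset"))
  if (data$units_state == "raw") data <- rescale_units(data)
  hyper <- fit_hyperparameters(data, restarts = restarts, bounds = bounds,
                               seed = seed)
  grid <- unit_interval_grid(data, n, m)
  surrogate <- joint_mean_cov(data, hyper, grid, eta = eta)
  list(data = data, hyper = hyper, grid = grid, surrogate = surrogate)
}

#' Discover mechanisms in a density dataset
#'
#' Runs the full pipeline for one or more candidate models: GP surrogate,
#' shared-draw parametric bootstrap per model, parameter summaries, MAPE
#' intervals, and (for several candidates) AICc model selection.
#'
#' @param data a [density_dataset()] (raw or rescaled).
#' @param models a [mechanism_model()] or named list of them, with `K` on
#'   the working scale (raw `K` times 1e6).
#' @param B bootstrap draws per model.
#' @param seed integer seed.
#' @param n,m surrogate grid size.
#' @param restarts hyperparameter restarts.
#' @param Np finite-volume nodes.
#' @param pilot pilot draws for parameter-scale estimation.
#' @param ... further arguments passed to [run_bootstrap()].
#' @return A list with `surrogate_fit`, `ensembles`, `summaries`,
#'   `mape`, and (for more than one model) `selection`.
#' @export
discover_mechanisms <- function(data, models, B = 100L, seed = 1L,
                                n = 50L, m = 50L, restarts = 250L,
                                Np = 500L, pilot = 10L, ...) {
  if (inherits(models, "mechanism_model")) models <- list(model = models)
  fit <- fit_surrogate(data, n = n, m = m, restarts = restarts, seed = seed)
  sel <- select_models(fit$surrogate, models, fit$data, B = B, seed = seed,
                       pilot = pilot, Np = Np, ...)
  summaries <- lapply(sel$ensembles, ensemble_summary)
  mapes <- lapply(sel$ensembles, function(e) mape_interval(e)$interval)
  out <- list(surrogate_fit = fit, ensembles = sel$ensembles,
              summaries = summaries, mape = mapes)
  if (length(models) > 1L) out$selection <- sel$selection
  out
}
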