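#' Small-sample-corrected AIC of one draw's PDE solution
#'
#' `AIC = NM log(SSR / NM) + 2 (k + 1)` with `k = a + d + r` mechanism
#' parameters plus one noise parameter, and
#' `AICc = AIC + 2 (k + 1)(k + 2) / (NM - k)`. Residuals are the same
#' replicate-averaged data-minus-solution residuals used by the GLS loss,
#' from the sampled-initial-condition PDE solve.
#'
#' @param residuals numeric array of residuals `uhat - u`.
#' @param a,d,r delay, diffusivity, and reaction parameter counts.
#' @return The AICc value.
#' @export
aicc <- function(residuals, a, d, r) {
  k <- a + d + r
  NM <- length(residuals)
  if (NM <= k) stop("domain error: need more residuals than parameters")
  aic <- NM * log(sum(residuals^2) / NM) + 2 * (k + 1)
  aic + 2 * (k + 1) * (k + 2) / (NM - k)
}

#' Evidence trichotomy for AICc differences
#'
#' `Delta <= 3` is substantial evidence the model is amongst the best
#' fitting class (`E1`); `3 < Delta <= 8` is considerably weaker evidence
#' (`E2`); `Delta > 8` is essentially no evidence (`E3`).
#'
#' @param delta non-negative AICc difference(s) from the per-draw minimum.
#' @return Factor with levels `E1`, `E2`, `E3`.
#' @export
classify_delta <- function(delta) {
  if (any(delta < 0)) stop("logic error: negative delta")
  cut(delta, breaks = c(-Inf, 3, 8, Inf), labels = c("E1", "E2", "E3"))
}

#' Evidence-class proportion matrix across candidate models
#'
#' For each bootstrap draw, AICc differences from the per-draw minimum are
#' classified into the evidence trichotomy; proportions over draws form the
#' 3 x |M| matrix `P` whose columns sum to 1 (rows need not: several models
#' can share the best class). Draws with a missing value for any model are
#' excluded for all models to keep the comparison paired.
#'
#' @param per_model_aicc `|M| x B` matrix of AICc values on shared draws
#'   (rows are models; `NA` marks a failed draw).
#' @param models optional model labels (defaults to rownames).
#' @return An object of class `selection_matrix` with fields `p` (3 x |M|),
#'   `models`, and `B` (draws used).
#' @export
selection_matrix <- function(per_model_aicc, models = NULL) {
  per_model_aicc <- as.matrix(per_model_aicc)
  n_models <- nrow(per_model_aicc)
  if (is.null(models)) {
    models <- rownames(per_model_aicc) %||% paste0("model", seq_len(n_models))
  }
  if (length(models) != n_models)
    stop("pairing error: one label per model row is required")
  keep <- which(colSums(is.na(per_model_aicc)) == 0L)
  if (!length(keep)) stop("pairing error: no draw succeeded for all models")
  counts <- matrix(0, 3, n_models,
                   dimnames = list(c("E1", "E2", "E3"), models))
  for (b in keep) {
    delta <- per_model_aicc[, b] - min(per_model_aicc[, b])
    cls <- classify_delta(delta)
    for (i in seq_len(n_models))
      counts[as.integer(cls[i]), i] <- counts[as.integer(cls[i]), i] + 1
  }
  structure(list(p = counts / length(keep), models = models,
                 B = length(keep)),
            class = "selection_matrix")
}

#' @export
print.selection_matrix <- function(x, ...) {
  cat(sprintf("selection_matrix over %d paired draws:\n", x$B))
  print(round(x$p, 3))
  invisible(x)
}

#' Fit and compare candidate models on shared bootstrap draws
#'
#' Runs the full bootstrap for every candidate model using one shared draw
#' registry, so the per-draw AICc comparison is paired, and assembles the
#' evidence-proportion matrix.
#'
#' @param surrogate a [joint_mean_cov()] surrogate.
#' @param models a named list of [mechanism_model()] candidates (e.g.
#'   [model_catalog()]).
#' @param data the rescaled [density_dataset()].
#' @param B bootstrap draws per model.
#' @param seed integer seed.
#' @param pilot pilot draws for scale estimation (shared registry columns).
#' @param ... further arguments passed to [run_bootstrap()].
#' @return A list with `selection` (a [selection_matrix()]) and `ensembles`
#'   (one [run_bootstrap()] ensemble per model).
#' @export
select_models <- function(surrogate, models, data, B = 100L, seed = 1L,
                          pilot = 10L, ...) {
  stopifnot(is.list(models), length(models) >= 1L)
  z_draws <- draw_registry(surrogate, pilot + B, seed)
  ensembles <- lapply(models, function(model)
    run_bootstrap(surrogate, model, data, B = B, seed = seed,
                  pilot = pilot, z_draws = z_draws, ...))
  labels <- names(models) %||% paste0("model", seq_along(models))
  aicc_mat <- do.call(rbind, lapply(ensembles, function(ens)
    vapply(ens$draws, function(d)
      if (isTRUE(d$ok)) d$aicc else NA_real_, numeric(1))))
  rownames(aicc_mat) <- labels
  list(selection = selection_matrix(aicc_mat, labels),
       ensembles = ensembles)
}
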