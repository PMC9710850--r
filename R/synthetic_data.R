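#' Synthetic scratch-assay data
#'
#' Generates spatiotemporal density datasets with known generating
#' mechanisms by solving the invasion model on a fine mesh and adding
#' additive Gaussian noise, emulating the shape of scratch-assay
#' experiments: a handful of observation times, a few dozen spatial
#' positions, a small number of replicates, and a scratch-shaped initial
#' profile (high plateaus near the well edges, depleted centre).
#'
#' @name synthetic_data
NULL

#' Scratch-shaped initial density profile
#'
#' A smooth symmetric well built from two tanh ramps: density `u_edge` on
#' plateaus near both domain ends, `u_mid` in the depleted centre, with C1
#' transitions of relative width `edge_width`.
#'
#' @param u_edge plateau density near the boundaries (`u_edge >= u_mid`).
#' @param u_mid central density (>= 0).
#' @param edge_width transition location as a fraction of the domain,
#'   in (0, 0.5).
#' @param positions spatial coordinates to evaluate at.
#' @return Density values at `positions`.
#' @export
scratch_ic <- function(u_edge, u_mid, edge_width, positions) {
  if (u_mid < 0 || u_edge < u_mid)
    stop("parameter error: need u_edge >= u_mid >= 0")
  if (edge_width <= 0 || edge_width >= 0.5)
    stop("parameter error: edge_width must lie in (0, 0.5)")
  rng <- range(positions)
  s <- (positions - rng[1]) / diff(rng)
  k <- edge_width / 4
  well <- 1 - 0.5 * tanh((s - edge_width) / k) +
    0.5 * tanh((s - (1 - edge_width)) / k)
  u_mid + (u_edge - u_mid) * well
}

#' Synthetic study design
#'
#' @param model the generating [mechanism_model()] with `K` in raw units.
#' @param theta_true generating parameters in physical units (rates per
#'   hour, diffusivities in square micrometres per hour).
#' @param sigma_n additive noise SD in raw density units (>= 0).
#' @param positions spatial observation grid (micrometres).
#' @param times temporal observation grid (hours, starting at 0).
#' @param replicates number of identically prepared replicates.
#' @param ic list with `u_edge`, `u_mid`, `edge_width` for [scratch_ic()].
#' @param seed integer seed used by [generate_study()].
#' @param label design label.
#' @return An object of class `study_design`.
#' @export
study_design <- function(model, theta_true, sigma_n,
                         positions = seq(75, 1875, length.out = 37),
                         times = seq(0, 48, by = 12),
                         replicates = 3L,
                         ic = list(u_edge = 0.5 * model$K,
                                   u_mid = 0.02 * model$K,
                                   edge_width = 0.2),
                         seed = 1L, label = model$label) {
  stopifnot(inherits(model, "mechanism_model"))
  if (length(theta_true) != n_parameters(model))
    stop("theta_true must have ", n_parameters(model), " parameters")
  if (sigma_n < 0) stop("sigma_n must be non-negative")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(model = model, theta_true = as.numeric(theta_true),
                 sigma_n = sigma_n, positions = as.numeric(positions),
                 times = as.numeric(times), replicates = as.integer(replicates),
                 ic = ic, seed = as.integer(seed), label = label),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %s; %d x %d x %d grid, sigma_n = %.3g\n",
              x$label, length(x$positions), length(x$times), x$replicates,
              x$sigma_n))
  invisible(x)
}

#' Generate a synthetic dataset from a study design
#'
#' Solves the generating PDE on a fine finite-volume mesh in raw units,
#' extracts the solution at the design's observation grid (nearest node),
#' and adds i.i.d. additive Gaussian noise independently per replicate.
#' Negative noisy densities are retained: the noise model is additive with
#' constant variance.
#'
#' @param design a [study_design()].
#' @param Np_fine nodes for the generating solve.
#' @param seed optional seed overriding the design's.
#' @return A raw-unit [density_dataset()] with attribute `truth`, the
#'   noise-free `N x M` solution at the observation grid.
#' @export
generate_study <- function(design, Np_fine = 500L, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  mesh <- build_mesh(min(design$positions), max(design$positions), Np_fine)
  ic <- scratch_ic(design$ic$u_edge, design$ic$u_mid, design$ic$edge_width,
                   mesh$nodes)
  sol <- solve_pde(design$model, design$theta_true, ic, design$times, mesh)
  if (!sol$ok) stop("generation error: the generating PDE solve failed")
  truth <- extract_solution(sol, design$positions, design$times)
  set.seed(seed %||% design$seed)
  N <- length(design$positions); M <- length(design$times)
  arr <- array(NA_real_, c(N, M, design$replicates))
  for (r in seq_len(design$replicates)) {
    arr[, , r] <- truth + design$sigma_n * matrix(stats::rnorm(N * M), N, M)
  }
  out <- density_dataset(design$positions, design$times, arr,
                         units_state = "raw")
  attr(out, "truth") <- truth
  out
}

#' Preset synthetic study designs
#'
#' Two designs mirroring the synthetic validation studies: study 1 is the
#' Fisher-Kolmogorov model (`beta1 = 301` um^2/h, `gamma1 = 0.044` /h);
#' study 2 is the Fisher-Kolmogorov model with logistic delay
#' (`alpha1 = -1.5`, `alpha2 = 0.31` /h, `beta1 = 571` um^2/h,
#' `gamma1 = 0.081` /h). Both use a 37 x 5 x 3 grid with
#' `x in [75, 1875]` um, `t in {0, 12, 24, 36, 48}` h, carrying capacity
#' `K = 1.7e-3` cells/um^2, and additive noise with SD 5% of `K`.
#'
#' @return A named list of two [study_design()] objects.
#' @export
study_presets <- function() {
  K <- 1.7e-3
  sigma_n <- 0.05 * K
  list(
    study1 = study_design(
      mechanism_model("none", "constant", "logistic", K,
                      label = "Fisher-Kolmogorov"),
      theta_true = c(beta1 = 301, gamma1 = 0.044),
      sigma_n = sigma_n, seed = 1L, label = "study 1 (Fisher-Kolmogorov)"),
    study2 = study_design(
      mechanism_model("logistic", "constant", "logistic", K,
                      label = "Fisher-Kolmogorov with delay"),
      theta_true = c(alpha1 = -1.5, alpha2 = 0.31, beta1 = 571,
                     gamma1 = 0.081),
      sigma_n = sigma_n, seed = 2L,
      label = "study 2 (delayed Fisher-Kolmogorov)"))
}

#' Serialise a study design to JSON
#'
#' Records the generating model, parameters, grid, noise level, and seed
#' alongside a generated dataset for provenance.
#'
#' @param design a [study_design()].
#' @param path output path.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  obj <- list(
    label = design$label,
    delay = design$model$delay_form,
    diffusivity = design$model$diffusivity_form,
    reaction = design$model$reaction_form,
    K = design$model$K,
    theta_true = as.list(stats::setNames(design$theta_true,
                                         design$model$par_names)),
    sigma_n = design$sigma_n,
    positions = design$positions,
    times = design$times,
    replicates = design$replicates,
    ic = design$ic,
    seed = design$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
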