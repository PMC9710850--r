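#' Vertex-centred finite-volume mesh
#'
#' Places `Np` equally spaced nodes on `[a, b]` with control-volume faces at
#' the midpoints between nodes. Boundary control volumes are half-width, so
#' volumes are `dx/2` at the two ends and `dx` in the interior, and the
#' volumes partition `[a, b]` exactly.
#'
#' @param a,b domain endpoints, `b > a`.
#' @param Np number of nodes (>= 3).
#' @return An object of class `fv_mesh` with `nodes`, `w_bounds`, `e_bounds`,
#'   `volumes`, and `dx`.
#' @export
build_mesh <- function(a, b, Np = 500L) {
  Np <- as.integer(Np)
  if (!is.finite(a) || !is.finite(b) || b <= a) stop("mesh error: need b > a")
  if (Np < 3L) stop("mesh error: Np must be >= 3")
  dx <- (b - a) / (Np - 1)
  nodes <- a + (seq_len(Np) - 1) * dx
  w <- c(nodes[1], (nodes[-Np] + nodes[-1]) / 2)
  e <- c((nodes[-Np] + nodes[-1]) / 2, nodes[Np])
  V <- rep(dx, Np)
  V[c(1, Np)] <- dx / 2
  structure(list(nodes = nodes, w_bounds = w, e_bounds = e,
                 volumes = V, dx = dx, Np = Np),
            class = "fv_mesh")
}

#' Finite-volume semi-discretisation of the invasion model
#'
#' Evaluates the right-hand side of the method-of-lines system for
#' `du/dt = T(t) [ d/dx ( D(u) du/dx ) + R(u) ]` with zero-flux boundaries.
#' Diffusivities at control-volume faces are arithmetic means of the nodal
#' values; gradients are first-order differences; the delay factor multiplies
#' the whole bracket. With `R = 0` the scheme conserves the discrete mass
#' `sum(V_i u_i)` exactly.
#'
#' @param u length-`Np` state vector.
#' @param t time.
#' @param model a [mechanism_model()].
#' @param theta parameter vector on the same unit scale as `u`, `t`.
#' @param mesh a [build_mesh()] mesh.
#' @return Length-`Np` time derivative.
#' @export
fvm_rhs <- function(u, t, model, theta, mesh) {
  fns <- model_functions(model, theta)
  fvm_rhs_fns(u, t, fns, mesh)
}

# Inner kernel reused by the integrator so closures are built once per solve.
# D and R are evaluated at densities clipped to zero: fractional-power
# diffusivities are undefined for negative u, and small undershoots near
# steep fronts are mesh artifacts (the flux itself uses the raw state).
fvm_rhs_fns <- function(u, t, fns, mesh) {
  Np <- mesh$Np
  dx <- mesh$dx
  u0 <- pmax(u, 0)
  D <- fns$Df(u0)$D
  R <- fns$Rf(u0)
  Tt <- fns$Tf(t)
  # face fluxes D_{i+1/2} (u_{i+1} - u_i) / dx at the Np - 1 interior faces
  flux <- (D[-Np] + D[-1]) / 2 * (u[-1] - u[-Np]) / dx
  dudt <- numeric(Np)
  dudt[1] <- 2 / dx * flux[1] + R[1]
  dudt[Np] <- -2 / dx * flux[Np - 1] + R[Np]
  dudt[2:(Np - 1)] <- (flux[-1] - flux[-(Np - 1)]) / dx + R[2:(Np - 1)]
  Tt * dudt
}

# Encode a model + parameter vector for the compiled right-hand side.
fvm_parms <- function(model, theta, mesh) {
  fns <- model_functions(model, theta)
  pad <- function(v, n) c(v, rep(0, n - length(v)))
  c(mesh$dx, model$K,
    match(model$delay_form, c("none", "logistic", "probit", "cloglog")) - 1,
    pad(fns$alpha, 2),
    match(model$diffusivity_form,
          c("constant", "porous", "generalized", "extended")) - 1,
    pad(fns$beta, 5),
    match(model$reaction_form, c("logistic", "gompertz", "richards")) - 1,
    pad(fns$gamma, 2))
}

#' Solve the invasion PDE
#'
#' Method-of-lines integration of the finite-volume system with a
#' stiff-capable adaptive integrator (lsoda, banded Jacobian). By default the
#' right-hand side is the package's compiled (C) finite-volume kernel, which
#' the integrator calls without per-step R overhead; `compiled = FALSE`
#' switches to the plain-R kernel ([fvm_rhs()]), which is the reference the
#' compiled one is tested against. Integration
#' failures from pathological parameter vectors are returned as a flagged
#' solution (`ok = FALSE`) rather than an error, so that optimisers can treat
#' them as infinitely bad trial points.
#'
#' @param model a [mechanism_model()].
#' @param theta parameter vector.
#' @param ic length-`Np` initial condition at `times[1]`.
#' @param times ascending output times starting at 0.
#' @param mesh a [build_mesh()] mesh.
#' @param rtol,atol integration tolerances.
#' @param maxsteps integrator step cap per output interval; trial parameter
#'   vectors that exceed it are flagged as failed solutions.
#' @param compiled use the compiled right-hand side (default) or the plain-R
#'   reference kernel.
#' @return An object of class `pde_solution` with `times`, `values`
#'   (`Np x length(times)`), `mesh`, `params`, and `ok`.
#' @export
solve_pde <- function(model, theta, ic, times, mesh,
                      rtol = 1e-6, atol = 1e-8, maxsteps = 5000L,
                      compiled = TRUE) {
  stopifnot(inherits(mesh, "fv_mesh"))
  if (length(ic) != mesh$Np) stop("dimension error: ic must have Np values")
  if (any(!is.finite(ic))) stop("ic must be finite")
  if (length(times) < 1L || any(diff(times) <= 0) ||
      abs(times[1]) > .Machine$double.eps)
    stop("times must be ascending and start at 0")
  sol <- if (compiled) {
    parms <- fvm_parms(model, theta, mesh)
    try(suppressWarnings(
      deSolve::ode(y = ic, times = times, func = "mechdisc_derivs",
                   initfunc = "mechdisc_initmod", dllname = "mechdisc",
                   parms = parms, method = "lsoda", jactype = "bandint",
                   bandup = 1L, banddown = 1L, rtol = rtol, atol = atol,
                   maxsteps = maxsteps)),
      silent = TRUE)
  } else {
    fns <- model_functions(model, theta)
    deriv <- function(t, y, parms) list(fvm_rhs_fns(y, t, fns, mesh))
    try(suppressWarnings(
      deSolve::ode(y = ic, times = times, func = deriv, parms = NULL,
                   method = "lsoda", jactype = "bandint",
                   bandup = 1L, banddown = 1L, rtol = rtol, atol = atol,
                   maxsteps = maxsteps)),
      silent = TRUE)
  }
  ok <- !inherits(sol, "try-error") &&
    nrow(sol) == length(times) && all(is.finite(sol[, -1]))
  values <- if (ok) t(unname(sol[, -1, drop = FALSE]))
            else matrix(NA_real_, mesh$Np, length(times))
  structure(list(times = times, values = values, mesh = mesh,
                 params = theta, ok = ok),
            class = "pde_solution")
}

#' Extract a PDE solution at data coordinates
#'
#' Nearest-node extraction in space, with ties broken toward the lower
#' index; output times must match the solution's output times.
#'
#' @param solution a [solve_pde()] result.
#' @param positions spatial data coordinates.
#' @param times temporal data coordinates (subset of `solution$times`).
#' @return A `length(positions) x length(times)` matrix.
#' @export
extract_solution <- function(solution, positions, times = solution$times) {
  stopifnot(inherits(solution, "pde_solution"))
  jt <- match_times(times, solution$times)
  ix <- nearest_lower(positions, solution$mesh$nodes)
  solution$values[ix, jt, drop = FALSE]
}

match_times <- function(times, solution_times) {
  jt <- vapply(times, function(t) {
    j <- which(abs(solution_times - t) < 1e-9 * max(1, abs(t)))
    if (!length(j)) stop("requested time not in solution output: ", t)
    j[1]
  }, integer(1))
  jt
}

# Index of the nearest grid node, ties toward the lower index.
nearest_lower <- function(x, nodes) {
  vapply(x, function(xi) {
    d <- abs(nodes - xi)
    which(d <= min(d) + .Machine$double.eps * max(1, abs(xi)))[1]
  }, integer(1))
}

#' Export a PDE solution as a delimited table
#'
#' Long-format rows `(position, time, density)`, space fastest.
#'
#' @param solution a [solve_pde()] result.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_solution_table <- function(solution, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(solution, "pde_solution"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(
    position = rep(solution$mesh$nodes, times = length(solution$times)),
    time = rep(solution$times, each = solution$mesh$Np),
    density = as.vector(solution$values))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linear-spline initial condition from data
#'
#' Linearly interpolates the replicate-averaged density profile at the first
#' observation time onto the mesh nodes.
#'
#' @param data a [density_dataset()] whose first time is 0.
#' @param mesh a [build_mesh()] mesh contained in the data's spatial range.
#' @return Length-`Np` initial condition.
#' @export
spline_ic <- function(data, mesh) {
  stopifnot(inherits(data, "density_dataset"), inherits(mesh, "fv_mesh"))
  if (abs(data$times[1]) > .Machine$double.eps * max(1, abs(data$times[2])))
    stop("data must contain t = 0")
  rng <- range(data$positions)
  eps <- 1e-9 * diff(rng)
  if (min(mesh$nodes) < rng[1] - eps || max(mesh$nodes) > rng[2] + eps)
    stop("extrapolation error: mesh extends beyond the data range")
  u0 <- average_replicates(data)[, 1]
  stats::approx(data$positions, u0, xout = mesh$nodes, rule = 2)$y
}

#' Sampled initial condition from a surrogate draw
#'
#' Takes the `t = 0` slice of a Gaussian-process function sample, clips
#' negative densities to zero, and linearly interpolates onto the mesh.
#'
#' @param sample a [sample_joint()] function sample.
#' @param mesh a [build_mesh()] mesh contained in the sample's spatial range.
#' @return Length-`Np` initial condition.
#' @export
sampled_ic <- function(sample, mesh) {
  stopifnot(inherits(sample, "function_sample"), inherits(mesh, "fv_mesh"))
  grid <- sample$grid
  rng <- range(grid$xs)
  eps <- 1e-9 * diff(rng)
  if (min(mesh$nodes) < rng[1] - eps || max(mesh$nodes) > rng[2] + eps)
    stop("extrapolation error: mesh extends beyond the sample range")
  u0 <- pmax(sample$u[, 1], 0)
  stats::approx(grid$xs, u0, xout = mesh$nodes, rule = 2)$y
}
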