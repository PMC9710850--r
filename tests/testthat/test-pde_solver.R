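Kw <- 1700  # carrying capacity on the working density scale

test_that("the mesh partitions the domain with half-volumes at the ends", {
  m3 <- build_mesh(0, 1, 3)
  expect_equal(m3$nodes, c(0, 0.5, 1))
  expect_equal(m3$volumes, c(0.25, 0.5, 0.25))
  expect_equal(m3$w_bounds, c(0, 0.25, 0.75))
  expect_equal(m3$e_bounds, c(0.25, 0.75, 1))
  m <- build_mesh(75, 1875, 50)
  expect_equal(sum(m$volumes), 1800)
  expect_true(all(m$w_bounds <= m$nodes & m$nodes <= m$e_bounds))
  expect_error(build_mesh(0, 1, 2), "mesh error")
  expect_error(build_mesh(1, 0, 10), "mesh error")
})

test_that("the semi-discretisation is exact on uniform states", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  mesh <- build_mesh(0, 1.8, 21)
  u <- rep(Kw / 2, 21)
  # zero reaction: flat state is stationary
  expect_equal(fvm_rhs(u, 0, mod, c(0.007, 0), mesh), rep(0, 21))
  # logistic reaction at u = K/2 reduces to the logistic ODE maximum
  expect_equal(fvm_rhs(u, 0, mod, c(0.007, 1), mesh), rep(Kw / 4, 21))
})

test_that("zero-flux diffusion conserves discrete mass", {
  mesh <- build_mesh(0, 1.8, 31)
  set.seed(21)
  for (mod in list(mechanism_model("none", "constant", "logistic", Kw),
                   mechanism_model("none", "porous", "logistic", Kw))) {
    theta <- c(0.01, 0)  # zero reaction rate
    u <- runif(31, 0, Kw)
    dudt <- fvm_rhs(u, 0, mod, theta, mesh)
    expect_lt(abs(sum(mesh$volumes * dudt)) / max(abs(dudt)), 1e-12)
  }
  # and over a full integration
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  ic <- scratch_ic(0.5 * Kw, 0.02 * Kw, 0.2, mesh$nodes)
  sol <- solve_pde(mod, c(0.007, 0), ic, c(0, 1, 2), mesh)
  mass <- colSums(mesh$volumes * sol$values)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)
})

test_that("uniform initial conditions follow the logistic closed form", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  mesh <- build_mesh(0, 1.8, 21)
  gam <- 1.1
  times <- c(0, 0.5, 1, 2)
  sol <- solve_pde(mod, c(0.0072, gam), rep(Kw / 2, 21), times, mesh)
  expect_true(sol$ok)
  exact <- Kw / (1 + exp(-gam * times))
  err <- abs(sweep(sol$values, 2, exact, "-")) / Kw
  expect_lt(max(err), 1e-5)
  expect_equal(sol$values[, 1], rep(Kw / 2, 21))
})

test_that("logistic delay acts as a closed-form time change", {
  mod <- mechanism_model("logistic", "constant", "logistic", Kw)
  mesh <- build_mesh(0, 1.8, 21)
  a1 <- -1.5; a2 <- 7.44; gam <- 1.9; u0 <- Kw / 4
  times <- c(0, 0.5, 1, 2)
  sol <- solve_pde(mod, c(a1, a2, 0.0072, gam), rep(u0, 21), times, mesh)
  S <- (log(1 + exp(a1 + a2 * times)) - log(1 + exp(a1))) / a2
  exact <- Kw * u0 / (u0 + (Kw - u0) * exp(-gam * S))
  err <- abs(sweep(sol$values, 2, exact, "-")) / Kw
  expect_lt(max(err), 1e-5)
})

test_that("the compiled kernel agrees with the plain-R reference", {
  mesh <- build_mesh(0.075, 1.875, 40)
  ic <- scratch_ic(0.5 * Kw, 0.02 * Kw, 0.2, mesh$nodes)
  times <- c(0, 0.7, 2)
  cases <- list(
    list(mechanism_model("none", "constant", "logistic", Kw),
         c(0.0072, 1.056)),
    list(mechanism_model("logistic", "porous", "logistic", Kw),
         c(-1.5, 7.44, 0.03, 1.9)),
    list(mechanism_model("probit", "generalized", "richards", Kw),
         c(-1, 5, 0.005, 0.01, 2.5, 1.8, 1.2)),
    list(mechanism_model("cloglog", "constant", "gompertz", Kw),
         c(-1, 5, 0.0072, 0.8)))
  for (cs in cases) {
    a <- solve_pde(cs[[1]], cs[[2]], ic, times, mesh, compiled = TRUE)
    b <- solve_pde(cs[[1]], cs[[2]], ic, times, mesh, compiled = FALSE)
    expect_true(a$ok && b$ok)
    expect_lt(max(abs(a$values - b$values)) / Kw, 1e-5)
  }
})

test_that("pathological parameters flag the solution instead of crashing", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  mesh <- build_mesh(0, 1.8, 11)
  ic <- scratch_ic(0.5 * Kw, 0.02 * Kw, 0.2, mesh$nodes)
  sol <- solve_pde(mod, c(-50, 0), ic, c(0, 1), mesh)  # backward diffusion
  expect_false(sol$ok)
  expect_error(solve_pde(mod, c(0.007, 1), ic, c(1, 2), mesh), "start at 0")
})

test_that("spatial error shrinks roughly quadratically with refinement", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  times <- c(0, 1)
  ref_mesh <- build_mesh(0, 1.8, 401)
  ic_fun <- function(x) scratch_ic(0.5 * Kw, 0.02 * Kw, 0.2, x)
  ref <- solve_pde(mod, c(0.02, 1), ic_fun(ref_mesh$nodes), times, ref_mesh,
                   rtol = 1e-10, atol = 1e-10)
  probe <- seq(0.36, 1.44, by = 0.36)  # shared nodes of all three meshes
  err_at <- function(Np) {
    mesh <- build_mesh(0, 1.8, Np)
    sol <- solve_pde(mod, c(0.02, 1), ic_fun(mesh$nodes), times, mesh,
                     rtol = 1e-10, atol = 1e-10)
    max(abs(extract_solution(sol, probe)[, 2] -
            extract_solution(ref, probe)[, 2]))
  }
  e1 <- err_at(51)
  e2 <- err_at(101)
  expect_gt(e1 / e2, 2.5)  # ~4 for a second-order scheme
})

test_that("initial conditions interpolate linearly onto the mesh", {
  dat <- density_dataset(c(0, 1, 2), c(0, 1),
                         array(c(1, 3, 5, 2, 2, 2), c(3, 2, 1)),
                         units_state = "rescaled")
  mesh <- build_mesh(0, 2, 5)
  expect_equal(spline_ic(dat, mesh), c(1, 2, 3, 4, 5))
  # nodes coinciding with data positions reproduce the averaged data
  mesh3 <- build_mesh(0, 2, 3)
  expect_equal(spline_ic(dat, mesh3), c(1, 3, 5))
  expect_error(spline_ic(dat, build_mesh(-1, 2, 4)), "extrapolation")

  s <- manual_sample(u = matrix(c(2, -0.3, 4, 1, 1, 1), 3, 2),
                     du_dt = matrix(0, 3, 2), x_span = c(0, 2))
  mesh_s <- build_mesh(0, 2, 3)
  expect_equal(sampled_ic(s, mesh_s), c(2, 0, 4))
  pos_s <- manual_sample(u = matrix(1:6, 3, 2), du_dt = matrix(0, 3, 2),
                         x_span = c(0, 2))
  expect_equal(sampled_ic(pos_s, mesh_s), c(1, 2, 3))
})

test_that("nearest-node extraction breaks ties toward the lower index", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  mesh <- build_mesh(0, 2, 3)  # nodes 0, 1, 2
  sol <- solve_pde(mod, c(0.007, 0), c(10, 20, 30), c(0, 1), mesh)
  expect_equal(as.vector(extract_solution(sol, c(0.5, 1.5), 0)), c(10, 20))
  expect_equal(as.vector(extract_solution(sol, c(0.4, 0.6), 0)), c(10, 20))
  # solutions export as long-format delimited tables
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution_table(sol, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$density[1:3], sol$values[, 1])
})
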