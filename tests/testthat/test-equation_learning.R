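Kw <- 1700

test_that("the PDE-residual loss is a mean of squared residuals", {
  # zero-diffusivity, zero-reaction model: residual reduces to du/dt
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  s <- manual_sample(u = matrix(Kw / 2, 2, 2),
                     du_dt = matrix(c(1, 2, 0, 1), 2, 2))
  expect_equal(loss_pde(c(0, 0), mod, s), 1.5)
  s2 <- s; s2$du_dt <- 2 * s$du_dt
  expect_equal(loss_pde(c(0, 0), mod, s2), 6)
  # a sample built exactly from the model has zero residual
  set.seed(31)
  u <- matrix(runif(12, 100, Kw), 3, 4)
  ux <- matrix(rnorm(12), 3, 4)
  uxx <- matrix(rnorm(12), 3, 4)
  theta <- c(0.007, 1.1)
  sm <- manual_sample(u = u, du_dt = 0 * u, du_dx = ux, d2u_dx2 = uxx)
  sm$du_dt <- mechdisc:::pde_residuals(theta, mod, sm) * 0 +
    (0.007 * uxx + 1.1 * u * (1 - u / Kw))
  expect_lt(loss_pde(theta, mod, sm), 1e-18)
  # masking restricts the average
  mask <- matrix(FALSE, 2, 2); mask[1, 1] <- TRUE
  expect_equal(loss_pde(c(0, 0), mod, s, mask = mask), 1)
})

test_that("the GLS loss standardises residuals and weights time 0", {
  dat <- density_dataset(c(0, 1, 2), c(0, 1),
                         array(rep(c(5, 6, 7), 2), c(3, 2, 1)),
                         units_state = "rescaled")
  mesh <- build_mesh(0, 2, 3)
  perfect <- structure(list(times = c(0, 1),
                            values = matrix(c(5, 6, 7, 5, 6, 7), 3, 2),
                            mesh = mesh, params = NULL, ok = TRUE),
                       class = "pde_solution")
  expect_equal(loss_gls(NULL, dat, perfect, sigma_n = 2), 0)
  # one residual of size sigma_n at time 1 picks up the weight 10
  off <- perfect; off$values[1, 1] <- 5 + 0.3
  expect_equal(loss_gls(NULL, dat, off, sigma_n = 0.3), 10 / 6)
  # scaling sigma_n by c scales the loss by 1/c^2
  l1 <- loss_gls(NULL, dat, off, sigma_n = 0.1)
  l2 <- loss_gls(NULL, dat, off, sigma_n = 0.2)
  expect_equal(l1 / l2, 4)
  expect_error(loss_gls(NULL, dat, off, sigma_n = 0), "positive")
})

test_that("losses combine on the log scale with an infinity barrier", {
  expect_equal(mechdisc:::combine_losses(exp(2), exp(3)), 5)
  expect_equal(mechdisc:::combine_losses(Inf, 1), Inf)
  expect_equal(mechdisc:::combine_losses(1, NaN), Inf)
  expect_equal(mechdisc:::combine_losses(1, 1, feasible = FALSE), Inf)
})

test_that("physically infeasible parameters receive infinite loss", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  set.seed(32)
  s <- manual_sample(u = matrix(runif(12, 100, Kw), 3, 4),
                     du_dt = matrix(rnorm(12), 3, 4))
  dat <- toy_dataset(function(x, t) 500 + 0 * x, n_x = 3, n_t = 3)
  mesh <- build_mesh(0, 1.8, 5)
  cfg <- fit_config(mesh, rep(500, 5), sigma_n = 85)
  # negative diffusivity
  bad <- combined_loss(c(-1, 1), mod, s, dat, cfg)
  expect_false(bad$feasible)
  expect_equal(bad$combined, Inf)
  # negative integrated reaction
  bad2 <- combined_loss(c(0.007, -1), mod, s, dat, cfg)
  expect_false(bad2$feasible)
  # a sensible parameter vector is feasible with finite losses
  good <- combined_loss(c(0.007, 1), mod, s, dat, cfg)
  expect_true(good$feasible)
  expect_true(is.finite(good$combined))
  expect_equal(good$combined,
               log(good$l_pde) + log(good$l_gls))
})

test_that("the reaction feasibility integral matches the closed form", {
  # logistic reaction: int_0^uM R du = gamma (uM^2/2 - uM^3/(3K)) > 0
  gam <- 1.3; uM <- 0.8 * Kw
  gl <- pracma::gaussLegendre(64, 0, uM)
  quad <- sum(gl$w * evaluate_reaction("logistic", gam, gl$x, Kw))
  expect_equal(quad, gam * (uM^2 / 2 - uM^3 / (3 * Kw)), tolerance = 1e-12)
})

test_that("the basis-function fit solves linear models exactly", {
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  set.seed(33)
  u <- matrix(runif(40, 10, Kw), 8, 5)
  ux <- matrix(rnorm(40), 8, 5)
  uxx <- matrix(rnorm(40), 8, 5)
  theta <- c(0.0072, 1.056)
  s <- manual_sample(u = u, du_dt = 0.0072 * uxx + 1.056 * u * (1 - u / Kw),
                     du_dx = ux, d2u_dx2 = uxx)
  fit <- linear_basis_fit(mod, s)
  expect_equal(unname(fit$theta), theta, tolerance = 1e-10)
  expect_false(fit$rank_deficient)
  # porous-diffusivity variant
  modp <- mechanism_model("none", "porous", "logistic", Kw)
  sp <- manual_sample(
    u = u, du_dx = ux, d2u_dx2 = uxx,
    du_dt = 0.01 * (ux^2 + u * uxx) / Kw + 0.9 * u * (1 - u / Kw))
  fitp <- linear_basis_fit(modp, sp)
  expect_equal(unname(fitp$theta), c(0.01, 0.9), tolerance = 1e-10)
  # delay models are rejected
  modd <- mechanism_model("logistic", "constant", "logistic", Kw)
  expect_error(linear_basis_fit(modd, s), "delay-free")
  # rank-deficient design (flat field) falls back to the pseudoinverse
  sflat <- manual_sample(u = matrix(Kw, 4, 4), du_dt = matrix(0, 4, 4))
  expect_warning(linear_basis_fit(mod, sflat), "rank-deficient")
})

test_that("estimation descends from its starts and honours scales", {
  # noiseless data from the generating model; the sample is built from the
  # model identity so the loss has its optimum at the truth
  des <- study_design(mechanism_model("none", "constant", "logistic", 1.7e-3),
                      theta_true = c(301, 0.044), sigma_n = 0,
                      positions = seq(75, 1875, length.out = 12),
                      times = seq(0, 48, by = 12), replicates = 1)
  dat <- rescale_units(generate_study(des, Np_fine = 100))
  mod <- mechanism_model("none", "constant", "logistic", Kw)
  theta_w <- unname(working_parameters(mod, c(301, 0.044)))
  # build the sample from the solved field on a coarse grid
  mesh <- build_mesh(0.075, 1.875, 100)
  ic <- stats::approx(dat$positions, dat$densities[, 1, 1],
                      xout = mesh$nodes)$y
  sol <- solve_pde(mod, theta_w, ic, dat$times, mesh)
  xs <- seq(0.075, 1.875, length.out = 10)
  u <- extract_solution(sol, xs)
  h <- mesh$dx
  ix <- mechdisc:::nearest_lower(xs, mesh$nodes)
  ux <- (sol$values[pmin(ix + 1, 100), ] - sol$values[pmax(ix - 1, 1), ]) /
    (2 * h)
  uxx <- (sol$values[pmin(ix + 1, 100), ] - 2 * sol$values[ix, ] +
          sol$values[pmax(ix - 1, 1), ]) / h^2
  s <- manual_sample(u = u, du_dt = 0.0072 * uxx + 1.056 * u * (1 - u / Kw),
                     du_dx = ux, d2u_dx2 = uxx,
                     x_span = c(0.075, 1.875), t_span = c(0, 2))
  cfg <- fit_config(build_mesh(0.075, 1.875, 50),
                    sampled_ic(s, build_mesh(0.075, 1.875, 50)),
                    sigma_n = 85)
  est <- estimate_parameters(mod, s, dat, cfg, strategy = "lhs",
                             n_starts = 5, seed = 34)
  # descent: the fit is no worse than its feasible starts
  start_loss <- combined_loss(est$start, mod, s, dat, cfg)$combined
  expect_lte(est$loss$combined, start_loss)
  expect_equal(est$theta[1], theta_w[1], tolerance = 0.25)
  expect_equal(est$theta[2], theta_w[2], tolerance = 0.25)
  # a rescaled search recovers the same optimum
  est2 <- estimate_parameters(mod, s, dat, cfg, scales = theta_w,
                              strategy = "scaled")
  expect_equal(est2$theta[1], theta_w[1], tolerance = 0.25)
  expect_equal(est2$theta[2], theta_w[2], tolerance = 0.25)
})

test_that("thresholding masks extreme densities and rates", {
  u <- matrix(c(0, 500, 900, 1000), 2, 2)
  r <- matrix(c(0.1, 1, 2, 4), 2, 2)
  s <- manual_sample(u = u, du_dt = r)
  expect_true(all(threshold_data(s, c(0, 1), c(0, 1))))
  m <- threshold_data(s, delta_u = c(0.01, 1))
  expect_false(m[1, 1])
  expect_equal(sum(m), 3)
  flat <- manual_sample(u = u, du_dt = 0 * u)
  expect_error(threshold_data(flat, delta_t = c(0.1, 1)), "thresholding")
  expect_error(threshold_data(s, delta_u = c(0.5, 0.2)), "low < high")
})
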