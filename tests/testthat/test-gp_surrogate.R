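test_that("posterior mean interpolates the data as noise vanishes", {
  # 5 x 5 toy with test grid equal to the training grid
  dat <- toy_dataset(function(x, t) sin(x) + 0.3 * t, n_x = 5, n_t = 5)
  hyp <- gp_hyperparameters(2, 1e-7, 0.8, 1.2)
  # near-zero noise needs a larger stabilising nugget; irrelevant here
  sur <- suppressWarnings(joint_mean_cov(dat, hyp, unit_interval_grid(dat, 5, 5)))
  s0 <- sample_joint(sur, rep(0, 4 * sur$nm))
  expect_lt(max(abs(s0$u - dat$densities[, , 1])), 1e-6)
})

test_that("derivative blocks recover simple fields", {
  # constant field: all derivative blocks vanish
  datc <- toy_dataset(function(x, t) 3 + 0 * x, n_x = 8, n_t = 4,
                      sigma = 1e-4, seed = 4)
  hyp <- gp_hyperparameters(2, 1e-3, 0.6, 1.5)
  surc <- joint_mean_cov(datc, hyp, unit_interval_grid(datc, 8, 4))
  sc <- sample_joint(surc, rep(0, 4 * surc$nm))
  expect_lt(max(abs(sc$du_dt)), 1e-2)
  expect_lt(max(abs(sc$du_dx)), 1e-2)
  expect_lt(max(abs(sc$d2u_dx2)), 0.1)

  # linear-in-x field: du/dx recovers the slope on the physical scale
  a <- 2.5
  datl <- toy_dataset(function(x, t) a * x + 1, n_x = 10, n_t = 4,
                      sigma = 1e-4, seed = 5)
  surl <- joint_mean_cov(datl, hyp, unit_interval_grid(datl, 10, 4))
  sl <- sample_joint(surl, rep(0, 4 * surl$nm))
  expect_equal(mean(sl$du_dx), a, tolerance = 0.05)

  # shape contract of the joint posterior
  expect_equal(length(surl$mu), 4 * surl$nm)
  expect_equal(dim(surl$Sigma), c(4 * surl$nm, 4 * surl$nm))
})

test_that("block nuggets scale with trace ratios", {
  nm <- 3
  base <- diag(c(rep(1, nm), rep(4, nm), rep(2, nm), rep(7, nm)))
  out <- regularize_covariance(base, eta = 1e-5)
  added <- diag(out) - diag(base)
  expect_equal(added[1:nm], rep(1e-5, nm))
  expect_equal(added[nm + 1:nm], rep(4e-5, nm))
  expect_equal(added[2 * nm + 1:nm], rep(2e-5, nm))
  expect_equal(added[3 * nm + 1:nm], rep(7e-5, nm))

  # equal traces: every block gets the base nugget
  eq <- regularize_covariance(diag(4 * nm), eta = 1e-5)
  expect_equal(diag(eq), rep(1 + 1e-5, 4 * nm))

  expect_error(regularize_covariance(diag(c(rep(0, nm), rep(1, 3 * nm)))),
               "degenerate-surrogate")
})

test_that("nugget regularisation only raises the smallest eigenvalue", {
  set.seed(6)
  nm <- 4
  A <- matrix(rnorm(16 * nm * nm), 4 * nm)
  Sigma <- crossprod(A) / (4 * nm)
  out <- regularize_covariance(Sigma, eta = 1e-4)
  expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values),
             min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values))
})

test_that("joint sampling is exact at z = 0, deterministic, and calibrated", {
  dat <- toy_dataset(function(x, t) 1 + x * (1.8 - x) + 0.2 * t,
                     n_x = 6, n_t = 3, sigma = 0.05, seed = 7)
  hyp <- gp_hyperparameters(1.5, 0.05, 0.5, 1)
  sur <- joint_mean_cov(dat, hyp, unit_interval_grid(dat, 6, 3))
  s0 <- sample_joint(sur, rep(0, 4 * sur$nm))
  dxs <- diff(sur$grid$x_span); dts <- diff(sur$grid$t_span)
  expect_equal(as.vector(s0$u), sur$mu[seq_len(sur$nm)])
  expect_equal(as.vector(s0$du_dt), sur$mu[sur$nm + seq_len(sur$nm)] / dts)
  expect_equal(as.vector(s0$d2u_dx2),
               sur$mu[3 * sur$nm + seq_len(sur$nm)] / dxs^2)
  expect_error(sample_joint(sur, rep(0, 3)), "dimension error")

  set.seed(11); z <- rnorm(4 * sur$nm)
  expect_identical(sample_joint(sur, z), sample_joint(sur, z))

  # empirical variance of repeated draws matches Sigma (Monte-Carlo check)
  set.seed(12)
  draws <- replicate(4000, sample_joint(sur, rnorm(4 * sur$nm))$u[3, 2])
  idx <- (2 - 1) * sur$n + 3
  expect_equal(stats::var(draws), sur$Sigma[idx, idx], tolerance = 0.1)
})

test_that("multistart maximum likelihood recovers known hyperparameters", {
  # simulate from a known GP on a 21 x 20 grid (420 observations)
  true <- gp_hyperparameters(sigma_f = 1, sigma_n = 0.05, ell1 = 0.3,
                             ell2 = 0.4)
  pos <- seq(0, 1.8, length.out = 21)
  tim <- seq(0, 2, length.out = 20)
  xi <- to_unit_interval(pos, range(pos))
  tau <- to_unit_interval(tim, range(tim))
  X <- rbind(rep(xi, times = 20), rep(tau, each = 21))
  Kf <- mechdisc:::se_cov_matrix(X, X, true, "id", "id")
  set.seed(13)
  f <- as.vector(t(chol(Kf + 1e-10 * diag(420))) %*% rnorm(420))
  u <- f + rnorm(420, 0, true$sigma_n)
  dat <- density_dataset(pos, tim, array(u, c(21, 20, 1)),
                         units_state = "rescaled")
  fit <- fit_hyperparameters(dat, restarts = 6, seed = 14)
  expect_equal(fit$sigma_f, true$sigma_f, tolerance = 0.25)
  expect_equal(fit$sigma_n, true$sigma_n, tolerance = 0.25)
  expect_equal(fit$ell1, true$ell1, tolerance = 0.25)
  expect_equal(fit$ell2, true$ell2, tolerance = 0.25)
  # the returned fit attains the best marginal likelihood over restarts
  lls <- attr(fit, "restart_logliks")
  expect_equal(attr(fit, "loglik"), max(lls))
  expect_equal(gp_marginal_loglik(fit, dat), attr(fit, "loglik"),
               tolerance = 1e-6)
})
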