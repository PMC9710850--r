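# Shared fixtures, built in code at test time.

# Small rescaled dataset from a smooth field u(x, t) with optional noise.
toy_dataset <- function(f = function(x, t) 2 + 0 * x,
                        n_x = 8, n_t = 4, reps = 1, sigma = 0,
                        x_max = 1.8, t_max = 2, seed = 1) {
  pos <- seq(0, x_max, length.out = n_x)
  tim <- seq(0, t_max, length.out = n_t)
  u <- outer(pos, tim, f)
  set.seed(seed)
  arr <- array(rep(u, reps), c(n_x, n_t, reps)) +
    array(stats::rnorm(n_x * n_t * reps, 0, sigma), c(n_x, n_t, reps))
  density_dataset(pos, tim, arr, units_state = "rescaled")
}

# Hand-built function sample on an n x m grid (for loss-function tests).
manual_sample <- function(u, du_dt, du_dx = 0 * u, d2u_dx2 = 0 * u,
                          x_span = c(0, 1.8), t_span = c(0, 2)) {
  n <- nrow(u); m <- ncol(u)
  grid <- structure(
    list(xi = seq(0, 1, length.out = n), tau = seq(0, 1, length.out = m),
         x_span = x_span, t_span = t_span,
         xs = seq(x_span[1], x_span[2], length.out = n),
         ts = seq(t_span[1], t_span[2], length.out = m),
         n = n, m = m),
    class = "unit_grid")
  structure(list(u = u, du_dt = du_dt, du_dx = du_dx, d2u_dx2 = d2u_dx2,
                 z = NULL, grid = grid),
            class = "function_sample")
}

# Minimal ensemble with prescribed parameter draws (for summary tests).
manual_ensemble <- function(model, thetas, ubar = NULL, uhats = NULL,
                            level = 0.95) {
  draws <- lapply(seq_len(nrow(thetas)), function(b) {
    list(z_id = b, theta = thetas[b, ],
         theta_phys = physical_parameters(model, thetas[b, ]),
         uhat = if (is.null(uhats)) NULL else uhats[[b]],
         aicc = NA_real_, ok = TRUE)
  })
  structure(list(draws = draws, model = model, level = level,
                 B = nrow(thetas), scales = rep(1, ncol(thetas)),
                 sigma_n = 1, positions = NULL, times = c(0, 1, 2),
                 ubar = ubar, n_failed = 0),
            class = "bootstrap_ensemble")
}

# Write a long-format density table for I/O tests.
write_toy_table <- function(path, N = 3, M = 2, R = 1, sep = ",") {
  df <- expand.grid(position = seq(25, by = 50, length.out = N),
                    time = seq(0, by = 12, length.out = M),
                    replicate = seq_len(R))
  df$density <- stats::runif(nrow(df), 0, 2e-3)
  df <- df[, c("position", "time", "density", "replicate")]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  df
}
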