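#' Parametric mechanism library
#'
#' A `mechanism_model` is a triple of parametric forms for the delay
#' `T(t; alpha)`, nonlinear diffusivity `D(u; beta)`, and reaction
#' `R(u; gamma)` entering the invasion model
#' `du/dt = T(t) [ d/dx ( D(u) du/dx ) + R(u) ]`,
#' together with the fixed carrying capacity `K`. The delay multiplies
#' migration and proliferation equally and maps into (0, 1]; the diffusivity
#' describes density-dependent migration; the reaction describes
#' proliferation.
#'
#' Supported forms and their parameter counts:
#' delay `none` (0), `logistic`/`probit`/`cloglog` (2);
#' diffusivity `constant` (1), `porous` (1), `generalized` (3),
#' `extended` (5); reaction `logistic` (1), `gompertz` (1), `richards` (2).
#'
#' @param delay,diffusivity,reaction form names (see above).
#' @param K carrying capacity, in the density units the model is used with.
#' @param label optional display label.
#' @return An object of class `mechanism_model` with fields `a`, `d`, `r`
#'   (parameter counts), `par_names`, and `par_kinds` (unit classes used when
#'   converting between working and physical scales).
#' @export
mechanism_model <- function(delay = c("none", "logistic", "probit", "cloglog"),
                            diffusivity = c("constant", "porous",
                                            "generalized", "extended"),
                            reaction = c("logistic", "gompertz", "richards"),
                            K, label = NULL) {
  delay <- match.arg(delay)
  diffusivity <- match.arg(diffusivity)
  reaction <- match.arg(reaction)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive number")
  delay_info <- switch(delay,
    none = list(a = 0L, names = character(), kinds = character()),
    list(a = 2L, names = c("alpha1", "alpha2"), kinds = c("plain", "rate")))
  diff_info <- switch(diffusivity,
    constant = list(d = 1L, names = "beta1", kinds = "diffusivity"),
    porous = list(d = 1L, names = "beta2", kinds = "diffusivity"),
    generalized = list(d = 3L, names = paste0("beta", 1:3),
                       kinds = c("diffusivity", "diffusivity", "plain")),
    extended = list(d = 5L, names = paste0("beta", 1:5),
                    kinds = c("diffusivity", "diffusivity", "plain",
                              "diffusivity", "plain")))
  reac_info <- switch(reaction,
    logistic = list(r = 1L, names = "gamma1", kinds = "rate"),
    gompertz = list(r = 1L, names = "gamma1", kinds = "rate"),
    richards = list(r = 2L, names = c("gamma1", "gamma2"),
                    kinds = c("rate", "plain")))
  if (is.null(label))
    label <- sprintf("T=%s, D=%s, R=%s", delay, diffusivity, reaction)
  structure(
    list(delay_form = delay, diffusivity_form = diffusivity,
         reaction_form = reaction, K = K,
         a = delay_info$a, d = diff_info$d, r = reac_info$r,
         par_names = c(delay_info$names, diff_info$names, reac_info$names),
         par_kinds = c(delay_info$kinds, diff_info$kinds, reac_info$kinds),
         label = label),
    class = "mechanism_model")
}

#' @export
print.mechanism_model <- function(x, ...) {
  cat(sprintf("mechanism_model: %s (a = %d, d = %d, r = %d; K = %.6g)\n",
              x$label, x$a, x$d, x$r, x$K))
  invisible(x)
}

#' Total number of mechanism parameters
#'
#' @param model a [mechanism_model()].
#' @return `a + d + r`.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "mechanism_model"))
  model$a + model$d + model$r
}

#' Evaluate a delay mechanism
#'
#' All delay forms map into (0, 1] and are non-decreasing in `t` when the
#' rate parameter is positive. `none` is identically 1.
#'
#' @param form delay form name.
#' @param alpha parameter vector (length 0 for `none`, 2 otherwise).
#' @param t time (vectorised).
#' @return Delay values, same length as `t`.
#' @export
evaluate_delay <- function(form, alpha, t) {
  expected <- if (form == "none") 0L else 2L
  if (length(alpha) != expected)
    stop("parameter error: delay form '", form, "' needs ", expected,
         " parameter(s)")
  switch(form,
    none = rep(1, length(t)),
    logistic = 1 / (1 + exp(-alpha[1] - alpha[2] * t)),
    probit = stats::pnorm(alpha[1] + alpha[2] * t),
    cloglog = 1 - exp(-exp(alpha[1] + alpha[2] * t)),
    stop("unknown delay form: ", form))
}

#' Evaluate a diffusivity mechanism and its density derivative
#'
#' Returns both `D(u)` and `dD/du`, which the PDE-residual loss needs for
#' the expanded flux term. No positivity clamping is applied: physical
#' feasibility is enforced by the loss, not here. The convention
#' `(u/K)^b = 0` at `u = 0` is used for positive exponents `b`.
#'
#' @param form diffusivity form name.
#' @param beta parameter vector (length 1, 1, 3, or 5 by form).
#' @param u density (vectorised, `u >= 0` when exponents are non-integer).
#' @param K carrying capacity.
#' @return A list with vectors `D` and `dD`.
#' @export
evaluate_diffusivity <- function(form, beta, u, K) {
  expected <- switch(form, constant = 1L, porous = 1L,
                     generalized = 3L, extended = 5L,
                     stop("unknown diffusivity form: ", form))
  if (length(beta) != expected)
    stop("parameter error: diffusivity form '", form, "' needs ", expected,
         " parameter(s)")
  pow_terms <- switch(form, generalized = beta[3],
                      extended = beta[c(3, 5)], numeric())
  if (any(u < 0) && any(pow_terms != round(pow_terms)))
    stop("domain error: negative density with non-integer exponent")
  switch(form,
    constant = list(D = rep(beta[1], length(u)), dD = rep(0, length(u))),
    porous = list(D = beta[1] * u / K, dD = rep(beta[1] / K, length(u))),
    generalized = {
      if (any(u == 0) && beta[3] <= 0)
        stop("domain error: non-positive exponent at zero density")
      s <- u / K
      list(D = beta[1] + beta[2] * s^beta[3],
           dD = beta[2] * beta[3] * s^(beta[3] - 1) / K)
    },
    extended = {
      if (any(u == 0) && any(beta[c(3, 5)] <= 0))
        stop("domain error: non-positive exponent at zero density")
      s <- u / K
      list(D = beta[1] + beta[2] * s^beta[3] + beta[4] * s^beta[5],
           dD = (beta[2] * beta[3] * s^(beta[3] - 1) +
                 beta[4] * beta[5] * s^(beta[5] - 1)) / K)
    })
}

#' Evaluate a reaction mechanism
#'
#' Logistic: `gamma1 u (1 - u/K)`; Gompertz: `gamma1 u log(K/u)` with the
#' limit value 0 at `u = 0`; Richards: `gamma1 u (1 - (u/K)^gamma2)`.
#' All three vanish at `u = K`.
#'
#' @param form reaction form name.
#' @param gamma parameter vector (length 1, 1, or 2 by form).
#' @param u density (vectorised, non-negative).
#' @param K carrying capacity.
#' @return Reaction values, same length as `u`.
#' @export
evaluate_reaction <- function(form, gamma, u, K) {
  expected <- switch(form, logistic = 1L, gompertz = 1L, richards = 2L,
                     stop("unknown reaction form: ", form))
  if (length(gamma) != expected)
    stop("parameter error: reaction form '", form, "' needs ", expected,
         " parameter(s)")
  switch(form,
    logistic = gamma[1] * u * (1 - u / K),
    gompertz = ifelse(u == 0, 0, gamma[1] * u * log(K / u)),
    richards = gamma[1] * u * (1 - (u / K)^gamma[2]))
}

# Bind a parameter vector to a model, returning fast closures for the delay,
# diffusivity (value and derivative), and reaction terms.
model_functions <- function(model, theta) {
  stopifnot(inherits(model, "mechanism_model"))
  theta <- as.numeric(theta)
  if (length(theta) != n_parameters(model))
    stop("parameter error: expected ", n_parameters(model), " parameters")
  alpha <- theta[seq_len(model$a)]
  beta <- theta[model$a + seq_len(model$d)]
  gamma <- theta[model$a + model$d + seq_len(model$r)]
  K <- model$K
  list(
    alpha = alpha, beta = beta, gamma = gamma,
    Tf = function(t) evaluate_delay(model$delay_form, alpha, t),
    Df = function(u) evaluate_diffusivity(model$diffusivity_form, beta, u, K),
    Rf = function(u) evaluate_reaction(model$reaction_form, gamma, u, K))
}

#' The five canonical candidate models
#'
#' The default candidate set combines no-delay/logistic-delay with constant
#' (Fisher-Kolmogorov), degenerate linear-in-density (Porous-Fisher), and
#' generalised Porous-FKPP diffusivities, all with logistic proliferation:
#' model 1 `T = 1, D = beta1`; model 2 adds logistic delay; model 3
#' `T = 1, D = beta2 u/K`; model 4 adds logistic delay; model 5 logistic
#' delay with `D = beta1 + beta2 (u/K)^beta3`. Total parameter counts are
#' 2, 4, 2, 4, and 6.
#'
#' @param K carrying capacity shared by all candidates.
#' @return A named list of five [mechanism_model()] objects.
#' @export
model_catalog <- function(K) {
  list(
    model1 = mechanism_model("none", "constant", "logistic", K,
                             label = "Fisher-Kolmogorov"),
    model2 = mechanism_model("logistic", "constant", "logistic", K,
                             label = "Fisher-Kolmogorov with delay"),
    model3 = mechanism_model("none", "porous", "logistic", K,
                             label = "Porous-Fisher"),
    model4 = mechanism_model("logistic", "porous", "logistic", K,
                             label = "Porous-Fisher with delay"),
    model5 = mechanism_model("logistic", "generalized", "logistic", K,
                             label = "Generalised Porous-FKPP with delay"))
}

# Unit conversion factors between working-scale parameters (mm, d, u x 1e6)
# and physical-scale parameters (um, h, cells um^-2).
.kind_to_physical <- c(plain = 1, rate = 1 / 24, diffusivity = 1e6 / 24)

#' Convert working-scale parameters to physical units
#'
#' Estimation runs on the rescaled working units (mm, days, densities x 1e6);
#' reporting uses the original units (rates in per hour, diffusivities in
#' square micrometres per hour, delay intercepts dimensionless).
#'
#' @param model a [mechanism_model()].
#' @param theta parameter vector on the working scale.
#' @return Named parameter vector in physical units.
#' @export
physical_parameters <- function(model, theta) {
  stopifnot(inherits(model, "mechanism_model"))
  out <- as.numeric(theta) * .kind_to_physical[model$par_kinds]
  names(out) <- model$par_names
  out
}

#' Convert physical-unit parameters to the working scale
#'
#' Inverse of [physical_parameters()].
#'
#' @inheritParams physical_parameters
#' @param theta parameter vector in physical units.
#' @return Named parameter vector on the working scale.
#' @export
working_parameters <- function(model, theta) {
  stopifnot(inherits(model, "mechanism_model"))
  out <- as.numeric(theta) / .kind_to_physical[model$par_kinds]
  names(out) <- model$par_names
  out
}
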