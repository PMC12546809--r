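#' Model-parameter constructors for the cognitive-state dynamics
#'
#' Each equation of the state model keeps its own namespaced parameter set so
#' reused Greek letters never collide across equations.
#'
#' * `ef_params()`: weights of the executive-function composite
#'   `EF = a1*WM + a2*IC + a3*CF + noise`.
#' * `tc_params()`: weights and integer session lags of the
#'   tactical-cognition composite
#'   `TC(t) = b1*SA(t-d1) + b2*PR(t-d2) + b3*DM(t-d3) + b4*SP(t-d4)`.
#' * `performance_params()`: weights of the interaction model
#'   `Performance = g1*EF*TC + g2*EF + g3*TC + noise`.
#' * `update_params()`: session-update rates — `rho` for the EF component
#'   deltas, `lambda_fb` for the feedback term, `mu` for the TC component
#'   deltas, `phi_context` and `psi_transfer` for contextual and
#'   cross-domain transfer inputs.
#' * `plasticity_params()`: BCM learning rate `eta`, plasticity threshold
#'   `theta_j`, initial weight `w0` and the STDP kernel time constant.
#' * `adaptation_params()`: neural-plasticity coefficient, decay constant,
#'   practice weight and baseline feedback level of the training-adaptation
#'   function.
#' * `cpi_weights()`: per-domain weights and normalization constants of the
#'   cognitive performance index.
#'
#' @param alpha Length-3 weights (WM, IC, CF).
#' @param noise_sd Noise SD in score units.
#' @name dynamics_params
NULL

#' @rdname dynamics_params
#' @export
ef_params <- function(alpha = c(1, 1, 1) / 3, noise_sd = 0) {
  stopifnot(length(alpha) == 3, all(is.finite(alpha)), noise_sd >= 0)
  structure(list(alpha = alpha, noise_sd = noise_sd), class = "ef_params")
}

#' @rdname dynamics_params
#' @param beta Length-4 weights (SA, PR, DM, SP).
#' @param delays Length-4 nonnegative integer session lags.
#' @export
tc_params <- function(beta = c(1, 1, 1, 1) / 4, delays = c(0, 0, 0, 0)) {
  stopifnot(length(beta) == 4, all(is.finite(beta)),
            length(delays) == 4, all(delays >= 0),
            all(delays == round(delays)))
  structure(list(beta = beta, delays = as.integer(delays)),
            class = "tc_params")
}

#' @rdname dynamics_params
#' @param gamma Length-3 weights (interaction, EF, TC).
#' @export
performance_params <- function(gamma = c(0.01, 0.5, 0.5), noise_sd = 0) {
  stopifnot(length(gamma) == 3, all(is.finite(gamma)), noise_sd >= 0)
  structure(list(gamma = gamma, noise_sd = noise_sd),
            class = "performance_params")
}

#' @rdname dynamics_params
#' @param rho Length-3 nonnegative EF learning rates (WM, IC, CF deltas).
#' @param lambda_fb Feedback coefficient.
#' @param mu Nonnegative per-TC-component learning rates.
#' @param phi_context Context coefficient.
#' @param psi_transfer Cross-domain transfer coefficient.
#' @export
update_params <- function(rho = c(1, 1, 1), lambda_fb = 0,
                          mu = c(1, 1, 1, 1), phi_context = 0,
                          psi_transfer = 0) {
  stopifnot(all(rho >= 0), all(mu >= 0))
  structure(list(rho = rho, lambda_fb = lambda_fb, mu = mu,
                 phi_context = phi_context, psi_transfer = psi_transfer),
            class = "update_params")
}

#' @rdname dynamics_params
#' @param eta BCM/STDP learning rate (>= 0).
#' @param theta_j Plasticity threshold.
#' @param w0 Initial synaptic weight (> 0 whenever a relative index is
#'   computed).
#' @param stdp_tau STDP kernel time constant in seconds (> 0).
#' @export
plasticity_params <- function(eta = 0.01, theta_j = 1, w0 = 1,
                              stdp_tau = 0.02) {
  stopifnot(eta >= 0, stdp_tau > 0)
  structure(list(eta = eta, theta_j = theta_j, w0 = w0,
                 stdp_tau = stdp_tau),
            class = "plasticity_params")
}

#' @rdname dynamics_params
#' @param lambda_ta Neural-plasticity coefficient.
#' @param delta_ta Decay constant (>= 0), per session.
#' @param beta_practice Practice-effect weight.
#' @param nf0 Baseline neural-feedback value.
#' @export
adaptation_params <- function(lambda_ta = 1, delta_ta = 0.1,
                              beta_practice = 0, nf0 = 0) {
  stopifnot(delta_ta >= 0)
  structure(list(lambda_ta = lambda_ta, delta_ta = delta_ta,
                 beta_practice = beta_practice, nf0 = nf0),
            class = "adaptation_params")
}

#' @rdname dynamics_params
#' @param weights Named nonnegative per-domain weights, not all zero.
#' @param norm_ref Named per-domain normalization constants (> 0); defaults
#'   to 100 for every weighted domain.
#' @export
cpi_weights <- function(weights, norm_ref = NULL) {
  if (is.null(names(weights)) || any(weights < 0)) {
    config_error("`weights` must be named and >= 0")
  }
  if (sum(weights) <= 0) config_error("weights must not all be zero")
  norm_ref <- norm_ref %||% setNames(rep(100, length(weights)),
                                     names(weights))
  structure(list(weights = weights, norm_ref = norm_ref),
            class = "cpi_weights")
}

#' Executive-function composite score
#'
#' `EF = a1*WM + a2*IC + a3*CF + e`, with `e ~ N(0, noise_sd^2)`.
#'
#' @param state List or one-row data frame with components `wm`, `ic`, `cf`.
#' @param p An [ef_params()].
#' @param noise_seed Optional integer seed for the noise draw.
#' @return EF value.
#' @export
#' @examples
#' ef_score(list(wm = 72.4, ic = 68.1, cf = 65.9), ef_params())
ef_score <- function(state, p = ef_params(), noise_seed = NULL) {
  stopifnot(inherits(p, "ef_params"))
  eps <- if (p$noise_sd > 0) {
    if (is.null(noise_seed)) rnorm(1, 0, p$noise_sd)
    else withr::with_seed(noise_seed, rnorm(1, 0, p$noise_sd))
  } else 0
  p$alpha[1] * state$wm + p$alpha[2] * state$ic + p$alpha[3] * state$cf + eps
}

#' Tactical-cognition composite with component lags
#'
#' `TC(t) = b1*SA(t-d1) + b2*PR(t-d2) + b3*DM(t-d3) + b4*SP(t-d4)` at the
#' final session of `history`.
#'
#' @param history Data frame ordered by session with columns `sa`, `pr`,
#'   `dm`, `sp`; must be at least `max(delays) + 1` rows long.
#' @param p A [tc_params()].
#' @return TC value at the last session.
#' @export
tc_score <- function(history, p = tc_params()) {
  stopifnot(inherits(p, "tc_params"))
  n <- nrow(history)
  if (n < max(p$delays) + 1L) {
    abort("history shorter than the largest component lag",
          class = "neurotrainr_lag_error")
  }
  comps <- c("sa", "pr", "dm", "sp")
  sum(vapply(seq_along(comps), function(i) {
    p$beta[i] * history[[comps[i]]][n - p$delays[i]]
  }, numeric(1)))
}

#' Performance interaction model
#'
#' `Performance = g1*EF*TC + g2*EF + g3*TC + noise`; the interaction term
#' carries the synergy between executive function and tactical cognition.
#'
#' @param ef,tc Composite scores.
#' @param p A [performance_params()].
#' @param noise_seed Optional integer seed for the noise draw.
#' @return Performance value.
#' @export
performance_score <- function(ef, tc, p = performance_params(),
                              noise_seed = NULL) {
  stopifnot(inherits(p, "performance_params"), is.finite(ef), is.finite(tc))
  eta <- if (p$noise_sd > 0) {
    if (is.null(noise_seed)) rnorm(1, 0, p$noise_sd)
    else withr::with_seed(noise_seed, rnorm(1, 0, p$noise_sd))
  } else 0
  p$gamma[1] * ef * tc + p$gamma[2] * ef + p$gamma[3] * tc + eta
}

#' One session update of the executive-function composite
#'
#' `EF(t+1) = EF(t) + rho1*dWM + rho2*dIC + rho3*dCF + lambda*FB`, clamped to
#' \[0, 100\]; the returned value carries attribute `n_clamped`.
#'
#' @param ef Current EF value.
#' @param deltas Length-3 numeric `(dWM, dIC, dCF)`.
#' @param feedback Feedback value `FB(t)` (unitless).
#' @param p An [update_params()].
#' @return Next EF value (attribute `n_clamped` reports clamping).
#' @export
ef_step <- function(ef, deltas, feedback = 0, p = update_params()) {
  stopifnot(inherits(p, "update_params"), length(deltas) == 3)
  clamp_score(ef + sum(p$rho * deltas) + p$lambda_fb * feedback)
}

#' One session update of the tactical-cognition composite
#'
#' `TC(t+1) = TC(t) + sum_i mu_i*dTC_i + phi*Context + psi*Transfer`,
#' clamped to \[0, 100\].
#'
#' @param tc Current TC value.
#' @param component_deltas Numeric vector of per-component TC increments
#'   (length must match `p$mu`).
#' @param context Exogenous context value.
#' @param transfer Cross-domain transfer value (typically the session's EF
#'   gain times a coupling constant).
#' @param p An [update_params()].
#' @return Next TC value (attribute `n_clamped` reports clamping).
#' @export
tc_step <- function(tc, component_deltas, context = 0, transfer = 0,
                    p = update_params()) {
  stopifnot(inherits(p, "update_params"))
  mu <- p$mu[seq_along(component_deltas)]
  clamp_score(tc + sum(mu * component_deltas) +
                p$phi_context * context + p$psi_transfer * transfer)
}

#' BCM synaptic weight change
#'
#' `dw = eta * y * (y - theta) * x`: postsynaptic activity above the
#' threshold potentiates, activity between zero and the threshold depresses.
#'
#' @param x_pre Presynaptic input.
#' @param y_post Postsynaptic activity.
#' @param p A [plasticity_params()].
#' @return Weight change.
#' @export
#' @examples
#' bcm_delta(0.5, 2, plasticity_params(eta = 0.1, theta_j = 1))
bcm_delta <- function(x_pre, y_post, p = plasticity_params()) {
  stopifnot(inherits(p, "plasticity_params"))
  p$eta * y_post * (y_post - p$theta_j) * x_pre
}

#' Training adaptation function
#'
#' `TA(t) = lambda * (NF(t) - NF0) * exp(-delta * t) + beta * Practice(t)`:
#' the feedback-driven component decays with the session index at rate
#' `delta`, leaving the practice effect as the long-run floor.
#'
#' @param nf_t Current neural-feedback value `NF(t)`.
#' @param t Session index (>= 0).
#' @param practice_t Practice-effect value `Practice(t)`.
#' @param p An [adaptation_params()].
#' @return TA value.
#' @export
training_adaptation <- function(nf_t, t, practice_t = 0,
                                p = adaptation_params()) {
  stopifnot(inherits(p, "adaptation_params"), t >= 0)
  p$lambda_ta * (nf_t - p$nf0) * exp(-p$delta_ta * t) +
    p$beta_practice * practice_t
}

#' Synaptic modification index
#'
#' `SMI = dw / w0` with
#' `dw = eta * int f_pre(t) * [int g(tau) f_post(t + tau) dtau] dt`,
#' where `g` is a two-sided exponential STDP kernel of time constant
#' `stdp_tau`, normalized to unit integral. Both integrals are evaluated by
#' trapezoidal quadrature; the kernel is truncated at eight time constants.
#'
#' @param pre_rate_fn,post_rate_fn Rate functions of time (vectorized).
#' @param window Length-2 numeric integration window in seconds.
#' @param p A [plasticity_params()] with `w0 > 0`.
#' @param dt Quadrature step (default `stdp_tau / 20`).
#' @return SMI value.
#' @export
smi <- function(pre_rate_fn, post_rate_fn, window, p = plasticity_params(),
                dt = NULL) {
  stopifnot(inherits(p, "plasticity_params"))
  if (p$w0 <= 0) domain_error("`w0` must be > 0")
  dt <- dt %||% (p$stdp_tau / 20)
  tau_max <- 8 * p$stdp_tau
  tau <- seq(-tau_max, tau_max, by = dt)
  g <- exp(-abs(tau) / p$stdp_tau)
  g <- g / pracma::trapz(tau, g)
  t_grid <- seq(window[1], window[2], by = dt)
  inner <- vapply(t_grid, function(tt) {
    pracma::trapz(tau, g * post_rate_fn(tt + tau))
  }, numeric(1))
  dw <- p$eta * pracma::trapz(t_grid, pre_rate_fn(t_grid) * inner)
  dw / p$w0
}

#' Cognitive performance index
#'
#' Weighted mean of normalized domain scores:
#' `CPI = sum_i w_i * (C_i / norm_i) / sum_i w_i`.
#'
#' @param domain_scores Named numeric vector of domain scores; names must
#'   appear in `w$weights`.
#' @param w A [cpi_weights()].
#' @return CPI value.
#' @export
#' @examples
#' cpi(c(a = 80, b = 60), cpi_weights(c(a = 3, b = 1)))
cpi <- function(domain_scores, w) {
  stopifnot(inherits(w, "cpi_weights"))
  doms <- names(domain_scores)
  if (!all(doms %in% names(w$weights))) {
    config_error("every scored domain needs a weight")
  }
  wi <- w$weights[doms]
  sum(wi * domain_scores / w$norm_ref[doms]) / sum(wi)
}
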