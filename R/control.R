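#' Training-task catalog
#'
#' The six task families of the training protocol with their admissible
#' difficulty-level ranges and session durations.
#'
#' @return Tibble with columns `task_type`, `level_min`, `level_max`,
#'   `duration_min_lo`, `duration_min_hi`.
#' @export
task_catalog <- function() {
  tibble::tribble(
    ~task_type,              ~level_min, ~level_max, ~duration_min_lo, ~duration_min_hi,
    "working_memory_update",         1L,         5L,               15,               20,
    "inhibitory_control",            1L,         4L,               12,               18,
    "cognitive_flexibility",         1L,         3L,               10,               15,
    "tactical_recognition",          1L,         6L,               20,               25,
    "strategic_planning",            1L,         4L,               18,               22,
    "integrated_scenarios",          1L,         5L,               25,               30
  )
}

#' Look up one task specification
#'
#' @param task_type One of the `task_type` values of [task_catalog()].
#' @return One-row tibble.
#' @export
task_spec <- function(task_type) {
  cat_ <- task_catalog()
  row <- cat_[cat_$task_type == task_type, ]
  if (nrow(row) != 1L) {
    config_error(sprintf("unknown task type '%s'", task_type))
  }
  row
}

#' Difficulty-adaptation parameters
#'
#' @param alpha_perf Gain on the performance gap (target minus current).
#' @param beta_load Gain on the neural-load signal.
#' @param target_performance Target performance score.
#' @return A `difficulty_params` list.
#' @export
difficulty_params <- function(alpha_perf = 0.05, beta_load = -0.01,
                              target_performance = 85) {
  stopifnot(is.finite(alpha_perf), is.finite(beta_load),
            is.finite(target_performance))
  structure(list(alpha_perf = alpha_perf, beta_load = beta_load,
                 target_performance = target_performance),
            class = "difficulty_params")
}

#' One step of adaptive difficulty control
#'
#' `level(t+1) = level(t) + alpha * (target - current) + beta * load`,
#' clamped to the task's admissible level range. Difficulty is held
#' continuous internally; round only at task-presentation time to avoid
#' quantization limit cycles.
#'
#' @param level Current (real-valued) difficulty level.
#' @param current_perf Current performance score.
#' @param neural_load Neural-load signal.
#' @param p A [difficulty_params()].
#' @param task A row of [task_catalog()] (or a `task_type` string).
#' @return Next difficulty level within the task range.
#' @export
#' @examples
#' difficulty_step(3, 75, 20, difficulty_params(0.1, -0.05, 85),
#'                 "working_memory_update")
difficulty_step <- function(level, current_perf, neural_load,
                            p = difficulty_params(),
                            task = "working_memory_update") {
  stopifnot(inherits(p, "difficulty_params"))
  if (is.character(task)) task <- task_spec(task)
  nxt <- level + p$alpha_perf * (p$target_performance - current_perf) +
    p$beta_load * neural_load
  min(max(nxt, task$level_min), task$level_max)
}

#' Feedback-selection policy
#'
#' @param actions Character vector of feedback actions (default the three
#'   feedback types the trainer can deliver).
#' @param discount Discount factor `gamma` in \[0, 1).
#' @param horizon Planning horizon in steps (>= 1).
#' @return A `feedback_policy` list.
#' @export
feedback_policy <- function(actions = c("reward_tone", "visual_gauge",
                                        "difficulty_hint"),
                            discount = 0.9, horizon = 5L) {
  if (length(actions) < 1) config_error("action set must be non-empty")
  check_number(discount, "discount", lower = 0, upper = 1 - 1e-12)
  stopifnot(horizon >= 1)
  structure(list(actions = actions, discount = discount,
                 horizon = as.integer(horizon)),
            class = "feedback_policy")
}

#' Select the feedback action maximizing expected discounted return
#'
#' Finite-horizon backward induction on a discrete model of coarse
#' cognitive-state bins: `V_0 = 0`,
#' `V_k(s) = max_a sum_s' T[s,a,s'] (R[s,a,s'] + gamma V_{k-1}(s'))`, and
#' the returned action is the argmax at the queried state with ties broken
#' by action order.
#'
#' @param state State name (must index the first dimension of `transition`).
#' @param policy A [feedback_policy()].
#' @param transition 3-d array `[state, action, next_state]` of transition
#'   probabilities (rows of each action slice sum to 1); dimnames give the
#'   state and action labels.
#' @param reward Reward specification: either a 3-d array conformable with
#'   `transition`, or a function `(s, a, s2) -> numeric`.
#' @return The selected action (character scalar), with attribute `value`
#'   giving its expected discounted return.
#' @export
select_feedback <- function(state, policy, transition, reward) {
  stopifnot(inherits(policy, "feedback_policy"))
  states <- dimnames(transition)[[1]]
  actions <- dimnames(transition)[[2]]
  if (!setequal(actions, policy$actions)) {
    config_error("transition actions must match the policy's action set")
  }
  actions <- policy$actions  # tie-break order is the policy's order
  r_arr <- if (is.function(reward)) {
    arr <- array(0, dim = dim(transition), dimnames = dimnames(transition))
    for (s in states) for (a in actions) for (s2 in states) {
      arr[s, a, s2] <- reward(s, a, s2)
    }
    arr
  } else {
    reward
  }
  v <- setNames(rep(0, length(states)), states)
  q <- NULL
  for (k in seq_len(policy$horizon)) {
    q <- sapply(actions, function(a) {
      vapply(states, function(s) {
        sum(transition[s, a, ] * (r_arr[s, a, ] + policy$discount * v))
      }, numeric(1))
    })
    v <- apply(q, 1, max)
  }
  qs <- q[state, ]
  best <- actions[which.max(qs)]  # which.max keeps the first (ordered) tie
  structure(best, value = unname(qs[which.max(qs)]))
}

#' Stability criterion settings
#'
#' @param x_equilibrium Target state vector.
#' @param v0 Initial squared deviation (>= 0); defaults to the trajectory's
#'   own first value.
#' @param delta_rate Required convergence rate (>= 0); 0 means "estimate it".
#' @return A `stability_criterion` list.
#' @export
stability_criterion <- function(x_equilibrium, v0 = NULL, delta_rate = 0) {
  stopifnot(is.numeric(x_equilibrium), delta_rate >= 0)
  if (!is.null(v0)) stopifnot(v0 >= 0)
  structure(list(x_equilibrium = x_equilibrium, v0 = v0,
                 delta_rate = delta_rate),
            class = "stability_criterion")
}

#' Check exponential (Lyapunov) convergence of a state trajectory
#'
#' Computes the squared deviation `V(t) = ||x(t) - x_eq||^2` and tests
#' whether it stays below the exponential envelope `V0 * exp(-delta * t)`
#' (with 1% slack) for a positive decay rate. When `crit$delta_rate` is 0
#' the rate is estimated by log-linear regression of `V(t)` on `t`.
#'
#' @param trajectory Numeric matrix or data frame, rows = time points,
#'   columns = state components.
#' @param crit A [stability_criterion()].
#' @return List with `stable` (logical), `rate` (fitted or supplied decay
#'   rate), and `V` (the deviation series).
#' @export
lyapunov_check <- function(trajectory, crit) {
  stopifnot(inherits(crit, "stability_criterion"))
  x <- as.matrix(as.data.frame(trajectory))
  if (nrow(x) < 3) {
    abort("trajectory must have at least 3 time points",
          class = "neurotrainr_data_error")
  }
  dev <- sweep(x, 2, crit$x_equilibrium)
  v <- rowSums(dev^2)
  t_idx <- seq_along(v) - 1
  if (all(v < 1e-12)) {
    return(list(stable = TRUE, rate = Inf, V = v))
  }
  v0 <- crit$v0 %||% v[1]
  rate <- crit$delta_rate
  if (rate == 0) {
    pos <- v > 0
    fit <- lm(log(v[pos]) ~ t_idx[pos])
    rate <- -unname(coef(fit)[2])
  }
  stable <- rate > 0 && all(v <= v0 * exp(-rate * t_idx) * 1.01 + 1e-12)
  list(stable = stable, rate = rate, V = v)
}
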