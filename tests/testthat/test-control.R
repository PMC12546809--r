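test_that("task catalog carries the protocol's difficulty ranges", {
  cat_ <- task_catalog()
  expect_equal(task_spec("working_memory_update")$level_max, 5L)
  expect_equal(task_spec("cognitive_flexibility")$level_max, 3L)
  expect_equal(task_spec("tactical_recognition")$level_max, 6L)
  expect_true(all(cat_$level_min == 1L))
  expect_error(task_spec("juggling"), class = "neurotrainr_config_error")
})

test_that("difficulty adaptation holds its equilibrium and its bounds", {
  p <- difficulty_params(alpha_perf = 0.1, beta_load = -0.05,
                         target_performance = 85)
  expect_equal(difficulty_step(3, 85, 0, p), 3)
  expect_equal(difficulty_step(3, 75, 20, p), 3)  # +1 gap, -1 load
  expect_equal(difficulty_step(5, 40, 0, p, "working_memory_update"), 5)
  # levels stay in range for every task under aggressive drives
  for (tt in task_catalog()$task_type) {
    ts <- task_spec(tt)
    lvl <- ts$level_min
    for (i in 1:50) {
      lvl <- difficulty_step(lvl, 10, -50,
                             difficulty_params(0.5, 0.5, 95), tt)
      expect_gte(lvl, ts$level_min)
      expect_lte(lvl, ts$level_max)
    }
  }
})

test_that("closed-loop difficulty converges for a monotone responder", {
  # synthetic responder: performance rises 6 points per difficulty level
  perf_of <- function(level) 55 + 6 * level
  p <- difficulty_params(alpha_perf = 0.05, beta_load = 0,
                         target_performance = 85)
  lvl <- 1
  for (i in 1:200) {
    lvl <- difficulty_step(lvl, perf_of(lvl), 0, p, "tactical_recognition")
  }
  expect_lt(abs(lvl - 5), 0.25)  # 85 = 55 + 6 * 5
})

test_that("feedback selection matches exhaustive rollout enumeration", {
  states <- c("low", "mid", "high")
  actions <- c("reward_tone", "visual_gauge")
  # deterministic chain: reward_tone moves up one bin, visual_gauge stays
  tr <- array(0, c(3, 2, 3), dimnames = list(states, actions, states))
  tr["low", "reward_tone", "mid"] <- 1
  tr["mid", "reward_tone", "high"] <- 1
  tr["high", "reward_tone", "high"] <- 1
  tr["low", "visual_gauge", "low"] <- 1
  tr["mid", "visual_gauge", "mid"] <- 1
  tr["high", "visual_gauge", "high"] <- 1
  # reward: being in high pays 1, stepping up pays 0.2, staying costs 0
  rew <- function(s, a, s2) (s2 == "high") * 1 + (s2 != s) * 0.2
  pol <- feedback_policy(actions, discount = 0.9, horizon = 5)
  chosen <- select_feedback("low", pol, tr, rew)

  # oracle: enumerate all 2^5 open-loop action sequences on the
  # deterministic chain
  seqs <- expand.grid(rep(list(actions), 5), stringsAsFactors = FALSE)
  ret_of <- function(acts) {
    s <- "low"
    tot <- 0
    for (k in seq_along(acts)) {
      s2 <- states[which(tr[s, acts[k], ] == 1)]
      tot <- tot + 0.9^(k - 1) * rew(s, acts[k], s2)
      s <- s2
    }
    tot
  }
  rets <- apply(seqs, 1, function(row) ret_of(as.character(row)))
  best_first <- as.character(seqs[which.max(rets), 1])
  expect_equal(as.character(chosen), best_first)
  expect_equal(attr(chosen, "value"), max(rets), tolerance = 1e-12)

  # single action: no choice
  tr1 <- tr[, "reward_tone", , drop = FALSE]
  pol1 <- feedback_policy("reward_tone", discount = 0.9, horizon = 3)
  expect_equal(as.character(select_feedback("low", pol1, tr1, rew)),
               "reward_tone")
  # myopic limit: discount 0 picks the best immediate reward
  pol0 <- feedback_policy(actions, discount = 0, horizon = 4)
  expect_equal(as.character(select_feedback("mid", pol0, tr, rew)),
               "reward_tone")
  expect_error(feedback_policy(character(0)),
               class = "neurotrainr_config_error")
})

test_that("feedback choice is invariant to affine reward transforms", {
  states <- c("a", "b")
  actions <- c("reward_tone", "visual_gauge")
  tr <- array(0.5, c(2, 2, 2), dimnames = list(states, actions, states))
  tr["a", "reward_tone", ] <- c(0.2, 0.8)
  tr["b", "visual_gauge", ] <- c(0.9, 0.1)
  rew <- function(s, a, s2) (s2 == "b") * 2 + (a == "reward_tone") * 0.3
  pol <- feedback_policy(actions, discount = 0.8, horizon = 4)
  base <- select_feedback("a", pol, tr, rew)
  shifted <- select_feedback("a", pol, tr,
                             function(s, a, s2) 5 * rew(s, a, s2) + 7)
  expect_equal(as.character(base), as.character(shifted))
})

test_that("Lyapunov check classifies decay, divergence and degeneracy", {
  flat <- matrix(1, nrow = 5, ncol = 2)
  crit <- stability_criterion(c(1, 1))
  res <- lyapunov_check(flat, crit)
  expect_true(res$stable)
  expect_true(all(res$V == 0))

  t_idx <- 0:30
  v <- exp(-0.3 * t_idx)
  traj <- cbind(sqrt(v / 2), sqrt(v / 2))
  fit <- lyapunov_check(traj, stability_criterion(c(0, 0)))
  expect_true(fit$stable)
  expect_lt(abs(fit$rate - 0.3), 0.01)

  grow <- cbind(sqrt(exp(0.1 * t_idx)), 0)
  bad <- lyapunov_check(grow, stability_criterion(c(0, 0)))
  expect_false(bad$stable)

  expect_error(lyapunov_check(traj[1:2, ], stability_criterion(c(0, 0))),
               class = "neurotrainr_data_error")
})
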