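test_that("composite scores evaluate their defining forms", {
  st <- list(wm = 72.4, ic = 68.1, cf = 65.9)
  expect_equal(ef_score(st, ef_params(alpha = c(1, 0, 0))), 72.4)
  expect_equal(ef_score(list(wm = 50, ic = 50, cf = 50),
                        ef_params(alpha = c(0.2, 0.3, 0.5))), 50)
  expect_equal(round_half_up(ef_score(st)), 68.8)
  # noise is reproducible under a seed
  pn <- ef_params(noise_sd = 2)
  expect_equal(ef_score(st, pn, noise_seed = 4),
               ef_score(st, pn, noise_seed = 4))

  hist1 <- data.frame(sa = 60, pr = 70, dm = 80, sp = 90)
  expect_equal(tc_score(hist1, tc_params(beta = c(1, 0, 0, 0))), 60)
  hist_const <- hist1[rep(1, 4), ]
  expect_equal(tc_score(hist_const, tc_params(delays = c(0, 1, 2, 3))),
               tc_score(hist_const, tc_params()))
  hist2 <- data.frame(sa = c(10, 20), pr = c(30, 40), dm = c(50, 60),
                      sp = c(70, 80))
  p2 <- tc_params(beta = c(1, 1, 1, 1), delays = c(0, 1, 0, 0))
  expect_equal(tc_score(hist2, p2), 20 + 30 + 60 + 80)
  expect_error(tc_score(hist1, tc_params(delays = c(0, 1, 0, 0))),
               class = "neurotrainr_lag_error")

  expect_equal(performance_score(70, 80, performance_params(c(1, 0, 0))),
               5600)
  expect_equal(performance_score(70, 80, performance_params(c(0, 1, 0))), 70)
  expect_equal(performance_score(70, 80,
                                 performance_params(c(0.01, 0.5, 0.5))), 131)
})

test_that("session updates are fixed-point, decoupled and linear", {
  p <- update_params(rho = c(0.5, 0.5, 0.5), lambda_fb = 1)
  expect_equal(as.numeric(ef_step(70, c(0, 0, 0), 0, p)), 70)
  p0 <- update_params(rho = c(0.5, 0.5, 0.5), lambda_fb = 0)
  expect_equal(as.numeric(ef_step(70, c(0, 0, 0), feedback = 99, p0)), 70)
  expect_equal(as.numeric(ef_step(70, c(2, 2, 2), feedback = 1, p)), 74)
  pt <- update_params(mu = c(0.5, 0.5), phi_context = 1, psi_transfer = 2)
  expect_equal(as.numeric(tc_step(70, c(2, 4), context = 1, transfer = 0.5,
                                  pt)), 75)
  expect_equal(as.numeric(tc_step(70, c(2, 4),
                                  context = 1, transfer = 99,
                                  update_params(mu = c(0.5, 0.5),
                                                phi_context = 1))), 74)
  # additivity of increments away from the clamp
  a <- c(1, 2, 0.5)
  b <- c(0.2, 0.1, 0.3)
  once <- ef_step(50, a + b, 0, p)
  twice <- ef_step(as.numeric(ef_step(50, a, 0, p)), b, 0, p)
  expect_equal(as.numeric(once), as.numeric(twice))
  # clamping is applied and reported
  high <- ef_step(99, c(10, 10, 10), 0, p)
  expect_equal(as.numeric(high), 100)
  expect_equal(attr(high, "n_clamped"), 1L)
})

test_that("with all rates zero every trajectory is constant", {
  p <- update_params(rho = c(0, 0, 0), lambda_fb = 0, mu = c(0, 0, 0, 0),
                     phi_context = 0, psi_transfer = 0)
  ef <- 63.2
  tc <- 58.9
  for (t in 1:25) {
    ef <- as.numeric(ef_step(ef, c(2, -1, 3), feedback = 5, p))
    tc <- as.numeric(tc_step(tc, c(1, 1, 1, 1), context = 2, transfer = 3, p))
  }
  expect_equal(ef, 63.2)
  expect_equal(tc, 58.9)
})

test_that("BCM rule has the threshold fixed point and sign structure", {
  p <- plasticity_params(eta = 0.1, theta_j = 1)
  expect_equal(bcm_delta(0.7, 1, p), 0)
  expect_equal(bcm_delta(0.7, 2, plasticity_params(eta = 0, theta_j = 1)), 0)
  expect_equal(bcm_delta(0.5, 2, p), 0.1)
  for (y in c(0.1, 0.5, 0.9)) expect_lt(bcm_delta(1, y, p), 0)
  for (y in c(1.1, 2, 5)) expect_gt(bcm_delta(1, y, p), 0)
  expect_equal(bcm_delta(1, 0, p), 0)
})

test_that("training adaptation decays to the practice floor", {
  p <- adaptation_params(lambda_ta = 2, delta_ta = 0, beta_practice = 0,
                         nf0 = 1)
  expect_equal(training_adaptation(2, t = 7, practice_t = 0, p), 2)
  pb <- adaptation_params(lambda_ta = 3, delta_ta = 0.5, beta_practice = 0.4,
                          nf0 = 1)
  expect_equal(training_adaptation(1, t = 3, practice_t = 2, pb), 0.8)
  expect_lt(abs(training_adaptation(5, t = 100, practice_t = 2, pb) - 0.8),
            1e-12)
})

test_that("synaptic modification index matches the constant-rate integral", {
  p <- plasticity_params(eta = 0.1, w0 = 2, stdp_tau = 0.02)
  expect_equal(smi(function(t) 0 * t, function(t) 3 + 0 * t, c(0, 1), p), 0)
  base <- smi(function(t) 2 + 0 * t, function(t) 3 + 0 * t, c(0, 1), p)
  dbl <- smi(function(t) 2 + 0 * t, function(t) 3 + 0 * t, c(0, 1),
             plasticity_params(eta = 0.2, w0 = 2, stdp_tau = 0.02))
  expect_equal(dbl, 2 * base)
  # closed form: eta * r1 * r2 * T / w0
  expect_lt(abs(base / (0.1 * 2 * 3 * 1 / 2) - 1), 0.01)
  expect_error(smi(identity, identity, c(0, 1),
                   plasticity_params(w0 = 0)),
               class = "neurotrainr_domain_error")
})

test_that("cognitive performance index is a normalized weighted mean", {
  w <- cpi_weights(c(a = 1, b = 2, c = 3))
  expect_equal(cpi(c(a = 60, b = 60, c = 60), w), 0.6)
  expect_equal(cpi(c(a = 80, b = 55), cpi_weights(c(a = 5, b = 0))), 0.8)
  expect_equal(cpi(c(a = 80, b = 60), cpi_weights(c(a = 3, b = 1))), 0.75)
  expect_error(cpi_weights(c(a = 0, b = 0)),
               class = "neurotrainr_config_error")
})
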