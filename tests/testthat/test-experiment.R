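test_that("improvement percentages reproduce the benchmark cells", {
  expect_equal(improvement_pct(72.4, 89.3), 23.3)
  expect_equal(improvement_pct(68.7, 89.6), 30.4)
  expect_equal(improvement_pct(50, 50), 0)
  expect_error(improvement_pct(0, 10), class = "neurotrainr_domain_error")
  expect_equal(improvement_pct(10, 12.345, digits = NULL), 23.45)
})

test_that("effect sizes follow both standard definitions", {
  x <- c(10, 12, 14, 16)
  y <- c(13, 15, 18, 20)
  d <- effect_size_d(x, y, "paired")
  expect_equal(as.numeric(d), mean(y - x) / sd(y - x))
  expect_equal(as.numeric(d), 6.0622, tolerance = 1e-4)
  expect_equal(as.numeric(effect_size_d(x, x, "pooled")), 0)
  expect_equal(as.numeric(effect_size_d(x, x, "paired")), 0)
  # constant nonzero shift: paired SD collapses
  expect_warning(dd <- effect_size_d(c(1, 2, 3), c(2, 3, 4), "paired"),
                 "zero variance")
  expect_true(is.na(dd))
  expect_true(attr(dd, "degenerate"))
  expect_error(effect_size_d(1:3, 1:4), class = "neurotrainr_shape_error")
})

test_that("repeated-measures F matches a sums-of-squares hand computation", {
  # 2 conditions x 2 domains x 4 subjects
  dat <- withr::with_seed(42, tidyr::expand_grid(
    profile = paste0("s", 1:4), condition = c("c1", "c2"),
    domain = c("d1", "d2")))
  dat$improvement_pct <- withr::with_seed(43, rnorm(nrow(dat), 10, 3))
  fit <- rm_anova(dat)

  # independent oracle: textbook partitioning of sums of squares
  y <- array(0, c(4, 2, 2))
  for (r in seq_len(nrow(dat))) {
    y[match(dat$profile[r], paste0("s", 1:4)),
      match(dat$condition[r], c("c1", "c2")),
      match(dat$domain[r], c("d1", "d2"))] <- dat$improvement_pct[r]
  }
  gm <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 4 * 2 * sum((m_a - gm)^2)
  ss_b <- 4 * 2 * sum((m_b - gm)^2)
  ss_ab <- 4 * sum((m_ab - outer(m_a, rep(1, 2)) -
                      outer(rep(1, 2), m_b) + gm)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, 4), m_a) + gm)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, 4), m_b) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_s <- 2 * 2 * sum((m_s - gm)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  f_a <- (ss_a / 1) / (ss_sa / 3)
  f_b <- (ss_b / 1) / (ss_sb / 3)
  f_ab <- (ss_ab / 1) / (ss_sab / 3)
  expect_equal(fit$anova$statistic, c(f_a, f_b, f_ab), tolerance = 1e-8)
  expect_equal(fit$anova$df1, c(1, 1, 1))
  expect_equal(fit$anova$df2, c(3, 3, 3))
})

test_that("degenerate and unbalanced ANOVA inputs are flagged", {
  dat <- tidyr::expand_grid(profile = paste0("s", 1:4),
                            condition = c("c1", "c2"),
                            domain = c("d1", "d2"))
  dat$improvement_pct <- 5
  expect_warning(fit <- rm_anova(dat), "variance")
  expect_true(fit$degenerate)
  expect_error(rm_anova(dat[-1, ]), class = "neurotrainr_design_error")
})

test_that("marker correlations satisfy closed-form checks", {
  # perfect linearity
  rec <- tibble::tibble(profile = paste0("p", 1:6),
                        condition = "collaborative", domain = "wm",
                        pre = 70, post = 70 + 1:6,
                        improvement_pct = 100 * (1:6) / 70)
  mk <- tibble::tibble(profile = paste0("p", 1:6), region = "frontal_fz",
                       band = "theta", pre_power = 10,
                       post_power = 10 + (1:6) * 0.5,
                       change_pct = 2 + 3 * rec$improvement_pct)
  out <- correlate_markers(fake_results(rec, mk))
  expect_equal(out$r, 1, tolerance = 1e-12)

  # five-point hand dataset against the direct Pearson formula
  xv <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  yv <- c(0.7, 2.9, 1.1, 4.8, 5.0)
  rec5 <- tibble::tibble(profile = paste0("p", 1:5),
                         condition = "collaborative", domain = "cf",
                         pre = 60, post = 60 + yv, improvement_pct = yv)
  mk5 <- tibble::tibble(profile = paste0("p", 1:5), region = "parietal_pz",
                        band = "alpha", pre_power = 20, post_power = 20,
                        change_pct = xv)
  r_hand <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  out5 <- correlate_markers(fake_results(rec5, mk5))
  expect_equal(out5$r, r_hand, tolerance = 1e-12)

  # independent marker and improvement decorrelate at large n
  n <- 1e4
  recn <- withr::with_seed(1, tibble::tibble(
    profile = paste0("p", 1:n), condition = "collaborative", domain = "wm",
    pre = 70, post = 80, improvement_pct = rnorm(n)))
  mkn <- withr::with_seed(2, tibble::tibble(
    profile = paste0("p", 1:n), region = "frontal_fz", band = "theta",
    pre_power = 10, post_power = 12, change_pct = rnorm(n)))
  expect_lt(abs(correlate_markers(fake_results(recn, mkn))$r), 0.03)

  # constant vectors are flagged
  mk_const <- mk5
  mk_const$change_pct <- 1
  expect_warning(cc <- correlate_markers(fake_results(rec5, mk_const)),
                 "constant")
  expect_true(is.na(cc$r))
})

test_that("the benchmark executive-function table regenerates exactly", {
  rep <- make_tables(ref_records())
  s <- rep$table4_summary
  wm <- s[s$domain == "wm", ]
  expect_equal(wm$pre_mean, 74.3)
  expect_equal(wm$pre_sd, 2.6)
  expect_equal(wm$improvement_pct, 20.4)
  expect_equal(wm$improvement_sd, 2.7)
  # every improvement cell equals the recomputation from its own row
  expect_equal(rep$table4$improvement_pct,
               improvement_pct(rep$table4$pre, rep$table4$post))
})

test_that("protocol runs are deterministic and condition-ordered", {
  co <- make_cohort(cohort_spec(n = 6, seed = 21))
  cfg <- protocol_config(weeks = 4, markers = FALSE, seed = 31)
  # this small cohort saturates one domain's ceiling; the calibration warns
  r1 <- suppressWarnings(run_protocol(co, cfg))
  r2 <- suppressWarnings(run_protocol(co, cfg))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$meta$config_hash, r2$meta$config_hash)

  by_cond <- tapply(r1$records$improvement_pct[r1$records$family == "ef"],
                    r1$records$condition[r1$records$family == "ef"], mean)
  expect_gte(by_cond[["collaborative"]], by_cond[["isolated_ef"]])
  expect_gte(by_cond[["isolated_ef"]], by_cond[["control"]])
  # control arm with zero learning rates never moves in the noise-free run
  noiseless <- suppressWarnings(run_protocol(co, protocol_config(
    weeks = 4, conditions = "control", session_noise_frac = 0,
    markers = FALSE, seed = 1)))
  expect_true(all(noiseless$records$improvement_pct == 0))
  expect_error(run_protocol(co[0, ], cfg),
               class = "neurotrainr_config_error")
})

test_that("calibration recovers the configured effect targets at large n", {
  co <- make_cohort(cohort_spec(n = 500, seed = 77))
  cfg <- protocol_config(conditions = "collaborative", markers = FALSE,
                         seed = 7)
  res <- run_protocol(co, cfg)
  means <- tapply(res$records$improvement_pct, res$records$domain, mean)
  for (d in names(cfg$effect_targets)) {
    expect_lt(abs(means[[d]] - cfg$effect_targets[[d]]), 1,
              label = sprintf("domain %s mean improvement", d))
  }
})

test_that("generated report tables are self-consistent", {
  co <- make_cohort(cohort_spec(n = 8, seed = 5))
  res <- run_protocol(co, protocol_config(weeks = 6, seed = 3,
                                          marker_duration_s = 4))
  rep <- make_tables(res)
  expect_equal(rep$table4$improvement_pct,
               improvement_pct(rep$table4$pre, rep$table4$post))
  expect_equal(rep$table5$improvement_pct,
               improvement_pct(rep$table5$pre, rep$table5$post))
  expect_equal(rep$table6$change_pct,
               round_half_up(tipi(rep$table6$pre_power,
                                  rep$table6$post_power), 1))
  expect_s3_class(rep$anova, "nt_rm_anova")
  expect_true(all(c("d_paired", "d_pooled") %in% names(rep$effect_sizes)))
  # report writes its files
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("table4.csv", "table5.csv", "table6.csv", "effects.json",
           "anova.json")))))
  expect_error(
    make_tables(res$records[setdiff(names(res$records), "pre")]),
    class = "neurotrainr_completeness_error")
})

test_that("configs round-trip from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cohort:", "  n: 6", "  seed: 3",
    "protocol:", "  weeks: 4", "  markers: false",
    "  conditions: [collaborative, control]",
    "eeg:", "  snr_db: 32", "  duration_s: 2"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$cohort$n, 6L)
  expect_equal(cfg$protocol$weeks, 4L)
  expect_false(cfg$protocol$markers)
  expect_equal(cfg$eeg$snr_db, 32)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"cohort": {"n": 4}, "protocol": {"weeks": 2}}', js)
  cfg2 <- read_config(js)
  expect_equal(cfg2$cohort$n, 4L)
  expect_error(read_config("nope.toml"), class = "neurotrainr_config_error")
})

test_that("the command-line front end runs a tiny simulation", {
  cli <- system.file("cli", "neurotrain.R", package = "neurotrainr")
  skip_if(cli == "", "CLI script not installed")
  out <- withr::local_tempdir()
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cohort:", "  n: 4", "protocol:", "  weeks: 2",
               "  conditions: [collaborative, control]"), yml)
  res <- system2("Rscript", c(cli, "simulate", "--config", yml,
                              "--seed", "2", "--out", out, "--no-markers"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "table4.csv")))
  expect_true(file.exists(file.path(out, "run_meta.json")))
  recs <- readr::read_csv(file.path(out, "records.csv"),
                          show_col_types = FALSE)
  expect_equal(sort(unique(recs$condition)), c("collaborative", "control"))
})
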