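#' Percent improvement from pre to post score
#'
#' `100 * (post - pre) / pre`, reported by default at one decimal with
#' halves rounded up — the rounding rule that reproduces the bundled
#' benchmark tables.
#'
#' @param pre,post Scores; `pre` must be > 0. Vectors recycle.
#' @param digits Decimal places for half-up rounding; `NULL` returns the
#'   unrounded value.
#' @return Percent improvement.
#' @export
#' @examples
#' improvement_pct(72.4, 89.3)
improvement_pct <- function(pre, post, digits = 1) {
  if (any(pre <= 0)) domain_error("`pre` must be > 0")
  out <- 100 * (post - pre) / pre
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Cohen's d for pre/post designs
#'
#' Paired variant: mean of within-subject differences over their SD. Pooled
#' variant: difference of means over the pooled SD of the two score sets.
#'
#' @param pre,post Equal-length score vectors (n >= 2).
#' @param variant `"paired"` (default) or `"pooled"`.
#' @return Cohen's d, with attribute `variant`. `NA` (with a warning and
#'   attribute `degenerate = TRUE`) when the relevant SD is zero.
#' @export
#' @examples
#' effect_size_d(c(10, 12, 14, 16), c(13, 15, 18, 20))
effect_size_d <- function(pre, post, variant = c("paired", "pooled")) {
  variant <- match.arg(variant)
  if (length(pre) != length(post) || length(pre) < 2) {
    abort("`pre` and `post` must be equal-length vectors with n >= 2",
          class = "neurotrainr_shape_error")
  }
  d <- if (variant == "paired") {
    dif <- post - pre
    if (all(dif == 0)) 0 else if (sd(dif) == 0) NA_real_ else mean(dif) / sd(dif)
  } else {
    sp <- sqrt((var(pre) + var(post)) / 2)
    if (sp == 0) NA_real_ else (mean(post) - mean(pre)) / sp
  }
  if (is.na(d)) {
    warn("zero variance: effect size undefined")
    return(structure(NA_real_, variant = variant, degenerate = TRUE))
  }
  structure(d, variant = variant)
}

#' Two-factor repeated-measures ANOVA
#'
#' Both factors vary within subject; the model is fitted with
#' `aov(value ~ A * B + Error(subject/(A*B)))`, testing each effect against
#' its own subject-interaction stratum. Bonferroni-adjusted paired post-hoc
#' contrasts are reported for the first factor.
#'
#' @param data Data frame in long format.
#' @param value,subject Column names (strings) of the response and the
#'   subject identifier.
#' @param factors Length-2 character vector naming the two within-subject
#'   factors.
#' @return List of class `nt_rm_anova` with elements `anova` (tibble: term,
#'   df1, df2, statistic, p.value), `posthoc` (tibble of pairwise
#'   Bonferroni-adjusted contrasts on the first factor), and `degenerate`
#'   (TRUE when the response has no variance).
#' @export
rm_anova <- function(data, value = "improvement_pct", subject = "profile",
                     factors = c("condition", "domain")) {
  df <- as.data.frame(data)
  need <- c(value, subject, factors)
  if (!all(need %in% names(df))) {
    config_error(sprintf("missing columns: %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df <- df[, need]
  names(df) <- c("y", "subj", "A", "B")
  df$subj <- factor(df$subj)
  df$A <- factor(df$A)
  df$B <- factor(df$B)
  counts <- table(df$subj, df$A, df$B)
  if (any(counts != 1)) {
    abort("design must be balanced: one observation per subject x cell",
          class = "neurotrainr_design_error")
  }
  if (stats::var(df$y) < .Machine$double.eps) {
    warn("no between-cell variance: F statistics undefined")
    return(structure(list(anova = tibble(
      term = c("A", "B", "A:B"), df1 = NA, df2 = NA,
      statistic = NA_real_, p.value = NA_real_),
      posthoc = NULL, degenerate = TRUE), class = "nt_rm_anova"))
  }
  fit <- aov(y ~ A * B + Error(subj / (A * B)), data = df)
  sm <- summary(fit)
  pull_row <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    tibble(term = term, df1 = tab[i, "Df"],
           df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
           statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
  }
  res <- dplyr::bind_rows(
    pull_row("subj:A", "A"),
    pull_row("subj:B", "B"),
    pull_row("subj:A:B", "A:B")
  )
  res$term <- c(factors, paste(factors, collapse = ":"))
  # Bonferroni post-hoc on the first factor: paired t-tests on subject means
  means <- stats::aggregate(y ~ subj + A, data = df, FUN = mean)
  lev <- levels(df$A)
  ph <- NULL
  if (length(lev) >= 2) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    ph <- purrr::map(pairs, function(pr) {
      a <- means$y[means$A == pr[1]][order(means$subj[means$A == pr[1]])]
      b <- means$y[means$A == pr[2]][order(means$subj[means$A == pr[2]])]
      tt <- stats::t.test(a, b, paired = TRUE)
      tibble(contrast = paste(pr, collapse = " - "),
             estimate = unname(tt$estimate), statistic = unname(tt$statistic),
             p.value = tt$p.value)
    }) |> list_rbind()
    ph$p.adj <- p.adjust(ph$p.value, method = "bonferroni")
  }
  structure(list(anova = res, posthoc = ph, degenerate = FALSE),
            class = "nt_rm_anova")
}

#' @export
print.nt_rm_anova <- function(x, ...) {
  cat("<nt_rm_anova>\n")
  print(x$anova)
  invisible(x)
}

#' @export
tidy.nt_rm_anova <- function(x, ...) x$anova

#' Empirical type-I error of the interaction test
#'
#' Simulates null datasets (i.i.d. Gaussian cell scores plus a subject
#' random intercept, so there is no true interaction) and reports the
#' rejection rate of the interaction F test at level `alpha`. A correctly
#' calibrated test rejects at about `alpha`.
#'
#' @param n_subjects,n_conditions,n_domains Design size per simulation.
#' @param n_sims Number of null simulations (default 200).
#' @param alpha Test level (default 0.05).
#' @param condition_effect Optional vector of true condition main effects
#'   (recycled), letting the null hold for the interaction while a main
#'   effect is present.
#' @param seed Integer seed.
#' @return Rejection rate of the interaction test.
#' @export
rm_anova_type1 <- function(n_subjects = 12, n_conditions = 3, n_domains = 3,
                           n_sims = 200, alpha = 0.05,
                           condition_effect = 0, seed = 1L) {
  withr::with_seed(seed, {
    rejections <- vapply(seq_len(n_sims), function(i) {
      grid <- expand_grid(profile = seq_len(n_subjects),
                          condition = paste0("c", seq_len(n_conditions)),
                          domain = paste0("d", seq_len(n_domains)))
      subj_fx <- rnorm(n_subjects, 0, 0.5)
      cond_fx <- rep_len(condition_effect, n_conditions)
      grid$improvement_pct <- subj_fx[grid$profile] +
        cond_fx[match(grid$condition, paste0("c", seq_len(n_conditions)))] +
        rnorm(nrow(grid))
      fit <- rm_anova(grid)
      fit$anova$p.value[3] < alpha
    }, logical(1))
    mean(rejections)
  })
}

#' Configure the training protocol
#'
#' @param weeks Protocol length in weeks (default 12).
#' @param sessions_per_week Training sessions per week (default 3).
#' @param conditions Subset of `collaborative`, `isolated_ef`,
#'   `isolated_tc`, `control`.
#' @param effect_targets Named percent mean-improvement targets per domain
#'   (`wm, ic, cf, sa, pr, dm, sp`); defaults to the bundled benchmark
#'   tables' improvement columns.
#' @param transfer_share Fraction of each domain's collaborative gain routed
#'   through the cross-domain transfer coupling (so isolated training keeps
#'   `1 - transfer_share` of the gain). Default 0.3, matching the benchmark
#'   ratio of isolated to collaborative effect sizes.
#' @param session_noise_frac Per-session noise on increments, as a fraction
#'   of the domain's total gain (default 0.05). Set 0 for noise-free runs.
#' @param markers Generate neurophysiological band-power markers through the
#'   signal-synthesis + spectral-feature path (collaborative condition).
#' @param marker_duration_s EEG duration per marker synthesis (default 6 s).
#' @param marker_noise_sd SD of the marker-specific change noise.
#' @param marker_loading Loading of the shared latent training-gain factor
#'   on marker changes; the default 1 with the default marker noise places
#'   marker-behaviour correlations near the benchmark 0.66-0.74 band in
#'   expectation.
#' @param seed Integer seed; identical configs + cohorts give identical
#'   results.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(weeks = 12, sessions_per_week = 3,
                            conditions = c("collaborative", "isolated_ef",
                                           "isolated_tc", "control"),
                            effect_targets = NULL,
                            transfer_share = 0.3,
                            session_noise_frac = 0.05,
                            markers = TRUE, marker_duration_s = 6,
                            marker_noise_sd = 0.06, marker_loading = 1,
                            seed = 1L) {
  if (weeks < 1) config_error("`weeks` must be >= 1")
  allowed <- c("collaborative", "isolated_ef", "isolated_tc", "control")
  if (length(conditions) < 1 || !all(conditions %in% allowed)) {
    config_error("`conditions` must be a non-empty subset of the four protocol arms")
  }
  defaults <- c(wm = 20.4, ic = 23.1, cf = 29.3,
                sa = 26.5, pr = 28.5, dm = 26.5, sp = 30.4)
  if (!is.null(effect_targets)) defaults[names(effect_targets)] <- effect_targets
  check_number(transfer_share, "transfer_share", lower = 0, upper = 0.95)
  structure(
    list(weeks = as.integer(weeks),
         sessions_per_week = as.integer(sessions_per_week),
         conditions = conditions, effect_targets = defaults,
         transfer_share = transfer_share,
         session_noise_frac = session_noise_frac,
         markers = isTRUE(markers), marker_duration_s = marker_duration_s,
         marker_noise_sd = marker_noise_sd, marker_loading = marker_loading,
         seed = as.integer(seed)),
    class = "protocol_config"
  )
}

ef_domains <- c("wm", "ic", "cf")
tc_domains <- c("sa", "pr", "dm", "sp")

#' Calibrate per-domain session gains to the configured effect targets
#'
#' For each domain, solves (by root-finding on the realized cohort) for the
#' total relative gain `g` such that the cohort mean of the clamped
#' improvement `100 * (min(pre * (1 + g * resp), 100) - pre) / pre` equals
#' the target. The gain is then split into a direct part
#' `(1 - transfer_share) * g`, applied through the component learning
#' rates, and a transfer part routed through the cross-domain coupling
#' (`psi` for tactical domains, the feedback coefficient for executive
#' domains), which only the collaborative condition activates.
#'
#' @param cohort An `nt_cohort`.
#' @param cfg A [protocol_config()].
#' @return Tibble with columns `domain`, `family`, `gain`, `direct_gain`,
#'   `coupling` (the calibrated per-domain transfer coefficient per unit of
#'   baseline score).
#' @export
calibrate_protocol <- function(cohort, cfg = protocol_config()) {
  targets <- cfg$effect_targets
  share <- cfg$transfer_share
  gain_for <- function(domain) {
    pre <- cohort[[paste0("baseline_", domain)]]
    resp <- cohort$responsiveness
    target <- targets[[domain]]
    f <- function(g) {
      post <- pmin(pre * (1 + g * resp), 100)
      mean(100 * (post - pre) / pre) - target
    }
    if (f(5) < 0) {
      # score ceiling: even saturating gains cannot reach the target mean
      warn(sprintf(
        "domain '%s': %.1f%% mean improvement unreachable under the score ceiling; gain saturates",
        domain, target))
      return(5)
    }
    uniroot(f, lower = 0, upper = 5, tol = 1e-10)$root
  }
  gains <- vapply(names(targets), gain_for, numeric(1))
  fam <- ifelse(names(targets) %in% ef_domains, "ef", "tc")
  # transfer coupling per unit baseline score: scales the other family's
  # mean relative session gain into this domain's transfer increment; the
  # protocol multiplies it by each profile's own baseline so the transfer
  # contribution is proportional to that profile's score scale
  mean_g <- c(ef = mean(gains[ef_domains]), tc = mean(gains[tc_domains]))
  other <- ifelse(fam == "ef", "tc", "ef")
  coupling <- share * gains / ((1 - share) * mean_g[other])
  tibble(domain = names(targets), family = fam, gain = unname(gains),
         direct_gain = unname((1 - share) * gains),
         coupling = unname(coupling))
}

#' Run the full training protocol over a cohort
#'
#' Simulates every configured condition over `weeks * sessions_per_week`
#' sessions. Each domain trajectory starts at the profile's baseline and is
#' advanced session by session through the executive-function and
#' tactical-cognition update rules: direct increments (calibrated by
#' [calibrate_protocol()] so the collaborative cohort mean improvement hits
#' the configured targets), plus — in the collaborative condition only — the
#' cross-domain transfer terms driven by the other family's realized session
#' gain. Isolated conditions train only their own family with the transfer
#' coupling set to zero; the control condition sets all learning rates to
#' zero. Scores clamp to \[0, 100\].
#'
#' When `cfg$markers` is `TRUE`, pre/post regional band powers are produced
#' through the synthetic-EEG + Welch band-power path, with per-profile
#' multiplicative training effects that load on the profile's realized
#' relative gain in the domain each region is generatively linked to (see
#' [ref_neural_markers()]), so marker changes correlate with behavioural
#' improvement in that domain.
#'
#' @param cohort An `nt_cohort` (non-empty).
#' @param cfg A [protocol_config()].
#' @return An `nt_results` object: `records` (tibble: profile, condition,
#'   domain, family, pre, post, improvement_pct), `markers` (tibble or NULL),
#'   `calibration`, and `meta` (seed, config hash, clamp count).
#' @export
#' @examples
#' cohort <- make_cohort(cohort_spec(n = 4, seed = 1))
#' res <- run_protocol(cohort, protocol_config(weeks = 2, markers = FALSE))
#' tidy(res)
run_protocol <- function(cohort, cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (is.null(cohort) || nrow(cohort) == 0) {
    config_error("cohort must be non-empty")
  }
  n_sessions <- cfg$weeks * cfg$sessions_per_week
  calib <- calibrate_protocol(cohort, cfg)
  doms <- calib$domain
  n_clamped <- 0L
  withr::with_seed(cfg$seed, {
    records <- purrr::map(cfg$conditions, function(cond) {
      active <- switch(cond,
                       collaborative = c("ef", "tc"),
                       isolated_ef = "ef",
                       isolated_tc = "tc",
                       control = character(0))
      transfer_on <- cond == "collaborative"
      purrr::map(seq_len(nrow(cohort)), function(i) {
        resp <- cohort$responsiveness[i]
        pre <- vapply(doms, function(d) cohort[[paste0("baseline_", d)]][i],
                      numeric(1))
        cur <- pre
        for (t in seq_len(n_sessions)) {
          on <- calib$family %in% active
          inc <- ifelse(on,
                        pre * calib$direct_gain * resp / n_sessions +
                          rnorm(length(doms), 0,
                                pre * calib$gain * cfg$session_noise_frac /
                                  sqrt(n_sessions)),
                        0)
          rel <- inc / pre
          fb_from_tc <- mean(rel[calib$family == "tc"])
          fb_from_ef <- mean(rel[calib$family == "ef"])
          for (j in seq_along(doms)) {
            cpl <- if (transfer_on) calib$coupling[j] * pre[j] else 0
            if (calib$family[j] == "ef") {
              p <- update_params(rho = c(1, 0, 0), lambda_fb = cpl)
              nxt <- ef_step(cur[j], c(inc[j], 0, 0),
                             feedback = fb_from_tc, p = p)
            } else {
              p <- update_params(mu = 1, psi_transfer = cpl)
              nxt <- tc_step(cur[j], inc[j], context = 0,
                             transfer = fb_from_ef, p = p)
            }
            n_clamped <<- n_clamped + attr(nxt, "n_clamped")
            cur[j] <- as.numeric(nxt)
          }
        }
        tibble(profile = cohort$id[i], condition = cond, domain = doms,
               family = calib$family, pre = unname(pre), post = unname(cur),
               improvement_pct = improvement_pct(unname(pre), unname(cur),
                                                 digits = NULL))
      }) |> list_rbind()
    }) |> list_rbind()

    markers <- NULL
    if (cfg$markers && "collaborative" %in% cfg$conditions) {
      ref <- ref_neural_markers()
      collab <- records[records$condition == "collaborative", ]
      # latent coupling factor per profile x domain: the realized relative
      # training gain (responsiveness plus ceiling effects), normalized to
      # unit cohort mean per domain
      rel_gain <- collab |>
        dplyr::group_by(.data$domain) |>
        dplyr::mutate(rel = .data$improvement_pct /
                        mean(.data$improvement_pct)) |>
        dplyr::ungroup()
      markers <- purrr::map(seq_len(nrow(cohort)), function(i) {
        purrr::map(seq_len(nrow(ref)), function(r) {
          lat <- rel_gain$rel[rel_gain$profile == cohort$id[i] &
                                rel_gain$domain == ref$linked_domain[r]]
          pre_t <- max(0.5, rnorm(1, ref$pre_power[r], ref$pre_sd[r]))
          base_rate <- (ref$post_power[r] - ref$pre_power[r]) / ref$pre_power[r]
          chg <- base_rate * (1 + cfg$marker_loading * (lat - 1)) +
            rnorm(1, 0, cfg$marker_noise_sd)
          synth_seed <- sample.int(.Machine$integer.max - 1L, 1L)
          pw <- purrr::map_dbl(
            c(pre_t, pre_t * (1 + chg)),
            function(pt) {
              sp <- eeg_synth_spec(
                bands = band_spec(ref$band[r], ref$f_low[r], ref$f_high[r],
                                  target_power = pt),
                snr_db = 35, fs = 500, duration_s = cfg$marker_duration_s,
                shared_fraction = 0, seed = synth_seed)
              fr <- synth_eeg(cohort[i, ], sp, channels = "Ch")
              unname(band_power(compute_psd(fr), ref$f_low[r], ref$f_high[r]))
            })
          tibble(profile = cohort$id[i], region = ref$region[r],
                 band = ref$band[r], pre_power = pw[1], post_power = pw[2],
                 change_pct = tipi(pw[1], pw[2]))
        }) |> list_rbind()
      }) |> list_rbind()
    }

    structure(
      list(records = records, markers = markers, calibration = calib,
           meta = list(seed = cfg$seed, n_sessions = n_sessions,
                       config_hash = rlang::hash(list(cfg, cohort)),
                       n_clamped = n_clamped)),
      class = "nt_results")
  })
}

#' @export
print.nt_results <- function(x, ...) {
  cat(sprintf("<nt_results> %d records (%d profiles x %d condition(s)), seed %d\n",
              nrow(x$records), length(unique(x$records$profile)),
              length(unique(x$records$condition)), x$meta$seed))
  invisible(x)
}

#' Tidy protocol results into the per-record tibble
#'
#' @param x An `nt_results`.
#' @param ... Unused.
#' @return The `records` tibble.
#' @export
tidy.nt_results <- function(x, ...) x$records

#' Summarize protocol results per condition and domain
#'
#' @param x An `nt_results`.
#' @param ... Unused.
#' @return Tibble with mean pre/post and the cohort improvement per
#'   condition x domain.
#' @export
glance.nt_results <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$condition, .data$domain) |>
    dplyr::summarise(
      pre_mean = mean(.data$pre), post_mean = mean(.data$post),
      improvement_sd = sd(.data$improvement_pct),
      improvement_pct = improvement_pct(mean(.data$pre), mean(.data$post),
                                        digits = NULL),
      .groups = "drop")
}

#' Plot cohort improvements by condition and domain
#'
#' @param object An `nt_results`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nt_results <- function(object, ...) {
  object$records |>
    ggplot2::ggplot(ggplot2::aes(x = .data$domain, y = .data$improvement_pct,
                                 fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Improvement (%)")
}

#' Correlate neural-marker changes with behavioural improvements
#'
#' Pearson correlation (with two-sided p) between each regional band-power
#' change and each domain's improvement across profiles, for the
#' collaborative condition.
#'
#' @param results An `nt_results` with markers.
#' @return Tibble with columns `region`, `band`, `domain`, `r`, `p.value`,
#'   `n`; degenerate (constant) pairs carry a missing `r` and a warning.
#' @export
correlate_markers <- function(results) {
  if (is.null(results$markers)) {
    config_error("results carry no neural markers (run with markers = TRUE)")
  }
  imp <- results$records |>
    dplyr::filter(.data$condition == "collaborative") |>
    dplyr::select("profile", "domain", "improvement_pct")
  pairs <- results$markers |>
    dplyr::inner_join(imp, by = "profile", relationship = "many-to-many")
  if (nrow(pairs) == 0 || length(unique(pairs$profile)) < 3) {
    abort("need at least 3 paired observations",
          class = "neurotrainr_data_error")
  }
  pairs |>
    dplyr::group_by(.data$region, .data$band, .data$domain) |>
    dplyr::group_modify(function(g, key) {
      if (sd(g$change_pct) == 0 || sd(g$improvement_pct) == 0) {
        warn("constant vector: correlation undefined")
        return(tibble(r = NA_real_, p.value = NA_real_, n = nrow(g)))
      }
      ct <- stats::cor.test(g$change_pct, g$improvement_pct)
      tibble(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(g))
    }) |>
    dplyr::ungroup()
}

#' Build the evaluation report tables from protocol results
#'
#' Produces tidy analogs of the three benchmark tables plus effect sizes and
#' the repeated-measures ANOVA:
#'
#' * `table4`: per-profile executive-function rows (pre/post with the
#'   cosmetic fixed-width display interval of +/- 2.6, improvement % at one
#'   decimal) and `table4_summary` with mean +/- SD per domain, where the
#'   summary improvement is the improvement of the cohort means.
#' * `table5`: tactical-cognition domain means.
#' * `table6`: regional band-power means +/- SD with the change rate of the
#'   means (requires markers).
#'
#' Every improvement cell equals [improvement_pct()] of its own row.
#'
#' @param results An `nt_results`, or a records tibble with columns
#'   `profile`, `condition`, `domain`, `pre`, `post`.
#' @param condition Which condition to tabulate (default `"collaborative"`).
#' @return List of class `nt_report`: `table4`, `table4_summary`, `table5`,
#'   `table6`, `effect_sizes`, `anova`, `correlations`.
#' @export
make_tables <- function(results, condition = "collaborative") {
  records <- if (inherits(results, "nt_results")) results$records else
    as_tibble(results)
  need <- c("profile", "condition", "domain", "pre", "post")
  if (!all(need %in% names(records))) {
    abort(sprintf("records are missing columns: %s",
                  paste(setdiff(need, names(records)), collapse = ", ")),
          class = "neurotrainr_completeness_error")
  }
  if (anyNA(records[need])) {
    abort("records contain missing cells",
          class = "neurotrainr_completeness_error")
  }
  sel <- records[records$condition == condition, ]
  ef <- sel[sel$domain %in% ef_domains, ]
  tc <- sel[sel$domain %in% setdiff(unique(sel$domain), ef_domains), ]

  ci <- 2.6  # fixed-width display interval mirroring the benchmark layout
  table4 <- ef |>
    dplyr::transmute(
      profile = .data$profile, domain = .data$domain,
      pre = .data$pre, pre_ci_lo = .data$pre - ci, pre_ci_hi = .data$pre + ci,
      post = .data$post, post_ci_lo = .data$post - ci,
      post_ci_hi = .data$post + ci,
      improvement_pct = improvement_pct(.data$pre, .data$post))
  table4_summary <- ef |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      pre_mean = round_half_up(mean(.data$pre), 1),
      pre_sd = round_half_up(sd(.data$pre), 1),
      post_mean = round_half_up(mean(.data$post), 1),
      post_sd = round_half_up(sd(.data$post), 1),
      improvement_sd = round_half_up(sd(improvement_pct(.data$pre,
                                                        .data$post)), 1),
      improvement_pct = improvement_pct(mean(.data$pre), mean(.data$post)),
      .groups = "drop")
  table5 <- if (nrow(tc) > 0) {
    tc |>
      dplyr::group_by(.data$domain) |>
      dplyr::summarise(pre = round_half_up(mean(.data$pre), 1),
                       post = round_half_up(mean(.data$post), 1),
                       .groups = "drop") |>
      dplyr::mutate(improvement_pct = improvement_pct(.data$pre, .data$post))
  } else NULL

  table6 <- correlations <- NULL
  if (inherits(results, "nt_results") && !is.null(results$markers)) {
    table6 <- results$markers |>
      dplyr::group_by(.data$region, .data$band) |>
      dplyr::summarise(pre_sd = sd(.data$pre_power),
                       post_sd = sd(.data$post_power),
                       pre_power = mean(.data$pre_power),
                       post_power = mean(.data$post_power),
                       .groups = "drop") |>
      dplyr::select("region", "band", "pre_power", "pre_sd",
                    "post_power", "post_sd") |>
      dplyr::mutate(change_pct = round_half_up(
        tipi(.data$pre_power, .data$post_power), 1))
    correlations <- correlate_markers(results)
  }

  effect_sizes <- sel |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      d_paired = as.numeric(effect_size_d(.data$pre, .data$post, "paired")),
      d_pooled = as.numeric(effect_size_d(.data$pre, .data$post, "pooled")),
      .groups = "drop")

  anova <- NULL
  if (length(unique(records$condition)) >= 2) {
    long <- records |>
      dplyr::mutate(improvement_pct = improvement_pct(.data$pre, .data$post,
                                                      digits = NULL))
    anova <- rm_anova(long)
  }

  structure(list(table4 = table4, table4_summary = table4_summary,
                 table5 = table5, table6 = table6,
                 effect_sizes = effect_sizes, anova = anova,
                 correlations = correlations),
            class = "nt_report")
}

#' @export
print.nt_report <- function(x, ...) {
  cat("<nt_report>\n")
  cat("Executive-function summary:\n")
  print(x$table4_summary)
  if (!is.null(x$table5)) {
    cat("Tactical-cognition summary:\n")
    print(x$table5)
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `table4.csv`, `table5.csv`, `table6.csv` (when present),
#' `effects.json` and `anova.json` into `dir`.
#'
#' @param report An `nt_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dplyr::bind_rows(
    report$table4,
    report$table4_summary |>
      dplyr::transmute(profile = "Mean +/- SD", domain = .data$domain,
                       pre = .data$pre_mean, post = .data$post_mean,
                       improvement_pct = .data$improvement_pct)),
    file.path(dir, "table4.csv"))
  if (!is.null(report$table5)) {
    readr::write_csv(report$table5, file.path(dir, "table5.csv"))
  }
  if (!is.null(report$table6)) {
    readr::write_csv(report$table6, file.path(dir, "table6.csv"))
  }
  jsonlite::write_json(report$effect_sizes, file.path(dir, "effects.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  if (!is.null(report$anova)) {
    jsonlite::write_json(report$anova$anova, file.path(dir, "anova.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
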