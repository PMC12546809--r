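#' Specify a synthetic cognitive cohort
#'
#' Describes how to draw a cohort of simulated individuals: cohort size, the
#' band of between-profile coefficients of variation (CV), and per-component
#' mean baseline scores on the 0-100 scale. The defaults reproduce the study
#' conditions the simulator is built around: n = 12 profiles and 15-25%
#' between-profile CV, with component means taken from the bundled benchmark
#' assessment tables (see [ref_ef_assessment()]).
#'
#' @param n Number of profiles (>= 2).
#' @param cv_range Length-2 numeric, low and high coefficient of variation as
#'   fractions in (0, 1). Each profile draws its own CV uniformly from this
#'   band.
#' @param score_means Named numeric vector of per-component mean baseline
#'   scores; names must cover `wm, ic, cf, sa, pr, dm, sp`.
#' @param resp_sd Standard deviation of the unit-mean responsiveness
#'   multiplier that scales each profile's training gains.
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' cohort_spec(n = 12, seed = 7)
cohort_spec <- function(n = 12,
                        cv_range = c(0.15, 0.25),
                        score_means = NULL,
                        resp_sd = 0.12,
                        seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be >= 2", class = "neurotrainr_cohort_size_error")
  }
  if (length(cv_range) != 2L || any(!is.finite(cv_range)) ||
      cv_range[1] <= 0 || cv_range[2] >= 1 || cv_range[1] > cv_range[2]) {
    config_error("`cv_range` must satisfy 0 < low <= high < 1")
  }
  defaults <- c(wm = 74.3, ic = 70.6, cf = 67.7,
                sa = 69.9, pr = 73.2, dm = 71.4, sp = 68.7)
  if (!is.null(score_means)) {
    if (is.null(names(score_means))) config_error("`score_means` must be named")
    defaults[names(score_means)] <- score_means
  }
  if (any(defaults < 0 | defaults > 100)) {
    config_error("score means must lie in [0, 100]")
  }
  check_number(resp_sd, "resp_sd", lower = 0)
  structure(
    list(n = as.integer(n), cv_range = as.numeric(cv_range),
         score_means = defaults, resp_sd = resp_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo = 0, hi = 100) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Draw from a normal truncated to [lo, hi] whose *truncated* mean equals
# `target_mean`: the latent location is recentred by root-finding so that
# boundary truncation does not bias the cohort mean.
rtruncnorm_centered <- function(n, target_mean, sd, lo = 0, hi = 100) {
  mu <- uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target_mean,
                lower = target_mean - 4 * sd, upper = target_mean + 4 * sd,
                extendInt = "upX", tol = 1e-9)$root
  u <- runif(n, pnorm((lo - mu) / sd), pnorm((hi - mu) / sd))
  mu + sd * qnorm(u)
}

#' Generate a synthetic cohort of cognitive profiles
#'
#' Draws one row per simulated individual. Baseline scores for the three
#' executive-function components (working memory `wm`, inhibitory control
#' `ic`, cognitive flexibility `cf`) and the four tactical-cognition
#' components (situational awareness `sa`, pattern recognition `pr`,
#' decision-making `dm`, strategic planning `sp`) are drawn from normals
#' truncated to \[0, 100\], recentred so truncation does not bias the mean.
#' Each profile draws its own CV uniformly from `spec$cv_range` and its
#' component SD is `mean * CV`, so the realized cohort CV falls inside the
#' configured band up to sampling slack. A unit-mean `responsiveness`
#' multiplier (truncated normal, SD `spec$resp_sd`) carries individual
#' differences in training gain into the dynamics layer.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `nt_cohort`, one row per profile, with columns
#'   `id`, `baseline_wm` ... `baseline_sp`, `responsiveness`, `cluster_id`
#'   (`NA` until [cluster_profiles()] is applied).
#' @export
#' @examples
#' make_cohort(cohort_spec(n = 12, seed = 7))
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  comps <- names(spec$score_means)
  out <- withr::with_seed(spec$seed, {
    cvs <- runif(spec$n, spec$cv_range[1], spec$cv_range[2])
    scores <- lapply(comps, function(cp) {
      m <- spec$score_means[[cp]]
      vapply(cvs, function(cv) rtruncnorm_centered(1L, m, m * cv), numeric(1))
    })
    names(scores) <- paste0("baseline_", comps)
    resp <- if (spec$resp_sd > 0) {
      rtruncnorm_centered(spec$n, 1, spec$resp_sd, lo = 0.2, hi = 5)
    } else {
      rep(1, spec$n)
    }
    tibble(
      id = sprintf("Model_%03d", seq_len(spec$n)),
      !!!scores,
      responsiveness = resp,
      cluster_id = NA_integer_
    )
  })
  class(out) <- c("nt_cohort", class(out))
  attr(out, "spec") <- spec
  out
}

#' Stratify profiles by k-means clustering
#'
#' Runs k-means on the scaled baseline scores with multiple restarts (best
#' within-cluster sum of squares wins; ties break to the earliest restart)
#' and reports the mean silhouette coefficient as a cluster-quality gate.
#' The quality benchmark used throughout the package treats mean silhouette
#' above 0.6 as acceptable stratification.
#'
#' @param profiles An `nt_cohort` tibble (or any data frame with
#'   `baseline_*` columns).
#' @param k Number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed Integer seed making the restarts deterministic.
#' @param restarts Number of random restarts (default 10).
#' @return `profiles` with `cluster_id` filled in (integers in `[0, k)`), and
#'   attributes `silhouette` (mean silhouette width, `NA` for k = 1) and
#'   `inertia` (total within-cluster sum of squares).
#' @export
#' @examples
#' cohort <- make_cohort(cohort_spec(n = 12, seed = 7))
#' clustered <- cluster_profiles(cohort, k = 2, seed = 1)
#' attr(clustered, "silhouette")
cluster_profiles <- function(profiles, k, seed = 1L, restarts = 10L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    config_error("`k` must be >= 1")
  }
  n <- nrow(profiles)
  if (k > n) {
    abort(sprintf("cannot form %d clusters from %d profiles", k, n),
          class = "neurotrainr_clustering_error")
  }
  feats <- as.matrix(profiles[grepl("^baseline_", names(profiles))])
  if (k == 1) {
    inform("k = 1: silhouette coefficient undefined for a single cluster")
    profiles$cluster_id <- 0L
    attr(profiles, "silhouette") <- NA_real_
    attr(profiles, "inertia") <- sum(scale(feats, scale = FALSE)^2)
    return(profiles)
  }
  x <- scale(feats)
  fits <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(i) kmeans(x, centers = k, nstart = 1L))
  })
  inertia <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  best <- fits[[which.min(inertia)]]  # which.min takes the earliest tie
  sil <- cluster::silhouette(best$cluster, stats::dist(x))
  profiles$cluster_id <- as.integer(best$cluster) - 1L
  attr(profiles, "silhouette") <- mean(sil[, "sil_width"])
  attr(profiles, "inertia") <- min(inertia)
  profiles
}

#' Write a cohort to CSV or JSON
#'
#' @param cohort An `nt_cohort` tibble.
#' @param path Output file path.
#' @param format `"csv"` (one row per profile) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(cohort, path)
  } else {
    jsonlite::write_json(cohort, path, dataframe = "rows", digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
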