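# Shared in-code fixtures for the test suite.

# Single-channel frame from a raw sample vector.
frame_of <- function(x, fs = 500, label = "Ch") {
  signal_frame(matrix(x, nrow = 1), fs, label)
}

# Frame holding a pure sinusoid of amplitude `a` at `freq` Hz.
sine_frame <- function(freq, duration_s = 10, fs = 500, a = 1, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  frame_of(a * sin(2 * pi * freq * t + phase), fs = fs)
}

# Cohort-like tibble of two well-separated score blobs (for clustering).
two_blob_cohort <- function(n_per = 6, gap = 40, seed = 1) {
  withr::with_seed(seed, {
    lows <- matrix(rnorm(n_per * 7, 30, 2), nrow = n_per)
    highs <- matrix(rnorm(n_per * 7, 30 + gap, 2), nrow = n_per)
    scores <- rbind(lows, highs)
    colnames(scores) <- paste0("baseline_",
                               c("wm", "ic", "cf", "sa", "pr", "dm", "sp"))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("P%02d", seq_len(2 * n_per))),
      tibble::as_tibble(scores),
      tibble::tibble(responsiveness = 1, cluster_id = NA_integer_)
    )
  })
}

# Minimal protocol-results object for evaluation-layer tests.
fake_results <- function(records, markers = NULL, seed = 0L) {
  structure(list(records = records, markers = markers, calibration = NULL,
                 meta = list(seed = seed, n_sessions = 0,
                             config_hash = "fixture", n_clamped = 0L)),
            class = "nt_results")
}

# Records tibble from the bundled executive-function benchmark table.
ref_records <- function() {
  ref <- ref_ef_assessment()
  tibble::tibble(profile = ref$id, condition = "collaborative",
                 domain = ref$domain, family = "ef",
                 pre = ref$pre, post = ref$post,
                 improvement_pct = 100 * (ref$post - ref$pre) / ref$pre)
}
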