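#' Define an oscillatory EEG band
#'
#' @param name Band label (e.g. `"theta"`).
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @param target_power Total band power to synthesize, in uV^2.
#' @return One-row tibble usable as a row of the `bands` table of
#'   [eeg_synth_spec()].
#' @export
band_spec <- function(name, f_low, f_high, target_power = 10) {
  check_number(f_low, "f_low", lower = 1e-9)
  check_number(f_high, "f_high")
  if (f_high <= f_low) config_error("`f_high` must exceed `f_low`")
  check_number(target_power, "target_power", lower = 0)
  tibble(name = name, f_low = f_low, f_high = f_high,
         target_power = target_power)
}

#' Conventional EEG training bands with benchmark-scale powers
#'
#' Theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz), the bands the
#' cognitive-training signal model is built on. Default target powers are on
#' the scale of the bundled neurophysiological benchmark table (about 12, 21
#' and 15 uV^2).
#'
#' @return Tibble with columns `name`, `f_low`, `f_high`, `target_power`.
#' @export
default_bands <- function() {
  dplyr::bind_rows(
    band_spec("theta", 4, 8, 12.4),
    band_spec("alpha", 8, 13, 21.3),
    band_spec("beta", 13, 30, 14.9)
  )
}

#' Specify a synthetic EEG generation run
#'
#' @param bands Tibble of band definitions (see [band_spec()]).
#' @param snr_db Target signal-to-noise ratio in dB: total oscillatory power
#'   over total broadband-noise power. The generator scales the noise so the
#'   realized per-channel ratio equals this target.
#' @param fs Sampling rate in Hz (default 500).
#' @param duration_s Duration in seconds (> 0).
#' @param noise_exponent Spectral slope of the 1/f^exponent background
#'   (default 1, classic pink noise).
#' @param shared_fraction Fraction (amplitude weight in \[0, 1)) of each band
#'   oscillation drawn from a common source shared across channels with a
#'   per-channel lag, so cross-channel phase locking is nontrivial.
#' @param shared_lag_s Per-channel lag of the shared source, seconds.
#' @param seed Integer seed; identical specs give identical frames.
#' @return An `eeg_synth_spec` list.
#' @export
eeg_synth_spec <- function(bands = default_bands(), snr_db = 35, fs = 500,
                           duration_s = 10, noise_exponent = 1,
                           shared_fraction = 0.2, shared_lag_s = 0.01,
                           seed = 1L) {
  check_number(snr_db, "snr_db")
  check_number(fs, "fs", lower = 1e-9)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    config_error("`duration_s` must be > 0")
  }
  if (any(bands$f_high > fs / 2)) {
    config_error("band edges must not exceed the Nyquist frequency fs/2")
  }
  check_number(shared_fraction, "shared_fraction", lower = 0, upper = 0.99)
  structure(
    list(bands = bands, snr_db = snr_db, fs = fs, duration_s = duration_s,
         noise_exponent = noise_exponent, shared_fraction = shared_fraction,
         shared_lag_s = shared_lag_s, seed = as.integer(seed)),
    class = "eeg_synth_spec"
  )
}

#' Construct a multichannel signal frame
#'
#' The basic signal container: a channels-by-samples matrix with a sampling
#' rate and channel labels. Generated frames come from [synth_eeg()] and
#' [synth_physio()]; this constructor lets external samples enter the same
#' feature pipeline.
#'
#' @param data Numeric matrix, channels x samples (a vector is taken as one
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param t0 Start time in seconds.
#' @return An `nt_frame`.
#' @export
signal_frame <- function(data, fs, channel_labels, t0 = 0) {
  data <- rbind(data)
  if (nrow(data) != length(channel_labels)) {
    config_error("channel count must equal label count")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 t0 = t0),
            class = "nt_frame")
}

#' @export
print.nt_frame <- function(x, ...) {
  cat(sprintf("<nt_frame> %d channel(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

#' Tidy a signal frame into long format
#'
#' @param x An `nt_frame`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `channel`, `value`.
#' @export
tidy.nt_frame <- function(x, ...) {
  n <- ncol(x$data)
  tibble(
    time = rep(x$t0 + (seq_len(n) - 1) / x$fs, times = nrow(x$data)),
    channel = rep(x$channel_labels, each = n),
    value = as.vector(t(x$data))
  )
}

#' Write a signal frame as long-format CSV
#'
#' @param frame An `nt_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  readr::write_csv(tidy.nt_frame(frame), path)
  invisible(path)
}

# 1/f^exponent noise via spectral shaping of white Gaussian noise, unit
# variance, zero mean. Frequencies below f_floor keep the f_floor amplitude so
# the DC-adjacent bins do not blow up.
pink_noise <- function(n, fs, exponent = 1, f_floor = 0.5) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- pmax(f, f_floor)^(-exponent / 2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  idx <- n - seq_len(nf) + 1
  keep <- idx > nf + 1
  spec[idx[keep]] <- Conj(z[keep])
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = rnorm(1) * amp[nf])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

# One band-limited oscillator: amplitude-modulated sinusoid whose
# instantaneous frequency drifts slowly inside [f_low, f_high]. Normalized to
# zero mean, unit variance.
band_oscillator <- function(n, fs, f_low, f_high) {
  t <- (seq_len(n) - 1) / fs
  f0 <- (f_low + f_high) / 2
  half <- (f_high - f_low) / 2
  f_drift <- runif(1, 0.05, 0.15)
  f_am <- runif(1, 0.1, 0.3)
  ph <- runif(3, 0, 2 * pi)
  inst_f <- f0 + 0.4 * half * sin(2 * pi * f_drift * t + ph[1])
  phase <- 2 * pi * cumsum(inst_f) / fs + ph[2]
  am <- 1 + 0.3 * sin(2 * pi * f_am * t + ph[3])
  x <- am * sin(phase)
  x <- x - mean(x)
  x / sd(x)
}

#' Synthesize band-structured EEG with controlled SNR
#'
#' Builds each channel as a sum of per-band oscillators (amplitude-modulated
#' sinusoids with slowly drifting instantaneous frequency, giving nontrivial
#' phase structure) scaled to the requested band powers, plus 1/f^exponent
#' background noise scaled so the realized oscillation-to-noise power ratio
#' equals `spec$snr_db` exactly on the generated samples. A configurable
#' fraction of each band oscillation is shared across channels with a
#' per-channel lag so connectivity measures are nontrivial.
#'
#' @param profile Optional cohort row (carried into the frame metadata).
#' @param spec An [eeg_synth_spec()].
#' @param channels Character vector of channel labels; defaults to the eight
#'   10-20 sites used by the neurophysiological benchmark table.
#' @return An `nt_frame` with attributes `realized_snr_db` (per channel),
#'   `osc_power`, `noise_power`, `snr_definition`.
#' @export
#' @examples
#' fr <- synth_eeg(spec = eeg_synth_spec(duration_s = 2, seed = 1),
#'                 channels = "Fz")
#' attr(fr, "realized_snr_db")
synth_eeg <- function(profile = NULL, spec = eeg_synth_spec(),
                      channels = c("Fz", "F3", "F4", "Pz", "Cz", "Oz",
                                   "T7", "T8")) {
  stopifnot(inherits(spec, "eeg_synth_spec"))
  if (length(channels) < 1) config_error("`channels` must be non-empty")
  n <- round(spec$duration_s * spec$fs)
  nb <- nrow(spec$bands)
  lag <- max(0L, round(spec$shared_lag_s * spec$fs))
  c2 <- spec$shared_fraction^2
  withr::with_seed(spec$seed, {
    shared <- lapply(seq_len(nb), function(b) {
      band_oscillator(n + lag * length(channels), spec$fs,
                      spec$bands$f_low[b], spec$bands$f_high[b])
    })
    data <- matrix(0, nrow = length(channels), ncol = n)
    osc_power <- noise_power <- numeric(length(channels))
    for (ch in seq_along(channels)) {
      osc <- rep(0, n)
      for (b in seq_len(nb)) {
        own <- band_oscillator(n, spec$fs,
                               spec$bands$f_low[b], spec$bands$f_high[b])
        sh <- shared[[b]][seq_len(n) + (ch - 1) * lag]
        sh <- (sh - mean(sh)) / sd(sh)
        p <- spec$bands$target_power[b]
        osc <- osc + sqrt((1 - c2) * p) * own + sqrt(c2 * p) * sh
      }
      noise <- pink_noise(n, spec$fs, spec$noise_exponent)
      po <- mean(osc^2) - mean(osc)^2
      pn_target <- po / 10^(spec$snr_db / 10)
      noise <- noise * sqrt(pn_target)
      x <- osc + noise
      data[ch, ] <- x - mean(x)
      osc_power[ch] <- po
      noise_power[ch] <- pn_target
    }
    fr <- signal_frame(data, spec$fs, channels)
    attr(fr, "realized_snr_db") <- 10 * log10(osc_power / noise_power)
    attr(fr, "osc_power") <- osc_power
    attr(fr, "noise_power") <- noise_power
    attr(fr, "snr_definition") <-
      "total oscillatory-component power / total broadband-noise power"
    attr(fr, "profile_id") <- if (!is.null(profile)) profile$id else NA
    fr
  })
}

#' Synthesize an auxiliary physiological stream
#'
#' Sampling rates follow the acquisition-hardware configuration the simulator
#' mirrors: galvanic skin response at 100 Hz, heart rate (ECG-derived) at
#' 500 Hz, surface EMG at 2000 Hz. GSR values stay inside the sensor's
#' 0.01-100 uS range.
#'
#' @param profile Optional cohort row (metadata only).
#' @param modality One of `"gsr"`, `"heart_rate"`, `"emg"`.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @return An `nt_frame` with one channel.
#' @export
synth_physio <- function(profile = NULL,
                         modality = c("gsr", "heart_rate", "emg"),
                         duration_s = 10, seed = 1L) {
  if (length(modality) != 1L || !modality %in% c("gsr", "heart_rate", "emg")) {
    config_error("unknown modality; use 'gsr', 'heart_rate' or 'emg'")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    config_error("`duration_s` must be > 0")
  }
  fs <- switch(modality, gsr = 100, heart_rate = 500, emg = 2000)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- withr::with_seed(seed, {
    switch(modality,
      gsr = {
        tonic <- 3 + 1.2 * sin(2 * pi * 0.02 * t + runif(1, 0, 2 * pi))
        phasic <- rep(0, n)
        n_events <- stats::rpois(1, 0.1 * duration_s)
        if (n_events > 0) {
          onsets <- sort(sample.int(n, n_events))
          for (o in onsets) {
            amp <- stats::rexp(1, rate = 2)
            k <- seq(0, min(n - o, round(5 * fs)))
            phasic[o + k] <- phasic[o + k] +
              amp * (1 - exp(-k / (0.75 * fs))) * exp(-k / (2 * fs))
          }
        }
        pmin(pmax(tonic + phasic + 0.05 * rnorm(n), 0.01), 100)
      },
      heart_rate = {
        hr <- 72 + 6 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
          as.numeric(stats::filter(rnorm(n, sd = 0.6), 0.995,
                                   method = "recursive"))
        pmin(pmax(hr, 40), 200)
      },
      emg = {
        bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
        base <- signal::filtfilt(bf, rnorm(n))
        burst <- 1 + 2 * (sin(2 * pi * 0.5 * t + runif(1, 0, 2 * pi)) > 0.3)
        30 * burst * base
      })
  })
  fr <- signal_frame(matrix(x, nrow = 1), fs, modality)
  attr(fr, "profile_id") <- if (!is.null(profile)) profile$id else NA
  fr
}

#' Estimate signal-to-noise ratio from band structure
#'
#' Computes `10 log10(in-band power / out-of-band power)` from a Welch
#' spectral estimate, pooling channels. "In band" means inside any of the
#' supplied signal bands; everything else above 0 Hz counts as noise. Note
#' this treats in-band background noise as signal, so for a generated frame
#' it upper-bounds the generator's oscillation-to-noise ratio.
#'
#' @param frame An `nt_frame`.
#' @param signal_bands Tibble of bands (`f_low`, `f_high`).
#' @return SNR in dB; `Inf` with a warning when the out-of-band power is zero.
#' @export
estimate_snr <- function(frame, signal_bands) {
  ps <- compute_psd(frame)
  f <- ps$freqs
  in_band <- rep(FALSE, length(f))
  for (b in seq_len(nrow(signal_bands))) {
    in_band <- in_band |
      (f >= signal_bands$f_low[b] & f <= signal_bands$f_high[b])
  }
  pos <- f > 0
  p_in <- sum(ps$psd[in_band & pos, , drop = FALSE]) * ps$df
  p_out <- sum(ps$psd[!in_band & pos, , drop = FALSE]) * ps$df
  if (p_out <= 1e-12 * p_in) {  # numerically zero (window leakage only)
    warn("zero out-of-band power: SNR is unbounded")
    return(Inf)
  }
  10 * log10(p_in / p_out)
}
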