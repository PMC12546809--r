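#' Welch power spectral density of a signal frame
#'
#' Averaged modified periodograms: the frame is split into (possibly
#' overlapping) segments, each segment is mean-detrended, windowed and
#' Fourier transformed, and the one-sided periodograms are averaged. The
#' density is scaled so that its rectangular-rule integral equals the
#' time-domain variance (windowed Parseval with the window power
#' correction `sum(w^2)`).
#'
#' @param frame An `nt_frame`.
#' @param window_name `"hann"` (default) or `"rectangular"`.
#' @param nperseg Segment length in samples; defaults to 2 s of data (or the
#'   whole record if shorter).
#' @param overlap Fractional segment overlap in \[0, 1) (default 0.5).
#' @param bands Optional band table; when given, per-band powers are
#'   aggregated into the result's `band_power` tibble.
#' @return An `nt_psd` object: `freqs` (Hz), `psd` (frequency x channel
#'   matrix, uV^2/Hz), `df`, `fs`, `window_name`, `nperseg`,
#'   `channel_labels`, `n_segments`, and optionally `band_power`.
#' @export
#' @examples
#' fr <- synth_eeg(spec = eeg_synth_spec(duration_s = 4, seed = 2),
#'                 channels = "Cz")
#' ps <- compute_psd(fr)
#' head(tidy(ps))
compute_psd <- function(frame, window_name = c("hann", "rectangular"),
                        nperseg = NULL, overlap = 0.5, bands = NULL) {
  window_name <- match.arg(window_name)
  x <- frame$data
  n <- ncol(x)
  nperseg <- nperseg %||% min(n, round(2 * frame$fs))
  if (nperseg > n) {
    abort("`nperseg` exceeds the number of samples",
          class = "neurotrainr_length_error")
  }
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- switch(window_name,
              hann = 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg),
              rectangular = rep(1, nperseg))
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  psd <- matrix(0, nrow = nf, ncol = nrow(x))
  for (s in starts) {
    seg <- x[, s:(s + nperseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    for (ch in seq_len(nrow(x))) {
      X <- fft(seg[ch, ] * w)[seq_len(nf)]
      p <- Mod(X)^2 / (frame$fs * u)
      scale2 <- rep(2, nf)
      scale2[1] <- 1
      if (nperseg %% 2 == 0) scale2[nf] <- 1
      psd[, ch] <- psd[, ch] + p * scale2
    }
  }
  psd <- psd / length(starts)
  out <- structure(
    list(freqs = (seq_len(nf) - 1) * frame$fs / nperseg,
         psd = psd, df = frame$fs / nperseg, fs = frame$fs,
         window_name = window_name, nperseg = nperseg,
         channel_labels = frame$channel_labels,
         n_segments = length(starts)),
    class = "nt_psd")
  if (!is.null(bands)) {
    out$band_power <- purrr::pmap(
      list(bands$name, bands$f_low, bands$f_high),
      function(nm, lo, hi) {
        tibble(band = nm, channel = frame$channel_labels,
               power = band_power(out, lo, hi))
      }) |> list_rbind()
  }
  out
}

#' @export
print.nt_psd <- function(x, ...) {
  cat(sprintf(
    "<nt_psd> %d freq bins x %d channel(s), df = %.3g Hz, %s window, %d segment(s)\n",
    length(x$freqs), ncol(x$psd), x$df, x$window_name, x$n_segments))
  invisible(x)
}

#' Tidy a spectral estimate into long format
#'
#' @param x An `nt_psd`.
#' @param ... Unused.
#' @return Tibble with columns `freq`, `channel`, `psd`.
#' @export
tidy.nt_psd <- function(x, ...) {
  tibble(freq = rep(x$freqs, times = ncol(x$psd)),
         channel = rep(x$channel_labels, each = length(x$freqs)),
         psd = as.vector(x$psd))
}

#' Plot a spectral estimate
#'
#' @param object An `nt_psd`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nt_psd <- function(object, ...) {
  tidy.nt_psd(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$freq, y = .data$psd,
                                 colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
}

#' Integrate spectral power over a band
#'
#' Trapezoidal integral of the density between `f_low` and `f_high`, with
#' linear interpolation at the band edges, so power is exactly additive over
#' disjoint adjacent bands.
#'
#' @param spectrum An `nt_psd`.
#' @param f_low,f_high Band edges in Hz within the spectrum's range.
#' @return Named numeric vector of band power (uV^2) per channel.
#' @export
band_power <- function(spectrum, f_low, f_high) {
  if (f_high < f_low) config_error("inverted band: `f_high` < `f_low`")
  f <- spectrum$freqs
  if (f_low < min(f) || f_high > max(f)) {
    config_error("band must lie within the spectrum's frequency range")
  }
  inner <- which(f > f_low & f < f_high)
  vapply(seq_len(ncol(spectrum$psd)), function(ch) {
    p <- spectrum$psd[, ch]
    xf <- c(f_low, f[inner], f_high)
    yf <- c(stats::approx(f, p, f_low)$y, p[inner],
            stats::approx(f, p, f_high)$y)
    if (length(xf) < 2) return(0)
    pracma::trapz(xf, yf)
  }, numeric(1)) |> setNames(spectrum$channel_labels)
}

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Zero-phase band-pass (4th order Butterworth run forwards and backwards).
bandpass_filter <- function(x, fs, f_low, f_high, order = 4) {
  bf <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Instantaneous phase of a band-limited component
#'
#' Zero-phase band-pass followed by the analytic-signal phase, wrapped to
#' (-pi, pi\].
#'
#' @param frame An `nt_frame`.
#' @param band Length-2 numeric band edges in Hz.
#' @param channel Channel index or label (default first channel).
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(frame, band, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, frame$channel_labels)
  xb <- bandpass_filter(frame$data[channel, ], frame$fs, band[1], band[2])
  Arg(analytic_signal(xb))
}

#' Phase-locking value between two phase series
#'
#' The magnitude of the trial-averaged unit phasor of the phase difference,
#' `|1/N * sum_n exp(i (phi_x - phi_y))|`. With trial-by-sample matrices the
#' average runs across trials, giving one PLV per time point. With plain
#' vectors there is a single realization, so the average is pooled across
#' time instead; the result then carries attribute `pooled = TRUE` to flag
#' that deviation from the trial-indexed definition.
#'
#' @param x,y Phase series in radians: matrices (trials x samples) with equal
#'   dimensions, or equal-length vectors.
#' @return Numeric vector of PLV values in \[0, 1\] (length = samples for
#'   matrix input, length 1 for pooled vector input).
#' @export
#' @examples
#' ph <- matrix(runif(40, -pi, pi), nrow = 10)
#' plv(ph, ph)  # identical phases lock perfectly
plv <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y))) {
      abort("`x` and `y` must be matrices with matching trial/sample counts",
            class = "neurotrainr_shape_error")
    }
    out <- Mod(colMeans(exp(1i * (x - y))))
    return(pmin(out, 1))
  }
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length",
          class = "neurotrainr_shape_error")
  }
  out <- Mod(mean(exp(1i * (x - y))))
  attr(out, "pooled") <- TRUE
  pmin(out, 1)
}

#' Kullback-Leibler modulation index of a phase/amplitude pair
#'
#' Bins the phase series into `n_bins` equal phase bins, computes the mean
#' amplitude per bin, normalizes to a distribution, and reports its KL
#' divergence from uniform scaled by `log(n_bins)` so the index lies in
#' \[0, 1\]. Zero means the amplitude is independent of phase.
#'
#' @param phase Phase series in radians.
#' @param amplitude Nonnegative amplitude series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return Modulation index in \[0, 1\], with attribute `null_bias`: the
#'   approximate small-sample positive bias of the estimator under the
#'   no-coupling null (assuming roughly independent samples).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude))
  bins <- findInterval(phase, seq(-pi, pi, length.out = n_bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  m <- vapply(seq_len(n_bins), function(b) {
    idx <- bins == b
    if (!any(idx)) 0 else mean(amplitude[idx])
  }, numeric(1))
  if (sum(m) <= 0) return(structure(0, null_bias = 0))
  p <- m / sum(m)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] * n_bins)) / log(n_bins)
  structure(max(mi, 0),
            null_bias = (n_bins - 1) / (2 * length(phase) * log(n_bins)))
}

#' Theta-gamma (phase-amplitude) coupling of a channel
#'
#' Extracts the analytic phase of the slow band and the analytic envelope of
#' the fast band (zero-phase 4th-order Butterworth band-passes), trims the
#' filter transients, and computes the KL [modulation_index()] over `n_bins`
#' phase bins.
#'
#' @param frame An `nt_frame` covering at least 10 cycles of the slow band.
#' @param phase_band,amp_band Band edges in Hz (defaults theta 4-8 and low
#'   gamma 30-50).
#' @param n_bins Number of phase bins (default 18).
#' @param channel Channel index or label.
#' @return Modulation index (>= 0) with attribute `null_bias` recomputed with
#'   the number of slow-band cycles as the effective sample count.
#' @export
theta_gamma_coupling <- function(frame, phase_band = c(4, 8),
                                 amp_band = c(30, 50), n_bins = 18,
                                 channel = 1L) {
  if (max(phase_band, amp_band) > frame$fs / 2) {
    config_error("bands must lie below the Nyquist frequency")
  }
  duration <- ncol(frame$data) / frame$fs
  n_cycles <- duration * phase_band[1]
  if (n_cycles < 10) {
    abort("recording shorter than 10 cycles of the phase band",
          class = "neurotrainr_data_length_error")
  }
  if (is.character(channel)) channel <- match(channel, frame$channel_labels)
  x <- frame$data[channel, ]
  ph <- Arg(analytic_signal(bandpass_filter(x, frame$fs,
                                            phase_band[1], phase_band[2])))
  env <- Mod(analytic_signal(bandpass_filter(x, frame$fs,
                                             amp_band[1], amp_band[2])))
  trim <- round(0.5 * frame$fs)
  keep <- (trim + 1):(length(x) - trim)
  mi <- modulation_index(ph[keep], env[keep], n_bins)
  attr(mi, "null_bias") <- (n_bins - 1) / (2 * n_cycles * log(n_bins))
  mi
}

#' Training-induced plasticity index
#'
#' Percent change in spectral power from pre- to post-training:
#' `100 * (post - pre) / pre`.
#'
#' @param psd_pre,psd_post Positive pre-training and post-training powers
#'   (vectors recycle).
#' @return Percent change (same length as the inputs).
#' @export
#' @examples
#' tipi(12.4, 15.8)
tipi <- function(psd_pre, psd_post) {
  if (any(psd_pre <= 0)) domain_error("`psd_pre` must be > 0")
  100 * (psd_post - psd_pre) / psd_pre
}

#' Near-infrared spectroscopy parameters
#'
#' @param alpha_coeff,beta_coeff Wavelength-dependent coefficients.
#' @param I0 Reference light intensity (> 0).
#' @param dHbR Deoxygenated-hemoglobin change series (recycled).
#' @return A `nirs_params` list.
#' @export
nirs_params <- function(alpha_coeff = 1, beta_coeff = 1, I0 = 1, dHbR = 0) {
  check_number(I0, "I0", lower = 1e-12)
  structure(list(alpha_coeff = alpha_coeff, beta_coeff = beta_coeff,
                 I0 = I0, dHbR = dHbR),
            class = "nirs_params")
}

#' Oxygenated-hemoglobin concentration change (modified Beer-Lambert)
#'
#' `alpha * log(I0 / I(t)) - beta * dHbR(t)`, with the natural logarithm
#' (the wavelength coefficient absorbs any base conversion).
#'
#' @param I_t Measured light-intensity series, strictly positive.
#' @param params A [nirs_params()].
#' @return Concentration-change series, same length as `I_t`.
#' @export
delta_hbo2 <- function(I_t, params) {
  stopifnot(inherits(params, "nirs_params"))
  if (any(I_t <= 0)) domain_error("intensities must be > 0")
  params$alpha_coeff * log(params$I0 / I_t) - params$beta_coeff * params$dHbR
}
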