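#' Weights for linear-plus-interaction multimodal fusion
#'
#' @param linear Named numeric vector of per-modality linear weights.
#' @param cross Named numeric vector of pairwise interaction weights; names
#'   are `"a:b"` for the unordered modality pair (a, b), both of which must
#'   appear in `linear`.
#' @return A `fusion_weights` list.
#' @export
fusion_weights <- function(linear, cross = NULL) {
  if (is.null(names(linear)) || any(!is.finite(linear))) {
    config_error("`linear` must be a named finite numeric vector")
  }
  if (!is.null(cross)) {
    if (is.null(names(cross)) || any(!is.finite(cross))) {
      config_error("`cross` must be a named finite numeric vector")
    }
    pair_mods <- unique(unlist(strsplit(names(cross), ":", fixed = TRUE)))
    if (!all(pair_mods %in% names(linear))) {
      config_error("cross-term modalities must all appear in `linear`")
    }
  }
  structure(list(linear = linear, cross = cross), class = "fusion_weights")
}

#' Fuse aligned modality streams by weighted sum plus pairwise interactions
#'
#' Implements `S = sum_i w_i S_i + sum_{j<k} w_jk S_j S_k` elementwise over
#' time-aligned streams, where the second sum runs over unordered modality
#' pairs.
#'
#' @param streams Data frame (or named list of equal-length numeric vectors),
#'   one column per modality.
#' @param weights A [fusion_weights()]; every weighted modality must be a
#'   column of `streams`.
#' @return Tibble with columns `step` and `fused`.
#' @export
#' @examples
#' linear_fuse(data.frame(eeg = c(2, 2), nirs = c(3, 3)),
#'             fusion_weights(c(eeg = 0.5, nirs = 0.5), c("eeg:nirs" = 0.1)))
linear_fuse <- function(streams, weights) {
  stopifnot(inherits(weights, "fusion_weights"))
  lens <- lengths(streams)
  if (length(unique(lens)) != 1L) {
    abort("modality streams must be time-aligned with equal length",
          class = "neurotrainr_alignment_error")
  }
  streams <- as.data.frame(streams)
  if (!all(names(weights$linear) %in% names(streams))) {
    config_error("unknown modality in `weights$linear`")
  }
  fused <- rep(0, lens[[1]])
  for (m in names(weights$linear)) {
    fused <- fused + weights$linear[[m]] * streams[[m]]
  }
  for (pair in names(weights$cross)) {
    mods <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (!all(mods %in% names(streams))) {
      config_error(sprintf("unknown modality in cross term '%s'", pair))
    }
    fused <- fused + weights$cross[[pair]] * streams[[mods[1]]] * streams[[mods[2]]]
  }
  tibble(step = seq_along(fused), fused = fused)
}

#' Configure the scalar Kalman fusion filter
#'
#' @param process_noise Process-noise variance (>= 0).
#' @param obs_noise Named numeric vector of per-modality observation-noise
#'   variances (>= 0).
#' @param init_state Initial state estimate.
#' @param init_var Initial state variance (> 0).
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(process_noise = 0.01, obs_noise, init_state = 0,
                          init_var = 1) {
  check_number(process_noise, "process_noise", lower = 0)
  if (is.null(names(obs_noise)) || any(obs_noise < 0)) {
    config_error("`obs_noise` must be a named vector of variances >= 0")
  }
  check_number(init_var, "init_var", lower = 1e-12)
  structure(list(process_noise = process_noise, obs_noise = obs_noise,
                 init_state = init_state, init_var = init_var),
            class = "kalman_config")
}

#' Kalman fusion of multimodal observations of one latent state
#'
#' A scalar random-walk latent state is tracked by predict/update cycles in
#' which each modality's observation is assimilated sequentially with its own
#' time-varying gain `K_i(t) = P / (P + r_i)`. Gains always lie in \[0, 1\]
#' and are reported per step. The filter is one scalar filter per fused
#' feature channel.
#'
#' @param observations Data frame or matrix, one column per modality, one row
#'   per time step; column names must match `names(cfg$obs_noise)`.
#' @param cfg A [kalman_config()].
#' @return Tibble with columns `step`, `state`, `var`, and `gain_<modality>`.
#' @export
kalman_fuse <- function(observations, cfg) {
  stopifnot(inherits(cfg, "kalman_config"))
  obs <- as.matrix(as.data.frame(observations))
  mods <- names(cfg$obs_noise)
  if (ncol(obs) < 1) config_error("at least one modality is required")
  if (!all(colnames(obs) %in% mods)) {
    config_error("observation columns must match `cfg$obs_noise` names")
  }
  mods <- colnames(obs)
  if (all(cfg$obs_noise[mods] == 0) && length(mods) > 1) {
    rng <- apply(obs, 1, function(z) diff(range(z)))
    if (any(rng > 1e-12)) {
      warn("all observation noises are zero but modalities disagree; the first modality dominates")
    }
  }
  n <- nrow(obs)
  state <- cfg$init_state
  p <- cfg$init_var
  states <- vars <- numeric(n)
  gains <- matrix(NA_real_, nrow = n, ncol = length(mods),
                  dimnames = list(NULL, paste0("gain_", mods)))
  for (t in seq_len(n)) {
    p <- p + cfg$process_noise
    for (j in seq_along(mods)) {
      r <- cfg$obs_noise[[mods[j]]]
      k <- p / (p + r)
      state <- state + k * (obs[t, j] - state)
      p <- (1 - k) * p
      gains[t, j] <- k
    }
    states[t] <- state
    vars[t] <- p
  }
  out <- tibble(step = seq_len(n), state = states, var = vars)
  dplyr::bind_cols(out, as_tibble(gains))
}

#' Closed-form steady-state gain of the scalar Kalman filter
#'
#' For a scalar random-walk state with process noise `q` and a single
#' observation stream with noise `r`, the steady-state prior variance solves
#' the algebraic Riccati equation `P^2 - q P - q r = 0`, giving
#' `P = (q + sqrt(q^2 + 4 q r)) / 2` and gain `K = P / (P + r)`.
#'
#' @param process_noise Process-noise variance `q` (>= 0).
#' @param obs_noise Observation-noise variance `r` (>= 0).
#' @return Steady-state gain in \[0, 1\].
#' @export
kalman_steady_gain <- function(process_noise, obs_noise) {
  q <- process_noise
  r <- obs_noise
  p_prior <- (q + sqrt(q^2 + 4 * q * r)) / 2
  if (p_prior + r == 0) return(1)
  p_prior / (p_prior + r)
}
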