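# Synthetic two-state EEG generator. Emulates the statistical structure the
# classifier relies on: spatially correlated 1/f background activity (a few
# latent sources mixed smoothly across the montage, mimicking volume
# conduction) plus an alpha-band (8-13 Hz) oscillation whose amplitude is
# elevated in the fatigue state, strongest over posterior channels, with slow
# random amplitude modulation ("alpha spindles") and white sensor noise.
# Declaredly synthetic: shapes, rates and the direction of the alpha-power
# contrast are faithful; everything else is a stand-in for real
# electrophysiology.

#' Simulation configuration
#'
#' Defaults mirror the emulated study layout: 6 subjects, 32 channels at
#' 500 Hz, 20 min (1,200 s) per state. The fatigue state multiplies the
#' alpha amplitude by `1 + effect_size`, so the alpha band-power ratio
#' between states converges to `(1 + effect_size)^2`.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param channels Channel count (default 32).
#' @param rate Sampling rate in Hz (default 500).
#' @param duration_per_state Seconds of signal per state (default 1200).
#' @param alpha_band Alpha band edges in Hz (default `c(8, 13)`).
#' @param effect_size Multiplicative alpha-amplitude increase in fatigue
#'   (>= 0, default 0.5).
#' @param background_exponent Spectral slope of the 1/f background power
#'   (default 2.5, a steep, delta-dominated drowsy-EEG spectrum): the
#'   background carries most of its power at low frequencies, so it is large
#'   in total yet nearly absent from the alpha band.
#' @param alpha_amplitude Baseline alpha RMS amplitude in signal units
#'   (default 11, attained at the focal peak of the posterior profile).
#'   Alpha dominates its own band (so the between-state
#'   band-power ratio follows the `(1 + effect_size)^2` law), while the total
#'   background power is tuned so the leading background spatial component
#'   sits between the alert and fatigue alpha eigenvalues — in the alert
#'   state the background pattern is the top principal component, in fatigue
#'   the posterior alpha pattern takes over, as in real drowsy EEG.
#' @param background_sd Background-activity RMS per channel (default 14).
#' @param n_background_sources Latent 1/f background sources mixed across
#'   the montage (default 8); fewer sources means stronger spatial
#'   correlation, as produced by volume conduction.
#' @param noise_sd White sensor-noise SD (default 1.5).
#' @param posterior_weight Per-channel alpha gain profile; default a focal
#'   posterior bump, `0.15 + 0.85 * exp(-(pos - 1)^2 / (2 * 0.15^2))` over
#'   normalized channel position `pos` in \[0, 1\]. A focal profile (rather
#'   than a flat gradient) is what survives the common-average-like
#'   column centering inside per-epoch PCA, as real occipital alpha does.
#' @param subject_sdlog Log-normal SD of per-subject base alpha amplitude
#'   (default 0.2), giving inter-subject variability.
#' @param seed Base RNG seed (default 1).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_subjects = 6L, channels = 32L, rate = 500,
                              duration_per_state = 1200,
                              alpha_band = c(8, 13), effect_size = 0.5,
                              background_exponent = 2.5, alpha_amplitude = 11,
                              background_sd = 14, n_background_sources = 8L,
                              noise_sd = 1.5,
                              posterior_weight = NULL, subject_sdlog = 0.2,
                              seed = 1L) {
  stopifnot(effect_size >= 0, rate > 2 * alpha_band[2], channels >= 1,
            duration_per_state > 0)
  if (is.null(posterior_weight)) {
    pos <- seq(0, 1, length.out = channels)
    posterior_weight <- 0.15 + 0.85 * exp(-(pos - 1)^2 / (2 * 0.15^2))
  }
  stopifnot(length(posterior_weight) == channels)
  structure(
    list(n_subjects = as.integer(n_subjects), channels = as.integer(channels),
         rate = rate, duration_per_state = duration_per_state,
         alpha_band = alpha_band, effect_size = effect_size,
         background_exponent = background_exponent,
         alpha_amplitude = alpha_amplitude, background_sd = background_sd,
         n_background_sources = as.integer(n_background_sources),
         noise_sd = noise_sd, posterior_weight = posterior_weight,
         subject_sdlog = subject_sdlog, seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

# Unit-variance noise band-limited to [low, high] Hz by FFT masking.
fft_band_noise <- function(n, rate, low, high) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)                  # two-sided frequency axis
  X[f < low | f > high] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

# 1/f^exponent power background, normalized to the requested RMS.
fft_colored_noise <- function(n, rate, exponent, target_sd) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  shape <- pmax(f, 0.5)^(-exponent / 2)   # clamp below 0.5 Hz
  shape[1] <- 0                           # no DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y) * target_sd
}

#' Generate one synthetic recording
#'
#' Deterministic given `(cfg$seed, subject_id, state)`; the per-subject base
#' alpha amplitude is drawn from a stream independent of the state so both
#' states of a subject share it.
#'
#' @param cfg A [simulation_config()].
#' @param subject_id Subject index (integer >= 1).
#' @param state 0 (alert) or 1 (fatigue).
#' @return A labeled [recording()].
#' @export
generate_recording <- function(cfg, subject_id, state) {
  stopifnot(inherits(cfg, "SimulationConfig"), state %in% c(0, 1))
  n <- round(cfg$duration_per_state * cfg$rate)
  base_amp <- with_seed(derive_seed(cfg$seed, subject_id, 900L),
                        stats::rlnorm(1, 0, cfg$subject_sdlog))
  amp_state <- cfg$alpha_amplitude * base_amp * (1 + cfg$effect_size * state)

  with_seed(derive_seed(cfg$seed, subject_id, state), {
    shared <- fft_band_noise(n, cfg$rate, cfg$alpha_band[1], cfg$alpha_band[2])
    # spindle-like waxing/waning on a seconds scale: fast enough that epoch
    # and recording means converge (no per-session power fingerprint)
    env <- exp(0.25 * fft_band_noise(n, cfg$rate, 0.1, 1))

    # spatially correlated background: latent 1/f sources mixed through
    # smooth (Gaussian-bump) spatial patterns, rows normalized so every
    # channel carries background RMS background_sd
    nb <- cfg$n_background_sources
    pos <- seq(0, 1, length.out = cfg$channels)
    centers <- seq(0, 1, length.out = nb)
    M <- exp(-outer(pos, centers, `-`)^2 / (2 * 0.15^2))
    M <- M * rep(0.75^(seq_len(nb) - 1L), each = cfg$channels)  # stable source ordering
    M <- M / sqrt(rowSums(M^2)) * cfg$background_sd
    S <- vapply(seq_len(nb), function(j) {
      fft_colored_noise(n, cfg$rate, cfg$background_exponent, 1)
    }, numeric(n))
    bg <- M %*% t(S)

    data <- matrix(0, cfg$channels, n)
    for (ch in seq_len(cfg$channels)) {
      own <- fft_band_noise(n, cfg$rate, cfg$alpha_band[1], cfg$alpha_band[2])
      alpha_src <- sqrt(0.7) * shared + sqrt(0.3) * own
      alpha <- amp_state * cfg$posterior_weight[ch] * env * alpha_src
      data[ch, ] <- bg[ch, ] + alpha + stats::rnorm(n, sd = cfg$noise_sd)
    }
    recording(data, cfg$rate, label = state,
              subject_id = sprintf("S%02d", subject_id))
  })
}

#' Generate a full labeled study
#'
#' One alert and one fatigue recording per subject, plus a manifest.
#'
#' @param cfg A [simulation_config()].
#' @return List with `recordings` (list of [recording()]s) and `manifest`
#'   (data frame of subject, state string, label).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  recs <- list()
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (st in c(0L, 1L)) {
      rec <- generate_recording(cfg, s, st)
      recs[[length(recs) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id,
        state = if (st == 1L) "fatigue" else "alert",
        label = st
      )
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}

#' Mean band power of an epoch set
#'
#' Mean over epochs and channels of the power spectral-density mass inside
#' `band`, estimated per epoch by the periodogram. Used to check the
#' generator's alpha-power contrast.
#'
#' @param es An [epoch_set()].
#' @param band Frequency band in Hz.
#' @return Scalar mean band power.
#' @export
band_power <- function(es, band = c(8, 13)) {
  stopifnot(inherits(es, "EpochSet"), length(es$epochs) > 0)
  n <- es$points_per_epoch
  f <- c(0, seq_len(n - 1)) * es$rate / n
  sel <- f >= band[1] & f <= band[2] & f <= es$rate / 2
  mean(vapply(es$epochs, function(ep) {
    P <- abs(stats::mvfft(t(ep)))^2 / n    # periodogram per channel
    mean(colSums(P[sel, , drop = FALSE])) / n
  }, numeric(1)))
}
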