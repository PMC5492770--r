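#' Electrode site labels
#'
#' Names of the eight arm-surface recording sites used by the default
#' simulator configurations, ordered by sensor number (forearm flexor and
#' extensor sites first, then upper-arm and shoulder sites).
#'
#' @return Character vector of length 8.
#' @export
emg_sites <- function() {
  c("Lateral brachial wrist flexor",
    "Brachioradialis",
    "Extensor digitorum",
    "Extensor carpi ulnaris",
    "Biceps",
    "Triceps",
    "Deltoid",
    "Shoulder capsulorrhaphy")
}

default_gain_matrix <- function(task, n_channels, rectify_per_sign) {
  if (task == "grip") {
    # four forearm channels with distinct positive gains (V/N)
    gains <- c(0.012, 0.009, 0.006, 0.004, 0.003, 0.002, 0.0015, 0.001)
    matrix(gains[seq_len(n_channels)], ncol = 1)
  } else if (rectify_per_sign) {
    # columns: x+, x-, y+, y-, z+, z- ; full column rank so that both the
    # axis and the sign of the applied force are identifiable from the
    # per-channel activation pattern
    0.001 * matrix(c(
      12,  2,  3,  1,  2,  1,
       2, 12,  1,  3,  1,  2,
       3,  1, 12,  2,  1,  2,
       1,  3,  2, 12,  2,  1,
       2,  1,  1,  2, 12,  3,
       1,  2,  2,  1,  3, 12,
       6,  1,  6,  1,  6,  1,
       1,  6,  1,  6,  1,  6), nrow = 8, byrow = TRUE)[seq_len(n_channels), ,
                                                       drop = FALSE]
  } else {
    0.001 * matrix(c(
      12,  2,  2,
       2, 12,  2,
       2,  2, 12,
       8,  6,  1,
       1,  8,  6,
       6,  1,  8,
       4,  4,  8,
       8,  4,  4), nrow = 8, byrow = TRUE)[seq_len(n_channels), ,
                                           drop = FALSE]
  }
}

#' Simulation configuration for synthetic sEMG + force sessions
#'
#' Describes the acquisition chain being emulated: electrode count, sampling
#' rate, EMG pass-band, amplifier noise floor, optional 50 Hz mains
#' interference, DC level shift and the analog-to-digital converter, plus the
#' force-to-activation coupling used to drive the channels.
#'
#' @param task `"grip"` (nonnegative grasp force, one output) or `"force3d"`
#'   (signed push-pull force along x, y, z).
#' @param n_channels Number of EMG channels; defaults to 4 for grip and 8 for
#'   the 3D task.
#' @param fs Sampling rate in Hz per channel, within the collector's
#'   200--2000 Hz range. Default 1000.
#' @param duration Session length in seconds, or `NULL` to size the session
#'   automatically around the requested episodes.
#' @param gain_matrix Nonnegative `n_channels x n_drive` matrix (V/N) mapping
#'   force drives to per-channel envelope increments. With
#'   `rectify_per_sign = TRUE` each signed component contributes two drive
#'   columns (positive and negative half-waves), so `n_drive` is twice the
#'   number of force components; otherwise drives are `|f|` per component.
#' @param noise_floor Baseline EMG amplitude (volts RMS) present at rest.
#' @param mains_amplitude Amplitude (V) of additive 50 Hz interference;
#'   0 by default since the emulated sensor carries a notch filter.
#' @param adc_bits,adc_range,dc_offset Quantizer resolution (bits), input
#'   range (V) and level-shift (V) of the data collector: 10 bit over
#'   0--3 V with a 1.5 V shift by default.
#' @param emg_band Pass-band of the EMG carrier in Hz (default 10--500,
#'   matching the sensor's analog filters).
#' @param amplitude_law `"linear"` (envelope proportional to drive) or
#'   `"sqrt"` (saturating square-root law, making the force-to-amplitude map
#'   nonlinear).
#' @param rectify_per_sign For signed force components, split each component
#'   into positive/negative half-wave drives. Default `TRUE` for the 3D task.
#' @param seed Integer seed controlling all randomness in the simulator.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(task = c("grip", "force3d"),
                       n_channels = NULL,
                       fs = 1000,
                       duration = NULL,
                       gain_matrix = NULL,
                       noise_floor = 0.02,
                       mains_amplitude = 0,
                       adc_bits = 10,
                       adc_range = c(0, 3),
                       dc_offset = 1.5,
                       emg_band = c(10, 500),
                       amplitude_law = c("linear", "sqrt"),
                       rectify_per_sign = NULL,
                       seed = 1L) {
  task <- match.arg(task)
  amplitude_law <- match.arg(amplitude_law)
  stop_if_not_scalar_number(fs, "fs")
  if (fs < 200 || fs > 2000) {
    stop("`fs` must lie in the collector's supported range [200, 2000] Hz",
         call. = FALSE)
  }
  if (is.null(n_channels)) n_channels <- if (task == "grip") 4L else 8L
  if (!n_channels %in% 1:8) {
    stop("`n_channels` must be between 1 and 8", call. = FALSE)
  }
  if (is.null(rectify_per_sign)) rectify_per_sign <- task == "force3d"
  if (is.null(gain_matrix)) {
    gain_matrix <- default_gain_matrix(task, n_channels, rectify_per_sign)
  }
  gain_matrix <- as.matrix(gain_matrix)
  if (nrow(gain_matrix) != n_channels) {
    stop("`gain_matrix` must have one row per EMG channel", call. = FALSE)
  }
  if (any(gain_matrix < 0)) {
    stop("`gain_matrix` entries must be nonnegative", call. = FALSE)
  }
  if (noise_floor < 0) stop("`noise_floor` must be >= 0", call. = FALSE)
  if (length(adc_range) != 2L || diff(adc_range) <= 0) {
    stop("`adc_range` must be an increasing pair of voltages", call. = FALSE)
  }
  structure(
    list(task = task, n_channels = as.integer(n_channels), fs = fs,
         duration = duration, gain_matrix = gain_matrix,
         noise_floor = noise_floor, mains_amplitude = mains_amplitude,
         adc_bits = as.integer(adc_bits), adc_range = adc_range,
         dc_offset = dc_offset, emg_band = emg_band,
         amplitude_law = amplitude_law, rectify_per_sign = rectify_per_sign,
         force_bound = if (task == "grip") 30 else 20,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a synthetic force profile
#'
#' Places `n_episodes` non-overlapping force bursts in a rest baseline.
#' Grip episodes are nonnegative raised-cosine bursts lasting 1--2 s with
#' peaks below 30 N; 3D episodes last about 1 s, activate a single signed
#' component each and stay below 20 N in magnitude. Episodes are separated
#' by at least 0.5 s of rest (including a leading rest segment).
#'
#' @param cfg A [sim_config()].
#' @param n_episodes Number of force bursts (>= 1).
#' @return An object of class `force_profile`: list with `t` (time vector,
#'   s), `f` (components x samples force matrix, N), `episode_table`
#'   (data.frame of start, end, component, peak) and `fs`.
#' @export
generate_force_profile <- function(cfg, n_episodes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(n_episodes) || n_episodes < 1) {
    stop("`n_episodes` must be >= 1", call. = FALSE)
  }
  n_episodes <- as.integer(n_episodes)
  rest <- 0.5
  with_seed(cfg$seed, {
    durations <- if (cfg$task == "grip") {
      runif(n_episodes, 1, 2)
    } else {
      runif(n_episodes, 0.8, 1.2)
    }
    required <- sum(durations) + rest * (n_episodes + 1)
    duration <- cfg$duration
    if (is.null(duration)) duration <- required * 1.2
    if (duration < required) {
      stop(sprintf(
        "cannot place %d episodes in %.2f s: need at least %.2f s",
        n_episodes, duration, required), call. = FALSE)
    }
    # distribute the slack beyond the minimum gaps at random
    slack <- duration - required
    w <- runif(n_episodes + 1)
    gaps <- rest + slack * w / sum(w)
    starts <- cumsum(gaps[seq_len(n_episodes)]) +
      c(0, cumsum(durations))[seq_len(n_episodes)]
    # peak magnitudes uniform within the task's bound (kept strictly below it)
    peaks <- if (cfg$task == "grip") {
      runif(n_episodes, 0.15 * cfg$force_bound, 0.95 * cfg$force_bound)
    } else {
      runif(n_episodes, 0.2 * cfg$force_bound, 0.95 * cfg$force_bound) *
        sample(c(-1, 1), n_episodes, replace = TRUE)
    }
    components <- if (cfg$task == "grip") {
      rep(1L, n_episodes)
    } else {
      sample(rep_len(1:3, n_episodes))
    }
    n_force <- if (cfg$task == "grip") 1L else 3L
    m <- floor(duration * cfg$fs)
    t <- (seq_len(m) - 1) / cfg$fs
    f <- matrix(0, nrow = n_force, ncol = m)
    for (e in seq_len(n_episodes)) {
      idx <- which(t >= starts[e] & t < starts[e] + durations[e])
      tau <- (t[idx] - starts[e]) / durations[e]
      f[components[e], idx] <- peaks[e] * 0.5 * (1 - cos(2 * pi * tau))
    }
    structure(
      list(t = t, f = f, fs = cfg$fs,
           episode_table = data.frame(
             start = starts, end = starts + durations,
             component = components, peak = peaks)),
      class = "force_profile")
  })
}

# Band-limited unit-RMS Gaussian carrier via FFT masking: exact pass-band
# support, deterministic under the caller's RNG state.
bandlimited_noise <- function(m, fs, band) {
  white <- rnorm(m)
  spec <- fft(white)
  freq <- (seq_len(m) - 1) * fs / m
  folded <- pmin(freq, fs - freq)
  spec[folded < band[1] | folded > band[2]] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / m
  x / sqrt(mean(x^2))
}

#' Synthesize a multichannel sEMG recording from a force profile
#'
#' Each channel is amplitude-modulated band-limited Gaussian noise: the
#' modulation envelope is `noise_floor + gain %*% g(drive)`, where the drives
#' are the rectified force components (split by sign when
#' `rectify_per_sign`) and `g` is the configured amplitude law. Optional
#' 50 Hz interference and the DC level shift are added, then the signal is
#' clipped to the converter range and quantized to the ADC grid.
#'
#' @param profile A [generate_force_profile()] result.
#' @param cfg The [sim_config()] used to generate it.
#' @return An [emg_recording()].
#' @export
synthesize_emg <- function(profile, cfg) {
  stopifnot(inherits(profile, "force_profile"), inherits(cfg, "sim_config"))
  if (cfg$fs < 2 * cfg$emg_band[2]) {
    stop(sprintf(
      paste("`fs` = %g Hz cannot carry a %g Hz band: raise `fs` to at least",
            "%g Hz or narrow `emg_band`"),
      cfg$fs, cfg$emg_band[2], 2 * cfg$emg_band[2]), call. = FALSE)
  }
  f <- profile$f
  drives <- if (cfg$rectify_per_sign && nrow(f) >= 1 && cfg$task != "grip") {
    # interleave positive/negative half-waves per component
    do.call(rbind, lapply(seq_len(nrow(f)), function(k) {
      rbind(pmax(f[k, ], 0), pmax(-f[k, ], 0))
    }))
  } else {
    abs(f)
  }
  if (ncol(cfg$gain_matrix) != nrow(drives)) {
    stop(sprintf(
      "`gain_matrix` has %d columns but the force profile provides %d drives",
      ncol(cfg$gain_matrix), nrow(drives)), call. = FALSE)
  }
  g <- switch(cfg$amplitude_law,
    linear = function(u) u,
    # saturating law, equal to the linear one at the task's force bound
    sqrt = function(u) sqrt(u * cfg$force_bound))
  envelope <- cfg$noise_floor + cfg$gain_matrix %*% g(drives)
  m <- ncol(f)
  # carrier seed offset from the profile seed so that two profiles generated
  # under one config share their carrier noise exactly
  signals <- with_seed(cfg$seed + 1L, {
    vapply(seq_len(cfg$n_channels), function(ch) {
      bandlimited_noise(m, cfg$fs, cfg$emg_band)
    }, numeric(m))
  })
  raw <- t(signals) * envelope + cfg$dc_offset
  if (cfg$mains_amplitude > 0) {
    mains <- cfg$mains_amplitude * sin(2 * pi * 50 * profile$t)
    raw <- raw + matrix(mains, nrow = cfg$n_channels, ncol = m, byrow = TRUE)
  }
  lo <- cfg$adc_range[1]; hi <- cfg$adc_range[2]
  step <- (hi - lo) / (2^cfg$adc_bits - 1)
  quantized <- pmin(pmax(raw, lo), hi)
  quantized <- round((quantized - lo) / step) * step + lo
  emg_recording(quantized, fs = cfg$fs,
                channel_sites = emg_sites()[seq_len(cfg$n_channels)])
}

#' Simulate a complete synchronized sEMG + force session
#'
#' Convenience wrapper chaining [generate_force_profile()] and
#' [synthesize_emg()], returning the paired recordings.
#'
#' @inheritParams generate_force_profile
#' @return List with `emg` ([emg_recording()]), `force`
#'   ([force_recording()]) and `profile` (the [generate_force_profile()]
#'   output).
#' @export
simulate_session <- function(cfg, n_episodes) {
  profile <- generate_force_profile(cfg, n_episodes)
  emg <- synthesize_emg(profile, cfg)
  force <- force_recording(profile$f,
                           kind = if (cfg$task == "grip") "grip" else "force3d",
                           fs = cfg$fs)
  list(emg = emg, force = force, profile = profile)
}
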