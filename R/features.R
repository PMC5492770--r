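#' Time-domain sEMG window features
#'
#' The four classical time-domain descriptors used for myoelectric force
#' estimation, each computed on one analysis window of `N` samples:
#'
#' * `mav(x)` — mean absolute value, `(1/N) * sum(|x_j|)`.
#' * `var_feature(x)` — mean square, `(1/N) * sum(x_j^2)`. Note this is the
#'   raw second moment, not the mean-centered sample variance: a constant
#'   window `c` scores `c^2`.
#' * `zc(x, variant)` — adjacent-sample product test over the `N - 1`
#'   in-window pairs. The `"as_printed"` variant counts pairs whose product
#'   is strictly positive (same-sign pairs, via the step function
#'   `sgn(u) = 1` for `u > 0`, else 0); `"sign_change"` counts strictly
#'   negative products, the conventional zero-crossing count.
#' * `wa(x, threshold)` — Willison amplitude: the number of consecutive-sample
#'   differences whose magnitude strictly exceeds `threshold` (volts).
#'
#' @param window Numeric vector, one analysis window.
#' @param variant `"as_printed"` (same-sign pairs) or `"sign_change"`
#'   (conventional crossings).
#' @param threshold Nonnegative difference threshold in volts.
#' @return A single number (`zc` and `wa` are integer-valued counts).
#' @name td_features
NULL

check_window <- function(window, min_len = 1L) {
  if (!is.numeric(window) || length(window) < min_len) {
    stop(sprintf("window must be numeric with at least %d sample(s)", min_len),
         call. = FALSE)
  }
  if (anyNA(window)) stop("window contains missing values", call. = FALSE)
  invisible(window)
}

#' @rdname td_features
#' @export
mav <- function(window) {
  check_window(window)
  mean(abs(window))
}

#' @rdname td_features
#' @export
var_feature <- function(window) {
  check_window(window)
  mean(window^2)
}

#' @rdname td_features
#' @export
zc <- function(window, variant = c("as_printed", "sign_change")) {
  variant <- match.arg(variant)
  check_window(window, min_len = 2L)
  prods <- window[-1] * window[-length(window)]
  if (variant == "as_printed") sum(prods > 0) else sum(prods < 0)
}

#' @rdname td_features
#' @export
wa <- function(window, threshold) {
  check_window(window, min_len = 2L)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("`threshold` must be a single number", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  sum(abs(diff(window)) > threshold)
}

#' Feature-extraction configuration
#'
#' @param window_len Window length `N` in samples (default 200: 200 ms at
#'   1 kHz, a standard myoelectric-control latency budget).
#' @param step Hop between consecutive windows, samples (default 50).
#' @param feature One of `"MAV"`, `"VAR"`, `"ZC"`, `"WA"`.
#' @param wa_threshold Willison threshold in volts, or `NULL` to derive it
#'   from the recording: 3 times the per-channel median absolute successive
#'   difference over a rest segment (the first 0.5 s by default).
#' @param zc_variant Zero-crossing convention, see [zc()].
#' @param remove_offset Subtract each window's mean before computing the
#'   feature, so features reflect EMG activity rather than the acquisition
#'   chain's DC level shift. Default `TRUE`.
#' @param rest_seconds Length of the leading rest segment used for the
#'   adaptive Willison threshold.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(window_len = 200L, step = 50L,
                           feature = c("MAV", "VAR", "ZC", "WA"),
                           wa_threshold = NULL,
                           zc_variant = c("as_printed", "sign_change"),
                           remove_offset = TRUE,
                           rest_seconds = 0.5) {
  feature <- match.arg(feature)
  zc_variant <- match.arg(zc_variant)
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  if (window_len < 1L) stop("`window_len` must be >= 1", call. = FALSE)
  if (step < 1L || step > window_len) {
    stop("`step` must satisfy 1 <= step <= window_len", call. = FALSE)
  }
  if (!is.null(wa_threshold) && wa_threshold < 0) {
    stop("`wa_threshold` must be >= 0", call. = FALSE)
  }
  structure(list(window_len = window_len, step = step, feature = feature,
                 wa_threshold = wa_threshold, zc_variant = zc_variant,
                 remove_offset = remove_offset, rest_seconds = rest_seconds),
            class = "feature_config")
}

feature_fun <- function(cfg, wa_threshold) {
  switch(cfg$feature,
    MAV = mav,
    VAR = var_feature,
    ZC = function(w) zc(w, cfg$zc_variant),
    WA = function(w) wa(w, wa_threshold))
}

#' Sliding-window feature extraction over all channels
#'
#' Evaluates the configured time-domain feature on every window of every
#' channel. Windows end at samples `N, N + step, N + 2*step, ...`, giving
#' `floor((m - N) / step) + 1` windows for an `m`-sample recording. With
#' `remove_offset` the per-window mean is subtracted first (for ZC this mean
#' removal precedes the sign-product tests).
#'
#' @param rec An [emg_recording()].
#' @param cfg A [feature_config()].
#' @return Object of class `feature_matrix`: `values`
#'   (`channels x n_windows`), `window_ends` (sample indices), `feature`,
#'   `config` (with any adaptive Willison threshold resolved per channel),
#'   and `fs`.
#' @export
sliding_features <- function(rec, cfg = feature_config()) {
  stopifnot(inherits(rec, "emg_recording"), inherits(cfg, "feature_config"))
  m <- ncol(rec$samples)
  N <- cfg$window_len
  if (m < N) {
    stop(sprintf("recording has %d samples, shorter than the %d-sample window",
                 m, N), call. = FALSE)
  }
  n_ch <- nrow(rec$samples)
  ends <- seq.int(N, m, by = cfg$step)
  wa_thresholds <- rep(NA_real_, n_ch)
  if (cfg$feature == "WA") {
    if (is.null(cfg$wa_threshold)) {
      rest_len <- max(2L, min(m, as.integer(round(cfg$rest_seconds * rec$fs))))
      rest <- rec$samples[, seq_len(rest_len), drop = FALSE]
      wa_thresholds <- vapply(seq_len(n_ch), function(ch) {
        3 * median(abs(diff(rest[ch, ])))
      }, numeric(1))
    } else {
      wa_thresholds <- rep(cfg$wa_threshold, n_ch)
    }
  }
  values <- matrix(0, nrow = n_ch, ncol = length(ends))
  for (ch in seq_len(n_ch)) {
    fun <- feature_fun(cfg, wa_thresholds[ch])
    x <- rec$samples[ch, ]
    for (w in seq_along(ends)) {
      win <- x[(ends[w] - N + 1L):ends[w]]
      if (cfg$remove_offset) win <- win - mean(win)
      values[ch, w] <- fun(win)
    }
  }
  cfg$resolved_wa_threshold <- wa_thresholds
  structure(list(values = values, window_ends = ends, feature = cfg$feature,
                 config = cfg, fs = rec$fs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d channels x %d windows (N=%d, step=%d)\n",
              x$feature, nrow(x$values), ncol(x$values),
              x$config$window_len, x$config$step))
  invisible(x)
}

#' Pair feature windows with force targets
#'
#' Builds the training set for the regressor: one row per analysis window,
#' one input column per channel, and the synchronized force sampled at each
#' window's final sample as the target (a causal labelling suited to online
#' estimation).
#'
#' @param fm A [sliding_features()] result.
#' @param force The session's [force_recording()].
#' @return Object of class `training_set`: `x` (`n_windows x channels`
#'   feature matrix), `y` (`n_windows x (1 or 3)` force targets, N),
#'   `window_ends`, `kind`.
#' @export
assemble_training <- function(fm, force) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(force, "force_recording"))
  if (fm$fs != force$fs) {
    stop("feature matrix and force recording have different sampling rates",
         call. = FALSE)
  }
  if (max(fm$window_ends) > ncol(force$values)) {
    stop(sprintf(
      "window ends reach sample %d but the force recording has %d samples",
      max(fm$window_ends), ncol(force$values)), call. = FALSE)
  }
  y <- t(force$values[, fm$window_ends, drop = FALSE])
  colnames(y) <- rownames(force$values)
  structure(list(x = t(fm$values), y = y, window_ends = fm$window_ends,
                 kind = force$kind, feature = fm$feature),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d windows, %d feature(s), %d output(s) [%s]\n",
              nrow(x$x), ncol(x$x), ncol(x$y), x$kind))
  invisible(x)
}
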