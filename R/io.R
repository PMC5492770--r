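# 17 significant digits round-trip IEEE doubles exactly through text
fmt_full <- function(x) sprintf("%.17g", x)

#' Multichannel sEMG recording
#'
#' Container for a synchronized block of surface EMG samples: one row per
#' channel, in volts, on a common clock.
#'
#' @param samples Numeric `channels x m` matrix of voltages.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_sites Character labels for the recording sites; defaults to
#'   the first `n_channels` entries of [emg_sites()].
#' @param t0 Time of the first sample, seconds.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_sites = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 1L) stop("recording must hold at least one sample",
                               call. = FALSE)
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (is.null(channel_sites)) {
    channel_sites <- emg_sites()[seq_len(nrow(samples))]
  }
  if (length(channel_sites) != nrow(samples)) {
    stop("`channel_sites` must name every channel", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs,
                 channel_sites = channel_sites, t0 = t0),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("sites:", paste(x$channel_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Synchronized force recording
#'
#' Grip force (one nonnegative row) or 3D push-pull force (three signed
#' rows: x, y, z; negative values mean the reverse direction), in newtons,
#' sharing the EMG clock.
#'
#' @param values Numeric `(1 or 3) x m` matrix of forces, N.
#' @param kind `"grip"` or `"force3d"`.
#' @param fs Sampling rate in Hz.
#' @return Object of class `force_recording`.
#' @export
force_recording <- function(values, kind = c("grip", "force3d"), fs) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind == "grip") {
    if (nrow(values) != 1L && ncol(values) == 1L) values <- t(values)
    if (nrow(values) != 1L) stop("grip force must be a single row",
                                 call. = FALSE)
    if (any(values < 0)) stop("grip force must be nonnegative", call. = FALSE)
  } else if (nrow(values) != 3L) {
    stop("3D force must have rows x, y, z", call. = FALSE)
  }
  stop_if_not_scalar_number(fs, "fs")
  rownames(values) <- if (kind == "grip") "grip" else c("x", "y", "z")
  structure(list(kind = kind, values = values, fs = fs),
            class = "force_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> kind=%s, %d x %d samples @ %g Hz, peak %.2f N\n",
              x$kind, nrow(x$values), ncol(x$values), x$fs,
              max(abs(x$values))))
  invisible(x)
}

#' Write a synchronized session to delimited text
#'
#' One row per sample: time, `emg_1..emg_n` (V), then `force_grip` or
#' `force_x/force_y/force_z` (N). A YAML sidecar (`<path>.yaml`) stores the
#' sampling rate, task kind, channel site labels and, when supplied, the
#' simulation seed. Values are written with shortest round-trip precision so
#' quantized simulator output survives a write/read cycle bit-exactly.
#'
#' @param emg An [emg_recording()].
#' @param force The paired [force_recording()].
#' @param path Output CSV path.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_session <- function(emg, force, path, seed = NULL) {
  stopifnot(inherits(emg, "emg_recording"), inherits(force, "force_recording"))
  if (ncol(emg$samples) != ncol(force$values)) {
    stop("EMG and force recordings have different lengths", call. = FALSE)
  }
  if (emg$fs != force$fs) {
    stop("EMG and force recordings have different sampling rates",
         call. = FALSE)
  }
  m <- ncol(emg$samples)
  t <- emg$t0 + (seq_len(m) - 1) / emg$fs
  df <- data.table::data.table(time = fmt_full(t))
  for (ch in seq_len(nrow(emg$samples))) {
    df[[paste0("emg_", ch)]] <- fmt_full(emg$samples[ch, ])
  }
  fcols <- if (force$kind == "grip") "force_grip" else
    c("force_x", "force_y", "force_z")
  for (k in seq_along(fcols)) df[[fcols[k]]] <- fmt_full(force$values[k, ])
  data.table::fwrite(df, path, quote = FALSE)
  sidecar <- list(fs = emg$fs, kind = force$kind,
                  channel_sites = as.list(emg$channel_sites), t0 = emg$t0)
  if (!is.null(seed)) sidecar$seed <- seed
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a synchronized session written by [write_session()]
#'
#' @param path CSV path; the `<path>.yaml` sidecar must sit next to it.
#' @return List with elements `emg` ([emg_recording()]) and `force`
#'   ([force_recording()]).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such session file: %s", path),
                               call. = FALSE)
  sidecar_path <- paste0(path, ".yaml")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing sidecar metadata: %s", sidecar_path), call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar_path)
  df <- data.table::fread(path, fill = TRUE)
  emg_cols <- grep("^emg_[0-9]+$", names(df), value = TRUE)
  force_cols <- grep("^force_", names(df), value = TRUE)
  if (length(emg_cols) == 0L || length(force_cols) == 0L) {
    stop("session file must contain emg_* and force_* columns", call. = FALSE)
  }
  bad <- names(df)[vapply(df, function(col) anyNA(col), logical(1))]
  if (length(bad)) {
    stop(sprintf("malformed session file: missing values in column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  kind <- if (length(force_cols) == 1L) "grip" else
    if (length(force_cols) == 3L) "force3d" else
      stop(sprintf("cannot infer force kind from %d force columns",
                   length(force_cols)), call. = FALSE)
  if (!is.null(meta$kind) && !identical(meta$kind, kind)) {
    stop(sprintf("sidecar declares kind '%s' but file has %d force column(s)",
                 meta$kind, length(force_cols)), call. = FALSE)
  }
  emg <- emg_recording(unname(t(as.matrix(df[, emg_cols, with = FALSE]))),
                       fs = meta$fs,
                       channel_sites = unlist(meta$channel_sites),
                       t0 = if (is.null(meta$t0)) df$time[1] else meta$t0)
  force_cols <- if (kind == "grip") "force_grip" else
    c("force_x", "force_y", "force_z")
  force <- force_recording(unname(t(as.matrix(df[, force_cols, with = FALSE]))),
                           kind = kind, fs = meta$fs)
  list(emg = emg, force = force)
}

#' Persist a fitted GRNN model
#'
#' Serializes the stored training pairs, smoothing parameter and feature
#' scaling constants to JSON at full numeric precision, so a restored model
#' reproduces the original's predictions exactly.
#'
#' @param model A fitted model from [grnn_fit()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "grnn_model")) {
    stop("`model` must be a fitted grnn_model", call. = FALSE)
  }
  payload <- list(
    format = "semgforce-grnn", version = 1L,
    sigma = model$sigma,
    center = model$center, scale = model$scale,
    x = model$x, y = model$y,
    output_names = model$output_names)
  # 17 significant digits: lossless for IEEE doubles
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "semgforce-grnn")) {
    stop("not a semgforce GRNN model file", call. = FALSE)
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop(sprintf("unsupported model version: %s", payload$version),
         call. = FALSE)
  }
  x <- as.matrix(payload$x)
  y <- as.matrix(payload$y)
  structure(list(x = x, y = y, sigma = payload$sigma,
                 center = payload$center, scale = payload$scale,
                 n = nrow(x), d = ncol(x), L = ncol(y),
                 output_names = payload$output_names),
            class = "grnn_model")
}

#' Write / read a feature matrix as delimited text
#'
#' Columns: `window_end`, then one column per channel. The extraction
#' configuration travels in a YAML sidecar.
#'
#' @param fm A [sliding_features()] result.
#' @param path Output CSV path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.table::data.table(window_end = fm$window_ends)
  for (ch in seq_len(nrow(fm$values))) {
    df[[paste0("ch_", ch)]] <- fmt_full(fm$values[ch, ])
  }
  data.table::fwrite(df, path, quote = FALSE)
  cfg <- fm$config
  yaml::write_yaml(list(feature = cfg$feature, window_len = cfg$window_len,
                        step = cfg$step, wa_threshold = cfg$wa_threshold,
                        zc_variant = cfg$zc_variant,
                        remove_offset = cfg$remove_offset, fs = fm$fs),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- data.table::fread(path)
  ch_cols <- grep("^ch_[0-9]+$", names(df), value = TRUE)
  cfg <- feature_config(window_len = meta$window_len, step = meta$step,
                        feature = meta$feature,
                        wa_threshold = meta$wa_threshold,
                        zc_variant = meta$zc_variant,
                        remove_offset = meta$remove_offset)
  structure(list(values = unname(t(as.matrix(df[, ch_cols, with = FALSE]))),
                 window_ends = df$window_end, feature = meta$feature,
                 config = cfg, fs = meta$fs),
            class = "feature_matrix")
}
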