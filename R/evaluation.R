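#' Estimation-accuracy metrics
#'
#' Three criteria comparing an estimated force series against the measured
#' one:
#'
#' * `mave_metric` — mean absolute value of the estimation error,
#'   `sum(|est - act|) / N`.
#' * `rms_metric` — root mean square of the estimation error with an `N - 1`
#'   denominator, `sqrt(sum((est - act)^2) / (N - 1))`; larger values flag a
#'   larger fluctuation of the error.
#' * `pearson_rho` — Pearson correlation between the two series, in
#'   `[-1, 1]`; reported in percent in printed tables.
#'
#' @param est,act Numeric vectors of equal length (estimated and measured
#'   force, N).
#' @return A single number.
#' @name accuracy_metrics
NULL

check_pair <- function(est, act, min_len = 1L) {
  if (length(est) != length(act)) {
    stop(sprintf("length mismatch: est has %d values, act has %d",
                 length(est), length(act)), call. = FALSE)
  }
  if (length(est) < min_len) {
    stop(sprintf("need at least %d points", min_len), call. = FALSE)
  }
  if (anyNA(est) || anyNA(act)) stop("inputs contain missing values",
                                     call. = FALSE)
}

#' @rdname accuracy_metrics
#' @export
mave_metric <- function(est, act) {
  check_pair(est, act)
  mean(abs(est - act))
}

#' @rdname accuracy_metrics
#' @export
rms_metric <- function(est, act) {
  check_pair(est, act, min_len = 2L)
  sqrt(sum((est - act)^2) / (length(est) - 1))
}

#' @rdname accuracy_metrics
#' @export
pearson_rho <- function(est, act) {
  check_pair(est, act, min_len = 2L)
  if (sd(est) == 0 || sd(act) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  cor(est, act)
}

#' Seeded k-fold partition
#'
#' Randomly partitions `1..n` into `k` groups of near-equal size (sizes
#' differ by at most one). The same seed always yields the same partition.
#'
#' @param n Number of samples, or a `training_set` whose rows are counted.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 2L, seed = 1L) {
  if (inherits(n, "training_set")) n <- nrow(n$x)
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("cannot split %d samples into %d folds", n, k),
                  call. = FALSE)
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(k), n))
    unname(split(seq_len(n), labels))
  })
}

subset_training <- function(ts, idx) {
  list(x = ts$x[idx, , drop = FALSE], y = ts$y[idx, , drop = FALSE])
}

#' k-fold cross-validated GRNN evaluation
#'
#' Splits the windowed training set into `k` folds, trains a GRNN on the
#' other `k - 1` folds, predicts the held-out fold, and averages the
#' per-output-dimension accuracy metrics over the `k` validation folds
#' (k = 2 being the protocol used for the reference experiments).
#'
#' @param ts A training set (see [grnn_fit()]).
#' @param sigma GRNN smoothing parameter.
#' @param k Number of folds (default 2).
#' @param seed Seed for the fold assignment.
#' @param standardize Passed to [grnn_fit()].
#' @return Object of class `evaluation_report`: `metrics` (data.frame with
#'   one row per output dimension: `mave`, `rms`, `rho`), `per_fold` (the
#'   fold-level tables), `n_points`, `k`, `sigma`.
#' @export
cross_validate <- function(ts, sigma, k = 2L, seed = 1L, standardize = TRUE) {
  folds <- kfold_split(nrow(ts$x), k = k, seed = seed)
  dims <- colnames(ts$y)
  if (is.null(dims)) dims <- paste0("dim", seq_len(ncol(ts$y)))
  per_fold <- lapply(seq_along(folds), function(i) {
    val <- folds[[i]]
    model <- grnn_fit(subset_training(ts, -val), sigma,
                      standardize = standardize)
    pred <- predict(model, ts$x[val, , drop = FALSE])
    data.frame(
      fold = i, dimension = dims,
      mave = vapply(seq_along(dims), function(j)
        mave_metric(pred[, j], ts$y[val, j]), numeric(1)),
      rms = vapply(seq_along(dims), function(j)
        rms_metric(pred[, j], ts$y[val, j]), numeric(1)),
      rho = vapply(seq_along(dims), function(j)
        pearson_rho(pred[, j], ts$y[val, j]), numeric(1)),
      row.names = NULL)
  })
  all_folds <- do.call(rbind, per_fold)
  metrics <- do.call(rbind, lapply(dims, function(d) {
    sub <- all_folds[all_folds$dimension == d, ]
    data.frame(dimension = d, mave = mean(sub$mave), rms = mean(sub$rms),
               rho = mean(sub$rho))
  }))
  structure(list(metrics = metrics, per_fold = all_folds,
                 n_points = nrow(ts$x), k = k, sigma = as.numeric(sigma)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV on %d windows (sigma = %g)\n",
              x$k, x$n_points, x$sigma))
  out <- x$metrics
  out$rho <- 100 * out$rho  # percent, as conventionally reported
  names(out) <- c("dimension", "MAVE (N)", "RMS (N)", "rho (%)")
  print(out, row.names = FALSE, digits = 4)
  invisible(x)
}
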