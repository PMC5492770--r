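#' Fit a Generalized Regression Neural Network
#'
#' A GRNN is an instance-based Gaussian-kernel regressor (Nadaraya-Watson
#' estimator): the pattern layer holds one unit per training sample, and a
#' prediction is the kernel-weighted average of the stored outputs,
#' \deqn{\hat y_j(x) = \frac{\sum_i y_{ij} P_i}{\sum_i P_i},\qquad
#'       P_i = \exp\!\left(-\frac{\lVert x - x_i\rVert^2}{2\sigma^2}\right).}
#' There is no iterative training: fitting stores the (optionally
#' standardized) inputs and raw outputs.
#'
#' Features are standardized by default (training mean/SD per column) before
#' distances are computed, since descriptors such as mean square and
#' zero-crossing counts live on incommensurate scales; `sigma` is then
#' expressed in standardized units.
#'
#' @param ts A [assemble_training()] result, or any list with numeric
#'   matrices `x` (n x d inputs) and `y` (n x L outputs).
#' @param sigma Positive smoothing parameter (kernel width) shared by all
#'   input dimensions.
#' @param standardize Center/scale inputs by training statistics. Default
#'   `TRUE`.
#' @return Object of class `grnn_model` holding the `n` pattern units
#'   (exactly one per training sample), outputs, `sigma` and the scaler.
#' @export
grnn_fit <- function(ts, sigma, standardize = TRUE) {
  x <- as.matrix(ts$x)
  y <- as.matrix(ts$y)
  stop_if_not_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (nrow(x) < 1L) stop("need at least one training sample", call. = FALSE)
  if (nrow(x) != nrow(y)) {
    stop("`x` and `y` must have one row per training sample", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("training data contain non-finite values", call. = FALSE)
  }
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  }
  x_std <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(x = x_std, y = y, sigma = sigma,
                 center = center, scale = scale,
                 n = nrow(x), d = ncol(x), L = ncol(y),
                 output_names = colnames(y)),
            class = "grnn_model")
}

#' @export
print.grnn_model <- function(x, ...) {
  cat(sprintf("<grnn_model> %d pattern units, %d inputs -> %d outputs, sigma = %g\n",
              x$n, x$d, x$L, x$sigma))
  invisible(x)
}

#' Predict with a fitted GRNN
#'
#' Evaluates the kernel-weighted average at each probe. Kernel weights are
#' computed in the log domain and shifted by their row maximum before
#' exponentiation, so predictions remain defined for probes arbitrarily far
#' from the training set (degrading gracefully to the nearest neighbour's
#' output) instead of underflowing to 0/0. Every prediction is a convex
#' combination of the stored training outputs.
#'
#' @param object A `grnn_model`.
#' @param newdata Numeric probe: a d-vector or an `q x d` matrix.
#' @param ... Unused.
#' @return A `q x L` matrix of predicted outputs, columns named after the
#'   output dimensions.
#' @export
predict.grnn_model <- function(object, newdata, ...) {
  q <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(q) != object$d) {
    stop(sprintf("probe has %d features but the model expects %d",
                 ncol(q), object$d), call. = FALSE)
  }
  if (!all(is.finite(q))) stop("probe contains non-finite values",
                               call. = FALSE)
  q_std <- sweep(sweep(q, 2, object$center), 2, object$scale, "/")
  x <- object$x
  d2 <- outer(rowSums(q_std^2), rep(1, object$n)) +
    outer(rep(1, nrow(q_std)), rowSums(x^2)) -
    2 * tcrossprod(q_std, x)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  logw <- -d2 / (2 * object$sigma^2)
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  pred <- (w %*% object$y) / rowSums(w)
  colnames(pred) <- object$output_names
  pred
}

#' Select the GRNN smoothing parameter by cross-validation
#'
#' Evaluates each candidate `sigma` by k-fold cross-validated mean absolute
#' estimation error (averaged over output dimensions and folds) and returns
#' the minimizer. Fold assignment is seeded, so the choice is reproducible.
#'
#' @param ts A training set (see [grnn_fit()]).
#' @param grid Positive candidate values; default 10 points log-spaced over
#'   `[0.05, 2]` in standardized feature units.
#' @param k Number of folds (default 2).
#' @param seed Seed for the fold assignment.
#' @param standardize Passed to [grnn_fit()].
#' @return The selected `sigma` (scalar), with the per-candidate CV errors
#'   attached as attribute `"cv_error"`.
#' @export
select_sigma <- function(ts, grid = exp(seq(log(0.05), log(2), length.out = 10)),
                         k = 2L, seed = 1L, standardize = TRUE) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid <= 0)) stop("`grid` values must be positive", call. = FALSE)
  errs <- vapply(grid, function(s) {
    rep <- cross_validate(ts, sigma = s, k = k, seed = seed,
                          standardize = standardize)
    mean(rep$metrics$mave)
  }, numeric(1))
  best <- grid[which.min(errs)]
  attr(best, "cv_error") <- data.frame(sigma = grid, mave = errs)
  best
}
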