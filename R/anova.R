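#' One-way analysis of variance
#'
#' Classical one-way ANOVA comparing group means (here: an accuracy metric
#' measured for each EMG feature across subjects). The decomposition is
#' fitted with [stats::aov()] and reported in the familiar
#' between/within/total layout.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return Object of class `anova_table`: a data.frame with columns
#'   `source`, `sum_sq`, `df`, `mean_sq`, `F`, `p`; attributes `design`
#'   (`"oneway"`), `mse`, `df_error`, `group_means`, `group_n`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop(sprintf("every group needs n >= 2 (got %s)",
                 paste(sizes, collapse = ", ")), call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), sizes), levels = names(groups))
  a <- anova(aov(value ~ group))
  ss <- a$`Sum Sq`; dfs <- a$Df
  tbl <- data.frame(
    source = c("Between groups", "Within groups", "Total"),
    sum_sq = c(ss[1], ss[2], sum(ss)),
    df = c(dfs[1], dfs[2], sum(dfs)),
    mean_sq = c(ss[1] / dfs[1], ss[2] / dfs[2], NA),
    F = c(a$`F value`[1], NA, NA),
    p = c(a$`Pr(>F)`[1], NA, NA))
  structure(tbl, class = c("anova_table", "data.frame"),
            design = "oneway", mse = ss[2] / dfs[2], df_error = dfs[2],
            group_means = vapply(groups, mean, numeric(1)),
            group_n = sizes)
}

#' Main-effects two-way analysis of variance
#'
#' Balanced two-factor ANOVA without an interaction term (the model used to
#' compare EMG features and force directions jointly: metric ~ direction +
#' feature, with subjects as replicates). Reported in the conventional
#' full-table layout with corrected-model, intercept, per-factor, error,
#' total and corrected-total rows; in a balanced design these Type III sums
#' of squares coincide with the sequential ones produced by
#' [stats::aov()].
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length as
#'   `values`; every `a x b` cell must hold the same number of replicates.
#' @param names_ab Labels for the two factor rows in the table.
#' @return An `anova_table` (see [oneway_anova()]) with `design =
#'   "twoway_main_effects"`; `group_means`/`group_n` refer to `factor_b`
#'   (the feature factor) for downstream Tukey comparisons.
#' @export
twoway_anova_main <- function(values, factor_a, factor_b,
                              names_ab = c("Force direction", "EMG feature")) {
  factor_a <- as.factor(factor_a)
  factor_b <- as.factor(factor_b)
  if (length(values) != length(factor_a) || length(values) != length(factor_b)) {
    stop("`values`, `factor_a` and `factor_b` must have equal length",
         call. = FALSE)
  }
  cell_n <- table(factor_a, factor_b)
  if (length(unique(as.vector(cell_n))) != 1L || any(cell_n == 0)) {
    stop("unbalanced layout: every factor_a x factor_b cell needs the same ",
         "number of replicates", call. = FALSE)
  }
  n <- length(values)
  # single-level factors contribute zero SS on zero df; drop them from the
  # fit so the model matrix stays full rank
  terms <- c(a = nlevels(factor_a) > 1L, b = nlevels(factor_b) > 1L)
  rhs <- paste(c("factor_a", "factor_b")[terms], collapse = " + ")
  if (rhs == "") rhs <- "1"
  a <- anova(aov(stats::as.formula(paste("values ~", rhs))))
  get_row <- function(nm, empty_df) {
    i <- match(nm, rownames(a))
    if (is.na(i)) c(ss = 0, df = empty_df) else
      c(ss = a$`Sum Sq`[i], df = a$Df[i])
  }
  row_a <- get_row("factor_a", nlevels(factor_a) - 1L)
  row_b <- get_row("factor_b", nlevels(factor_b) - 1L)
  row_e <- get_row("Residuals", NA)
  ss <- unname(c(row_a["ss"], row_b["ss"], row_e["ss"]))
  dfs <- unname(c(row_a["df"], row_b["df"], row_e["df"]))
  mse <- ss[3] / dfs[3]
  ss_model <- ss[1] + ss[2]
  df_model <- dfs[1] + dfs[2]
  ss_intercept <- n * mean(values)^2
  rows <- data.frame(
    source = c("Corrected model", "Intercept", names_ab, "Error", "Total",
               "Corrected total"),
    sum_sq = c(ss_model, ss_intercept, ss[1], ss[2], ss[3],
               sum(values^2), sum(ss)),
    df = c(df_model, 1L, dfs[1], dfs[2], dfs[3], n, n - 1L),
    mean_sq = c(ss_model / df_model, ss_intercept, ss[1] / dfs[1],
                ss[2] / dfs[2], mse, NA, NA),
    F = c((ss_model / df_model) / mse, ss_intercept / mse,
          (ss[1] / dfs[1]) / mse, (ss[2] / dfs[2]) / mse, NA, NA, NA),
    p = NA)
  rows$p[1:4] <- pf(rows$F[1:4], rows$df[1:4], dfs[3], lower.tail = FALSE)
  structure(rows, class = c("anova_table", "data.frame"),
            design = "twoway_main_effects", mse = mse, df_error = dfs[3],
            group_means = tapply(values, factor_b, mean),
            group_n = as.vector(table(factor_b)))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("<anova_table> design = %s\n", attr(x, "design")))
  out <- as.data.frame(x)
  out$sum_sq <- round(out$sum_sq, 3)
  out$mean_sq <- round(out$mean_sq, 3)
  out$F <- round(out$F, 3)
  out$p <- signif(out$p, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD comparisons and homogeneous subsets
#'
#' Pairwise studentized-range tests between group means, plus the familiar
#' homogeneous-subset table: groups are sorted by mean and a subset is a
#' maximal run of consecutive groups whose extreme means do not differ
#' significantly under the studentized range with the full number of groups
#' and the error degrees of freedom. Each subset's `sig` is the p-value of
#' that extreme-pair range test (1 for singleton subsets). Requires equal
#' group sizes.
#'
#' @param groups Named list of equal-length numeric vectors, or `NULL` when
#'   `means`/`n` are given directly.
#' @param alpha Significance level (default 0.05).
#' @param mse,df_error Error mean square and degrees of freedom from the
#'   accompanying ANOVA. Computed from a one-way ANOVA of `groups` when
#'   omitted; pass the values from [twoway_anova_main()] to compare feature
#'   means adjusted for a second factor.
#' @param means,n Alternative direct interface: named vector of group means
#'   and common group size (then `mse`/`df_error` are required).
#' @return Object of class `tukey_result`: `means` (sorted increasing), `n`,
#'   `subsets` (list of character vectors), `subset_sig`, `pairwise`
#'   (data.frame with `group1`, `group2`, `diff`, `p_adj`), `alpha`.
#' @export
tukey_hsd <- function(groups = NULL, alpha = 0.05, mse = NULL,
                      df_error = NULL, means = NULL, n = NULL) {
  if (!is.null(groups)) {
    sizes <- lengths(groups)
    if (length(unique(sizes)) != 1L) {
      stop("Tukey HSD here requires equal group sizes", call. = FALSE)
    }
    n <- sizes[[1]]
    if (is.null(mse) || is.null(df_error)) {
      a <- oneway_anova(groups)
      mse <- attr(a, "mse")
      df_error <- attr(a, "df_error")
    }
    means <- vapply(groups, mean, numeric(1))
  } else if (is.null(means) || is.null(n) || is.null(mse) ||
             is.null(df_error)) {
    stop("supply `groups`, or all of `means`, `n`, `mse`, `df_error`",
         call. = FALSE)
  }
  k <- length(means)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  se <- sqrt(mse / n)
  ord <- order(means)
  m_sorted <- means[ord]
  range_p <- function(i, j) {
    if (i == j) return(1)
    unname(ptukey((m_sorted[j] - m_sorted[i]) / se, nmeans = k,
                  df = df_error, lower.tail = FALSE))
  }
  # sweep over ordered means: extend each run while its extremes agree
  subsets <- list(); sig <- numeric(0)
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && range_p(i, j + 1L) > alpha) j <- j + 1L
    if (length(subsets) == 0L ||
        !all(names(m_sorted)[i:j] %in% subsets[[length(subsets)]])) {
      subsets[[length(subsets) + 1L]] <- names(m_sorted)[i:j]
      sig <- c(sig, range_p(i, j))
    }
    i <- i + 1L
  }
  pairs <- utils::combn(k, 2)
  pairwise <- data.frame(
    group1 = names(m_sorted)[pairs[1, ]],
    group2 = names(m_sorted)[pairs[2, ]],
    diff = unname(m_sorted[pairs[2, ]] - m_sorted[pairs[1, ]]),
    p_adj = vapply(seq_len(ncol(pairs)), function(c)
      range_p(pairs[1, c], pairs[2, c]), numeric(1)),
    row.names = NULL)
  structure(list(means = m_sorted, n = n, subsets = subsets,
                 subset_sig = sig, pairwise = pairwise, alpha = alpha,
                 mse = mse, df_error = df_error),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  k <- length(x$means)
  cat(sprintf("<tukey_result> %d groups, n = %d, alpha = %g\n",
              k, x$n, x$alpha))
  tab <- matrix("", nrow = k + 1L, ncol = length(x$subsets) + 2L)
  tab[seq_len(k), 1] <- names(x$means)
  tab[seq_len(k), 2] <- as.character(x$n)
  for (s in seq_along(x$subsets)) {
    rows <- match(x$subsets[[s]], names(x$means))
    tab[rows, s + 2L] <- sprintf("%.4f", x$means[rows])
    tab[k + 1L, s + 2L] <- sprintf("%.3f", x$subset_sig[s])
  }
  tab[k + 1L, 1] <- "Sig."
  colnames(tab) <- c("group", "N", paste0("subset_", seq_along(x$subsets)))
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Compare EMG features from a per-subject accuracy table
#'
#' Runs the full statistical comparison for each accuracy metric: one-way
#' ANOVA across features (grip design) or main-effects two-way ANOVA across
#' force direction and feature (3D design), followed by Tukey HSD
#' homogeneous subsets of the feature means (using the ANOVA's error term)
#' whenever the feature effect is significant at `alpha`.
#'
#' @param table Data.frame with columns `subject`, `feature`, the metric
#'   columns `mave`, `rms`, `rho`, and (for the two-way design) `direction`.
#' @param design `"oneway"` or `"twoway"`; inferred from the presence of a
#'   `direction` column when `NULL`.
#' @param alpha Significance level (default 0.05).
#' @return Named list (one entry per metric), each holding `anova`
#'   (an `anova_table`) and `tukey` (a `tukey_result`, or `NULL` when the
#'   feature effect is not significant).
#' @export
compare_features <- function(table, design = NULL, alpha = 0.05) {
  metrics <- intersect(c("mave", "rms", "rho"), names(table))
  if (length(metrics) == 0L) {
    stop("`table` must contain at least one of columns mave, rms, rho",
         call. = FALSE)
  }
  if (!"feature" %in% names(table)) {
    stop("`table` must contain a `feature` column", call. = FALSE)
  }
  if (is.null(design)) {
    design <- if ("direction" %in% names(table)) "twoway" else "oneway"
  }
  design <- match.arg(design, c("oneway", "twoway"))
  feature <- factor(table$feature, levels = unique(table$feature))
  out <- lapply(metrics, function(m) {
    v <- table[[m]]
    if (design == "oneway") {
      a <- oneway_anova(split(v, feature))
      p_feat <- a$p[1]
    } else {
      if (!"direction" %in% names(table)) {
        stop("two-way design requires a `direction` column", call. = FALSE)
      }
      a <- twoway_anova_main(v, table$direction, feature)
      p_feat <- a$p[a$source == "EMG feature"]
    }
    tk <- if (is.finite(p_feat) && p_feat < alpha) {
      tukey_hsd(split(v, feature), alpha = alpha,
                mse = attr(a, "mse"), df_error = attr(a, "df_error"))
    }
    list(anova = a, tukey = tk)
  })
  names(out) <- metrics
  out
}

#' Benchmark per-subject estimation accuracy tables
#'
#' Published per-subject accuracy results from a six-subject study of
#' GRNN-based force estimation, shipped with the package as delimited text:
#' for each subject and each time-domain feature, the 2-fold cross-validated
#' MAVE (N), RMS error (N) and correlation (percent) of the estimated
#' force — per grip session (`"grip"`, 24 rows) or per force direction
#' (`"force3d"`, 72 rows). These tables drive the feature-comparison
#' statistics and serve as worked-example input for [compare_features()].
#'
#' @param task `"grip"` or `"force3d"`.
#' @return Data.frame with columns `subject`, `feature`, (`direction`,)
#'   `mave`, `rms`, `rho`.
#' @export
reference_accuracy <- function(task = c("grip", "force3d")) {
  task <- match.arg(task)
  path <- system.file("extdata",
                      paste0(task, "_accuracy.csv"), package = "semgforce",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$feature <- factor(df$feature, levels = c("MAV", "VAR", "ZC", "WA"))
  df
}
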