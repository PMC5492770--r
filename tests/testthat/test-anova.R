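# Explicit sums-of-squares oracles, independent of the model-fitting route
# used inside the package.
oneway_ss_oracle <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  between <- sum(lengths(groups) *
                   (vapply(groups, mean, numeric(1)) - grand)^2)
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(between = between, within = within, total = sum((all - grand)^2))
}

test_that("one-way ANOVA matches the explicit sums-of-squares oracle", {
  set.seed(40)
  for (rep in 1:4) {
    groups <- lapply(1:4, function(i) rnorm(6, mean = i / 2))
    names(groups) <- paste0("g", 1:4)
    a <- oneway_anova(groups)
    o <- oneway_ss_oracle(groups)
    expect_equal(a$sum_sq, c(o$between, o$within, o$total), tolerance = 1e-9)
    expect_equal(a$df, c(3, 20, 23))
    expect_equal(a$F[1], (o$between / 3) / (o$within / 20), tolerance = 1e-9)
    expect_equal(a$p[1], pf(a$F[1], 3, 20, lower.tail = FALSE))
    # SS additivity
    expect_equal(a$sum_sq[1] + a$sum_sq[2], a$sum_sq[3], tolerance = 1e-9)
  }
})

test_that("identical groups give F = 0; two groups give F = t^2", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(oneway_anova(g)$F[1], 0)
  set.seed(41)
  x <- rnorm(8); y <- rnorm(8, mean = 1)
  a <- oneway_anova(list(x = x, y = y))
  t2 <- t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(a$F[1], as.numeric(t2), tolerance = 1e-10)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(oneway_anova(list(a = c(1, 2))), "two groups")
})

test_that("ANOVA tables are invariant to jointly permuting labels and values", {
  set.seed(42)
  groups <- lapply(1:3, function(i) rnorm(5, i))
  names(groups) <- c("a", "b", "c")
  a1 <- oneway_anova(groups)
  a2 <- oneway_anova(rev(groups))
  expect_equal(a1$sum_sq, a2$sum_sq, tolerance = 1e-12)
  expect_equal(a1$F, a2$F, tolerance = 1e-12)
})

test_that("main-effects two-way ANOVA matches the balanced closed form", {
  set.seed(43)
  for (rep in 1:3) {
    A <- factor(rep(c("x", "y", "z"), each = 8))
    B <- factor(rep(rep(c("p", "q", "r", "s"), each = 2), times = 3))
    v <- rnorm(24) + as.integer(B) / 3
    tab <- twoway_anova_main(v, A, B)
    grand <- mean(v)
    ss_a <- 8 * sum((tapply(v, A, mean) - grand)^2)
    ss_b <- 6 * sum((tapply(v, B, mean) - grand)^2)
    ss_tot <- sum((v - grand)^2)
    ss_err <- ss_tot - ss_a - ss_b
    expect_equal(tab$sum_sq[tab$source == "Force direction"], ss_a,
                 tolerance = 1e-9)
    expect_equal(tab$sum_sq[tab$source == "EMG feature"], ss_b,
                 tolerance = 1e-9)
    expect_equal(tab$sum_sq[tab$source == "Error"], ss_err, tolerance = 1e-9)
    expect_equal(tab$sum_sq[tab$source == "Corrected total"], ss_tot,
                 tolerance = 1e-9)
    expect_equal(tab$df, c(5, 1, 2, 3, 18, 24, 23))
    # intercept row: N * grand_mean^2 tested against the error term
    expect_equal(tab$sum_sq[tab$source == "Intercept"], 24 * grand^2,
                 tolerance = 1e-9)
  }
})

test_that("two-way ANOVA degenerates to one-way when one factor is constant", {
  set.seed(44)
  B <- factor(rep(c("p", "q", "r"), each = 6))
  v <- rnorm(18) + as.integer(B)
  tw <- twoway_anova_main(v, factor(rep("only", 18)), B)
  ow <- oneway_anova(split(v, B))
  expect_equal(tw$sum_sq[tw$source == "EMG feature"], ow$sum_sq[1],
               tolerance = 1e-10)
  # the vanished factor contributes zero SS, so F agrees despite its df
  expect_equal(tw$sum_sq[tw$source == "Force direction"], 0, tolerance = 1e-10)
})

test_that("constant responses yield zero effect SS; unbalanced layouts are rejected", {
  A <- factor(rep(c("x", "y"), each = 4))
  B <- factor(rep(c("p", "q"), times = 4))
  # base R warns that F-tests on a perfect fit are unreliable; only the
  # sums of squares matter here
  tab <- suppressWarnings(twoway_anova_main(rep(2, 8), A, B))
  expect_equal(tab$sum_sq[3:5], rep(0, 3), tolerance = 1e-12)
  expect_error(twoway_anova_main(rnorm(7), factor(c(1, 1, 1, 2, 2, 2, 2)),
                                 factor(c(1, 2, 1, 2, 1, 2, 1))),
               "unbalanced|equal length")
})

test_that("pairwise Tukey p-values agree with stats::TukeyHSD", {
  set.seed(45)
  for (rep in 1:3) {
    groups <- lapply(1:4, function(i) rnorm(6, i / 3))
    names(groups) <- c("a", "b", "c", "d")
    tk <- tukey_hsd(groups)
    value <- unlist(groups)
    g <- factor(rep(names(groups), each = 6))
    ref <- TukeyHSD(aov(value ~ g))$g
    for (r in seq_len(nrow(tk$pairwise))) {
      pair <- sort(c(tk$pairwise$group1[r], tk$pairwise$group2[r]))
      ref_row <- ref[paste(pair[2], pair[1], sep = "-"), ]
      expect_equal(tk$pairwise$p_adj[r], unname(ref_row["p adj"]),
                   tolerance = 1e-8)
      expect_equal(abs(tk$pairwise$diff[r]), abs(unname(ref_row["diff"])),
                   tolerance = 1e-10)
    }
  }
})

test_that("homogeneous subsets cover all groups and respect pairwise decisions", {
  set.seed(46)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(8, sample(1:3, 1) / 2))
    names(groups) <- letters[seq_len(k)]
    tk <- tukey_hsd(groups)
    expect_setequal(unlist(tk$subsets), names(groups))
    for (s in seq_along(tk$subsets)) {
      members <- tk$subsets[[s]]
      # within a subset every pairwise comparison is non-significant
      if (length(members) > 1) {
        sub <- tk$pairwise[tk$pairwise$group1 %in% members &
                             tk$pairwise$group2 %in% members, ]
        expect_true(all(sub$p_adj > tk$alpha))
      }
    }
  }
})

test_that("identical groups collapse to a single subset", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  tk <- tukey_hsd(g)
  expect_length(tk$subsets, 1)
  expect_setequal(tk$subsets[[1]], c("a", "b", "c"))
  expect_error(tukey_hsd(list(a = 1:3, b = 1:4)), "equal group sizes")
})

test_that("compare_features wires metrics through the right design", {
  tab <- reference_accuracy("grip")
  res <- compare_features(tab)
  expect_named(res, c("mave", "rms", "rho"))
  expect_equal(attr(res$mave$anova, "design"), "oneway")
  expect_false(is.null(res$mave$tukey))
  tab3 <- reference_accuracy("force3d")
  res3 <- compare_features(tab3)
  expect_equal(attr(res3$rms$anova, "design"), "twoway_main_effects")
  # Tukey error term comes from the two-way ANOVA
  expect_equal(res3$rms$tukey$df_error, 66)
})
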