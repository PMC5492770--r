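test_that("scalar window features match their closed forms", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(0, 200)), 0)
  expect_equal(var_feature(c(1, -1, 1, -1)), 1)
  # mean-square semantics: a constant window scores c^2, not 0
  expect_equal(var_feature(rep(2.5, 10)), 6.25)
  # same-sign-pair convention: alternating signs -> all products negative -> 0
  expect_equal(zc(c(1, -1, 1, -1), "as_printed"), 0)
  expect_equal(zc(c(2, 3, 4, 5), "as_printed"), 3)
  expect_equal(zc(c(1, -1, 1, -1), "sign_change"), 3)
  expect_equal(wa(c(0, 1, 1.2, 0), 0.5), 2)
  expect_equal(wa(rnorm(50), Inf), 0)
  # strict inequality: zero differences never exceed a zero threshold
  expect_equal(wa(rep(0, 10), 0), 0)
})

test_that("scalar features reject degenerate input", {
  expect_error(mav(numeric(0)), "at least 1")
  expect_error(var_feature(numeric(0)), "at least 1")
  expect_error(zc(1), "at least 2")
  expect_error(wa(c(1, 2), -0.1), ">= 0")
})

test_that("features equal brute-force summation oracles on random windows", {
  set.seed(7)
  for (rep in 1:5) {
    w <- rnorm(200)
    n <- length(w)
    expect_equal(mav(w), sum(abs(w)) / n, tolerance = 1e-12)
    expect_equal(var_feature(w), sum(w^2) / n, tolerance = 1e-12)
    zc_oracle <- 0L
    for (j in 2:n) zc_oracle <- zc_oracle + as.integer(w[j] * w[j - 1] > 0)
    expect_identical(zc(w, "as_printed"), zc_oracle)
    thr <- 0.8
    wa_oracle <- 0L
    for (j in 2:n) wa_oracle <- wa_oracle + as.integer(abs(w[j] - w[j - 1]) > thr)
    expect_identical(wa(w, thr), wa_oracle)
  }
})

test_that("features obey scale equivariance", {
  set.seed(11)
  x <- rnorm(100)
  for (a in c(0.5, 3, -2)) {
    expect_equal(mav(a * x), abs(a) * mav(x))
    expect_equal(var_feature(a * x), a^2 * var_feature(x))
  }
  expect_identical(zc(4 * x), zc(x))
  expect_identical(zc(4 * x, "sign_change"), zc(x, "sign_change"))
})

test_that("sliding extraction has the right window count and per-window values", {
  set.seed(3)
  rec <- emg_recording(matrix(rnorm(2 * 1000), 2, 1000), fs = 1000,
                       channel_sites = c("a", "b"))
  cfg <- feature_config(window_len = 200, step = 50, feature = "MAV",
                        remove_offset = FALSE)
  fm <- sliding_features(rec, cfg)
  expect_equal(ncol(fm$values), floor((1000 - 200) / 50) + 1)  # 17
  expect_equal(fm$window_ends[1], 200)
  # each window equals the scalar op applied to that slice
  for (w in c(1, 5, 17)) {
    idx <- (fm$window_ends[w] - 199):fm$window_ends[w]
    expect_equal(fm$values[2, w], mav(rec$samples[2, idx]), tolerance = 1e-12)
  }
  expect_error(sliding_features(
    emg_recording(matrix(rnorm(100), 1, 100), fs = 1000, "a"), cfg),
    "shorter than")
})

test_that("offset removal makes features blind to the DC level shift", {
  rec <- emg_recording(matrix(1.5, 1, 600), fs = 1000, "a")
  fm <- sliding_features(rec, feature_config(feature = "MAV",
                                             remove_offset = TRUE))
  expect_true(all(fm$values == 0))
  fm_raw <- sliding_features(rec, feature_config(feature = "MAV",
                                                 remove_offset = FALSE))
  expect_true(all(fm_raw$values == 1.5))
})

test_that("sliding extraction matches per-window scalar oracles for all features", {
  set.seed(9)
  rec <- emg_recording(matrix(rnorm(800, sd = 0.1) + 1.5, 1, 800), fs = 1000,
                       "a")
  for (feat in c("MAV", "VAR", "ZC", "WA")) {
    cfg <- feature_config(window_len = 100, step = 40, feature = feat,
                          wa_threshold = 0.05, remove_offset = TRUE)
    fm <- sliding_features(rec, cfg)
    fun <- switch(feat, MAV = mav, VAR = var_feature,
                  ZC = function(w) zc(w, "as_printed"),
                  WA = function(w) wa(w, 0.05))
    for (w in seq_along(fm$window_ends)) {
      win <- rec$samples[1, (fm$window_ends[w] - 99):fm$window_ends[w]]
      expect_equal(fm$values[1, w], fun(win - mean(win)), tolerance = 1e-12)
    }
  }
})

test_that("adaptive Willison threshold resolves from the rest segment", {
  set.seed(13)
  x <- c(rnorm(500, sd = 0.01), rnorm(500, sd = 0.3)) + 1.5
  rec <- emg_recording(matrix(x, 1, 1000), fs = 1000, "a")
  fm <- sliding_features(rec, feature_config(feature = "WA"))
  thr <- fm$config$resolved_wa_threshold
  expect_equal(thr, 3 * median(abs(diff(x[1:500]))))
  # rest windows count few suprathreshold steps, active windows nearly all
  expect_lt(fm$values[1, 1], 30)
  expect_gt(fm$values[1, ncol(fm$values)], 120)
})

test_that("training assembly aligns targets to window ends", {
  s <- tiny_grip_session(seed = 5)
  fm <- sliding_features(s$emg)
  ts <- assemble_training(fm, s$force)
  expect_equal(nrow(ts$x), ncol(fm$values))
  expect_equal(ncol(ts$y), 1)
  expect_true(all(ts$y >= 0))
  expect_equal(ts$y[, 1], s$force$values[1, fm$window_ends])
  # 3D sessions carry three signed target rows
  s3 <- simulate_session(sim_config("force3d", seed = 5), 4)
  ts3 <- assemble_training(sliding_features(s3$emg), s3$force)
  expect_equal(colnames(ts3$y), c("x", "y", "z"))
  expect_equal(ncol(ts3$y), 3)
  # force shorter than the feature span is rejected
  short <- force_recording(s$force$values[, 1:100, drop = FALSE],
                           "grip", fs = s$force$fs)
  expect_error(assemble_training(fm, short), "window ends reach")
  # clock mismatch is rejected
  wrong_fs <- force_recording(s$force$values, "grip", fs = 500)
  expect_error(assemble_training(fm, wrong_fs), "sampling rates")
})
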