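test_that("J1 is the three-axis RMS of the differenced sample", {
  expect_identical(j1_feature(c(0, 0, 0)), 0)
  expect_equal(j1_feature(c(3, 4, 0)), sqrt(25 / 3))
  # homogeneity
  set.seed(1)
  d <- matrix(rnorm(60), 20, 3)
  expect_equal(j1_feature(2 * d), 2 * j1_feature(d))
})

test_that("J2 is the across-axis RMS of windowed population deviations", {
  # constant window -> 0
  expect_equal(j2_feature(matrix(5, 30, 3))[30], 0)
  # constructed window with population sd exactly 1 per axis -> 1
  v <- rep(c(-1, 1), length.out = 26)[1:25]  # 13 of one sign, 12 of the other
  v <- scale(v, center = TRUE, scale = FALSE)[, 1]
  v <- v / sqrt(mean(v^2))                    # population sd exactly 1
  states <- cbind(v, v, v)
  expect_equal(j2_feature(states, 25)[25], 1, tolerance = 1e-12)
  # stats::sd as the independent oracle (sample -> population correction)
  set.seed(2)
  s <- matrix(rnorm(75, 0, 10), 25, 3)
  ref <- sqrt(mean(vapply(1:3, function(a) {
    stats::sd(s[, a])^2 * 24 / 25
  }, numeric(1))))
  expect_equal(j2_feature(s, 25)[25], ref)
  # translation invariance per axis
  s2 <- s
  s2[, 2] <- s2[, 2] + 1000
  expect_equal(j2_feature(s2, 25)[25], j2_feature(s, 25)[25])
})

test_that("J3 multiplies the windowed maxima with J2 squared", {
  j1 <- c(rep(0, 24), 2)
  j2 <- c(rep(1, 24), 3)
  expect_equal(j3_feature(j1, j2, 25)[25], 2 * 9)
  # zero J1 window forces J3 to zero
  expect_equal(j3_feature(rep(0, 30), runif(30), 25), rep(0, 30))
  # monotone in each window maximum
  j1b <- j1; j1b[25] <- 5
  expect_gte(j3_feature(j1b, j2, 25)[25], j3_feature(j1, j2, 25)[25])
})

test_that("features are jointly homogeneous: input x a scales J3 by a^3", {
  set.seed(3)
  base <- matrix(rnorm(200 * 3, 0, 40), 200, 3)
  a <- 2.5
  d1 <- differentiate(base); d2 <- differentiate(a * base)
  j1a <- j1_feature(d1); j1b <- j1_feature(d2)
  expect_equal(j1b, a * j1a)
  # J2 scales linearly because the smoother is linear in its measurements
  # for fixed gains; verify through the full linear chain
  cfg <- kalman_config(init = "zero")
  ka <- run_kalman(base, cfg); kb <- run_kalman(a * base, cfg)
  j2a <- j2_feature(ka$states); j2b <- j2_feature(kb$states)
  expect_equal(j2b, a * j2a, tolerance = 1e-9)
  expect_equal(j3_feature(j1b, j2b), a^3 * j3_feature(j1a, j2a),
               tolerance = 1e-9)
})

test_that("streaming detector trace equals the batch feature computation", {
  rec <- gen_recording(synth_spec("jog_trip_fall", seed = 6))
  batch <- compute_features(rec)
  out <- run_file(rec, detector_config(threshold = 1e12))  # no events
  expect_equal(out$trace$j3, batch$j3)
  expect_equal(out$trace$x4, batch$x4)
  expect_equal(out$trace$j1, batch$j1)
  expect_equal(out$trace$j2, batch$j2)
})

test_that("the feature report separates disjoint classes and flags ties", {
  df <- data.frame(activity = rep(c("D01", "F01"), each = 5),
                   is_fall = rep(c(FALSE, TRUE), each = 5),
                   f = c(1:5, 11:15))
  rep1 <- feature_report(df, "f")
  expect_equal(rep1$thresholds$balanced_accuracy, 1.0)
  expect_gt(rep1$thresholds$threshold, 5)
  expect_lte(rep1$thresholds$threshold, 11)
  # identical distributions cannot beat chance
  df2 <- data.frame(activity = rep(c("D01", "F01"), each = 5),
                    is_fall = rep(c(FALSE, TRUE), each = 5),
                    f = rep(1:5, 2))
  expect_equal(feature_report(df2, "f")$thresholds$balanced_accuracy, 0.5)
  expect_error(feature_report(df[df$activity == "D01", ], "f"), "activities")
})

test_that("composing complementary weak features separates all files", {
  # feature A fails on periodic files, feature B fails on transition files
  per <- data.frame(activity = "D03", is_fall = FALSE, A = c(90, 95, 100), B = c(2, 2.5, 3))
  tra <- data.frame(activity = "D07", is_fall = FALSE, A = c(4, 5, 6), B = c(36, 38, 40))
  fal <- data.frame(activity = "F01", is_fall = TRUE, A = c(80, 90, 110), B = c(35, 40, 45))
  df <- rbind(per, tra, fal)
  # each alone fails
  expect_lt(feature_report(df, "A")$thresholds$balanced_accuracy, 1)
  expect_lt(feature_report(df, "B")$thresholds$balanced_accuracy, 1)
  # the product with the stronger feature squared separates
  df$AB2 <- compose_product(df$A, df$B)
  expect_equal(feature_report(df, "AB2")$thresholds$balanced_accuracy, 1)
  expect_gt(min(df$AB2[df$is_fall]), max(df$AB2[!df$is_fall]))
})
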