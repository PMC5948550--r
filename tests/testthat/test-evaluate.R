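test_that("stratified folds balance sizes and class proportions", {
  labels <- rep(c(TRUE, FALSE), c(1800, 2710))  # 4510 files, fall share 0.399
  fold <- stratified_folds(labels, k = 10, seed = 1)
  sizes <- table(fold)
  expect_true(all(sizes == 451L))
  per_fold_falls <- tapply(labels, fold, sum)
  expect_lte(diff(range(per_fold_falls)), 1)
  # small balanced case: two folds of 10 with 5 falls each
  lab2 <- rep(c(TRUE, FALSE), each = 10)
  f2 <- stratified_folds(lab2, k = 2, seed = 3)
  expect_equal(unname(table(f2)), c(10L, 10L), ignore_attr = TRUE)
  expect_true(all(tapply(lab2, f2, sum) == 5))
  # determinism
  expect_identical(stratified_folds(labels, 10, seed = 7),
                   stratified_folds(labels, 10, seed = 7))
  expect_error(stratified_folds(c(TRUE, rep(FALSE, 20)), k = 2), "at least k")
})

test_that("threshold training maximizes balanced accuracy, preferring lower values", {
  fit <- train_threshold(c(10, 12, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fit$threshold, 6)
  expect_equal(fit$balanced_accuracy, 1)
  # tie handling returns the smallest maximizing candidate
  sc <- c(10, 12, 1, 2, 11)
  lb <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  fit2 <- train_threshold(sc, lb)
  ref <- oracle_best_balanced_accuracy(sc, lb)
  expect_equal(fit2$balanced_accuracy, ref)
  expect_equal(fit2$threshold, 6)  # unique best here (SEN 1, SPE 2/3)
  # perfectly interleaved scores stay at chance with the low sentinel
  sc3 <- 1:10
  lb3 <- rep(c(TRUE, FALSE), 5)
  fit3 <- train_threshold(sc3, lb3)
  expect_equal(fit3$balanced_accuracy, 0.5)
  expect_lt(fit3$threshold, 1)
  expect_error(train_threshold(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trained thresholds are optimal against a brute-force grid", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::rlnorm(n, 8, 2))
    fit <- train_threshold(scores, labels)
    ref <- oracle_best_balanced_accuracy(scores, labels)
    expect_equal(fit$balanced_accuracy, ref, tolerance = 1e-12)
  }
})

test_that("sensitivity, specificity and balanced accuracy follow the ratios", {
  m <- cm_metrics(confusion_matrix(tp = 1, fn = 1, tn = 3, fp = 1))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$balanced_accuracy, 0.625)
  perfect <- cm_metrics(confusion_matrix(tp = 5, fn = 0, tn = 7, fp = 0))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_error(cm_metrics(confusion_matrix(tp = 0, fn = 0, tn = 3, fp = 1)),
               "SEN undefined")
})

test_that("the reference fold-mean matrix reproduces the published arithmetic", {
  cm <- sisfall_reference_cm()
  m <- cm_metrics(cm)
  expect_equal(round(100 * m$sensitivity, 2), 99.28)
  kr <- kappa_report(cm)
  expect_equal(round(kr$observed_accuracy, 4), 0.9945)
  expect_equal(round(kr$expected_standard, 4), 0.5204)
  expect_equal(round(kr$expected_prevalence, 4), 0.3991)
  expect_equal(round(kr$kappa_prevalence, 4), 0.9908)
})

test_that("kappa agrees with an independent contingency-table oracle", {
  skip_if_not_installed("e1071")
  set.seed(15)
  for (rep in 1:1000) {
    v <- sample(0:40, 4, replace = TRUE) + c(1, 0, 1, 0)  # nonempty classes
    cm <- confusion_matrix(tp = v[1], fn = v[2], tn = v[3], fp = v[4])
    tab <- matrix(c(cm$tn, cm$fp, cm$fn, cm$tp), 2, 2)
    ref <- e1071::classAgreement(tab)
    kr <- kappa_report(cm)
    expect_equal(kr$observed_accuracy, ref$diag, tolerance = 1e-12)
    expect_equal(kr$kappa_standard, ref$kappa, tolerance = 1e-12)
  }
  # perfect diagonal -> kappa 1; degenerate chance -> error
  expect_equal(kappa_report(confusion_matrix(5, 0, 9, 0))$kappa_standard, 1)
  expect_error(kappa_report(confusion_matrix(0, 0, 4, 0)), "undefined")
})

test_that("cross-validation separates the default synthetic corpus perfectly", {
  corp <- fixture_default_corpus()
  cv <- cross_validate(corp, k = 10, seed = 11,
                       scores = fixture_default_scores())
  expect_true(all(cv$per_fold$balanced_accuracy == 1))
  expect_lt(cv$summary["threshold", "sd"] / cv$summary["threshold", "mean"],
            0.05)
  expect_equal(cv$kappa$kappa_standard, 1)
  expect_error(cross_validate(list(
    recordings = corp$recordings[1:3],
    manifest = corp$manifest[1:3, ]), k = 2, seed = 1), "both classes")
})

test_that("cross-validation is invariant to corpus file order", {
  corp <- fixture_default_corpus()
  sc <- fixture_default_scores()
  cv1 <- cross_validate(corp, k = 5, seed = 2, scores = sc)
  set.seed(77)
  perm <- sample(seq_along(sc))
  corp2 <- list(recordings = corp$recordings[perm],
                manifest = corp$manifest[perm, ])
  cv2 <- cross_validate(corp2, k = 5, seed = 2, scores = sc[perm])
  expect_equal(cv1$per_fold, cv2$per_fold)
})

test_that("the veto improves specificity on the hard corpus", {
  hard <- fixture_hard_corpus()
  cv_on <- cross_validate(hard, k = 7, seed = 11,
                          config = detector_config(veto = TRUE),
                          scores = fixture_hard_scores(TRUE))
  cv_off <- cross_validate(hard, k = 7, seed = 11,
                           config = detector_config(veto = FALSE),
                           scores = fixture_hard_scores(FALSE))
  expect_gte(cv_on$fold_mean_metrics$specificity,
             cv_off$fold_mean_metrics$specificity)
  expect_gt(cv_on$fold_mean_metrics$specificity, 0.95)
})
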