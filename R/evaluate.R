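#' Confusion matrix for fall/ADL classification
#'
#' Counts may be fractional: the cross-validation harness reports the mean of
#' per-fold matrices. TP = falls detected, FN = falls missed, TN = ADLs
#' passed, FP = false alarms.
#'
#' @param tp,fn,tn,fp non-negative counts (or fold means).
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0)) stop("confusion matrix entries must be non-negative")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2L, 2L,
              dimnames = list(predicted = c("ADL", "FALL"),
                              truth = c("ADL", "FALL")))
  print(m)
  invisible(x)
}

#' Reference mean confusion matrix (SisFall, 10-fold, veto enabled)
#'
#' The published 10-fold cross-validation mean confusion matrix for this
#' detector on the SisFall dataset (451 validation files per fold, J3 with
#' the periodicity veto): fold-mean counts 178.7 true positives, 1.3 false
#' negatives, 269.8 true negatives, 1.2 false positives. Used as a worked
#' example for the metric and kappa arithmetic.
#'
#' @return a [confusion_matrix()] with attributes `sd` (per-cell fold
#'   standard deviations), `n_folds` and `files_per_fold`.
#' @export
sisfall_reference_cm <- function() {
  cm <- confusion_matrix(tp = 178.7, fn = 1.3, tn = 269.8, fp = 1.2)
  attr(cm, "sd") <- c(tp = 9.68, fn = 1.25, tn = 9.56, fp = 0.92)
  attr(cm, "n_folds") <- 10L
  attr(cm, "files_per_fold") <- 451L
  cm
}

#' Sensitivity, specificity and balanced accuracy
#'
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `ACC = (SEN+SPE)/2`. The balanced
#' form is used because ADL files far outnumber fall files.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
cm_metrics <- function(cm) {
  if (cm$tp + cm$fn <= 0) stop("no positive (fall) examples: SEN undefined")
  if (cm$tn + cm$fp <= 0) stop("no negative (ADL) examples: SPE undefined")
  sen <- cm$tp / (cm$tp + cm$fn)
  spe <- cm$tn / (cm$tn + cm$fp)
  list(sensitivity = sen, specificity = spe,
       balanced_accuracy = (sen + spe) / 2)
}

#' Observed accuracy, chance agreement and Cohen's kappa
#'
#' Reports the observed accuracy `(TP+TN)/total`, the standard chance
#' agreement `Pe = sum(row marginal x column marginal) / total^2` with the
#' corresponding Cohen kappa `(Po - Pe)/(1 - Pe)`, and two variants: a
#' prevalence-based kappa whose chance term is the fall-class ground-truth
#' proportion `(TP+FN)/total`, and, when `expected_accuracy` is supplied, a
#' kappa computed against that externally stated chance term.
#'
#' @param cm a [confusion_matrix()].
#' @param expected_accuracy optional externally supplied chance agreement.
#' @return list with `observed_accuracy`, `expected_standard`,
#'   `kappa_standard`, `expected_prevalence`, `kappa_prevalence`, and (when
#'   supplied) `expected_supplied`, `kappa_supplied`.
#' @export
kappa_report <- function(cm, expected_accuracy = NULL) {
  total <- cm$tp + cm$fn + cm$tn + cm$fp
  if (total <= 0) stop("empty confusion matrix")
  po <- (cm$tp + cm$tn) / total
  row_fall <- cm$tp + cm$fp   # predicted FALL
  row_adl <- cm$tn + cm$fn
  col_fall <- cm$tp + cm$fn   # ground-truth FALL
  col_adl <- cm$tn + cm$fp
  pe <- (row_fall * col_fall + row_adl * col_adl) / total^2
  kap <- function(pe) {
    if (pe >= 1) stop("chance agreement of 1: kappa undefined")
    (po - pe) / (1 - pe)
  }
  out <- list(observed_accuracy = po,
              expected_standard = pe, kappa_standard = kap(pe),
              expected_prevalence = col_fall / total,
              kappa_prevalence = kap(col_fall / total))
  if (!is.null(expected_accuracy)) {
    out$expected_supplied <- expected_accuracy
    out$kappa_supplied <- kap(expected_accuracy)
  }
  out
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified fold assignment
#'
#' Shuffles within each class (seeded) and deals indices round-robin across
#' folds, continuing the deal from one class to the next: fold sizes differ
#' by at most one file overall and per class.
#'
#' @param labels logical vector (TRUE = fall) per file.
#' @param k number of folds (>= 2).
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @return integer vector of fold numbers in 1..k.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- as.logical(labels)
  counts <- table(factor(labels, levels = c(FALSE, TRUE)))
  if (any(counts < k)) {
    stop(sprintf("each class needs at least k = %d members (have %d / %d)",
                 k, counts[1], counts[2]))
  }
  fold <- integer(length(labels))
  pos <- 0L
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        fold[i] <- (pos %% k) + 1L
        pos <- pos + 1L
      }
    }
  })
  fold
}

#' Train the detection threshold on per-file scores
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus below-minimum and above-maximum sentinels; a file is classified
#' as a fall when `score >= t`. Among the balanced-accuracy maximizers the
#' smallest candidate is returned: the falls available for training are
#' energetic compared to real-life falls of elderly people, so when a range of
#' thresholds is equally accurate the lower one avoids false negatives.
#'
#' @param scores per-file detection scores (max J3).
#' @param labels logical fall labels.
#' @return list with `threshold` and its training `balanced_accuracy`.
#' @export
train_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes required for training")
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  npos <- sum(labels)
  nneg <- sum(!labels)
  acc <- vapply(cand, function(t) {
    pred <- scores >= t
    (sum(pred & labels) / npos + sum(!pred & !labels) / nneg) / 2
  }, numeric(1))
  best <- max(acc)
  t <- min(cand[acc >= best - 1e-12])
  list(threshold = t, balanced_accuracy = best)
}

#' Stratified k-fold cross-validation of the detector
#'
#' Reproduces the training/validation protocol: per-file scores (max J3 after
#' optional veto zeroing) are computed once, files are dealt into stratified
#' folds, and in each round a threshold is trained on the other k-1 folds and
#' evaluated on the held-out fold. Files are canonically ordered by name
#' before folding, so the result is invariant to the order the corpus was
#' assembled in.
#'
#' @param corpus list with `recordings` (list of [new_recording()] objects)
#'   and `manifest` (data frame with `file`, `activity`, `is_fall`), as
#'   produced by [gen_corpus()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param config a [detector_config()]; its `veto` flag selects the scoring
#'   mode.
#' @param scores optional precomputed per-file scores (same order as the
#'   manifest), to compare veto settings without re-running the pipeline.
#' @return object of class `fall_cv`: per-fold table, mean +/- sd summaries,
#'   mean confusion matrix, pooled metrics, and a [kappa_report()] of the
#'   mean matrix.
#' @export
cross_validate <- function(corpus, k = 10L, seed = 1L,
                           config = detector_config(), scores = NULL) {
  man <- corpus$manifest
  labels <- as.logical(man$is_fall)
  if (!any(labels) || all(labels)) stop("corpus must contain both classes")
  if (is.null(scores)) {
    scores <- vapply(corpus$recordings, score_recording, numeric(1),
                     config = config)
  }
  ord <- order(man$file)
  scores <- scores[ord]
  labels <- labels[ord]
  fold <- stratified_folds(labels, k = k, seed = seed)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- train_threshold(scores[tr], labels[tr])
    pred <- scores[!tr] >= fit$threshold
    truth <- labels[!tr]
    cm <- confusion_matrix(tp = sum(pred & truth), fn = sum(!pred & truth),
                           tn = sum(!pred & !truth), fp = sum(pred & !truth))
    m <- cm_metrics(cm)
    data.frame(fold = f, threshold = fit$threshold,
               tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
               sensitivity = m$sensitivity, specificity = m$specificity,
               balanced_accuracy = m$balanced_accuracy)
  }))
  mean_cm <- confusion_matrix(tp = mean(per_fold$tp), fn = mean(per_fold$fn),
                              tn = mean(per_fold$tn), fp = mean(per_fold$fp))
  pooled <- confusion_matrix(tp = sum(per_fold$tp), fn = sum(per_fold$fn),
                             tn = sum(per_fold$tn), fp = sum(per_fold$fp))
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(
    list(per_fold = per_fold,
         summary = rbind(sensitivity = msd(per_fold$sensitivity),
                         specificity = msd(per_fold$specificity),
                         balanced_accuracy = msd(per_fold$balanced_accuracy),
                         threshold = msd(per_fold$threshold)),
         mean_cm = mean_cm,
         fold_mean_metrics = list(
           sensitivity = mean(per_fold$sensitivity),
           specificity = mean(per_fold$specificity),
           balanced_accuracy = mean(per_fold$balanced_accuracy)),
         pooled_metrics = cm_metrics(pooled),
         kappa = kappa_report(mean_cm),
         k = k, seed = seed, veto = config$veto),
    class = "fall_cv"
  )
}

#' @export
print.fall_cv <- function(x, ...) {
  cat(sprintf("<fall_cv> %d-fold stratified cross-validation (veto %s)\n",
              x$k, if (x$veto) "on" else "off"))
  s <- x$summary
  for (r in rownames(s)) {
    cat(sprintf("  %-18s %10.4f +/- %.4f\n", r, s[r, "mean"], s[r, "sd"]))
  }
  cat(sprintf("  kappa (standard)   %10.4f\n", x$kappa$kappa_standard))
  invisible(x)
}
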