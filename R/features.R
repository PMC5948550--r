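#' Sum-vector-magnitude feature J1
#'
#' Root-mean-square of the differenced (bias-removed) acceleration triple:
#' `sqrt((dax^2 + day^2 + daz^2) / 3)`. Responds to impacts. The division by
#' three is the literal RMS convention; any constant factor is absorbed by the
#' trained threshold.
#'
#' @param delta differenced acceleration: a triple or a matrix (samples x 3)
#'   from [differentiate()].
#' @return non-negative scalar or vector of per-sample J1 values (bits scale).
#' @export
j1_feature <- function(delta) {
  if (is.null(dim(delta))) {
    sqrt(sum(delta^2) / 3)
  } else {
    sqrt(rowSums(delta^2) / 3)
  }
}

# population (divide-by-N) standard deviation of a time-ordered window
pop_sd <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  sqrt(max(sum((v - m)^2) / n, 0))
}

#' Standard-deviation-magnitude feature J2
#'
#' Per-axis population standard deviation of the orientation states x1..x3
#' over a sliding 1 s window, combined as an RMS across the three axes:
#' `sqrt((s1^2 + s2^2 + s3^2) / 3)`. Responds to orientation change. During
#' warm-up the window is partial; a single-sample window yields 0.
#'
#' @param states matrix (samples x >=3) of Kalman states; only the first three
#'   columns are used.
#' @param window window length in samples (25 = 1 s at 25 Hz).
#' @return vector of per-sample J2 values.
#' @export
j2_feature <- function(states, window = 25L) {
  states <- as.matrix(states)
  n <- nrow(states)
  out <- numeric(n)
  for (k in seq_len(n)) {
    idx <- max(1L, k - window + 1L):k
    if (length(idx) < 2L) { out[k] <- 0; next }
    v <- vapply(1:3, function(a) pop_sd(states[idx, a])^2, numeric(1))
    out[k] <- sqrt(sum(v) / 3)
  }
  out
}

# trailing-window maximum, partial at stream start
roll_max <- function(x, window) {
  n <- length(x)
  vapply(seq_len(n), function(k) max(x[max(1L, k - window + 1L):k]), numeric(1))
}

#' Fused non-linear feature J3
#'
#' `J3[k] = max(J1 over last N) * max(J2 over last N)^2` with N = 25 (1 s).
#' The windowed maxima align the two features (the smoother takes time to
#' peak); squaring J2 prioritizes orientation change over raw impact. J3 is
#' the single thresholded detection statistic.
#'
#' @param j1,j2 per-sample feature vectors of equal length.
#' @param window sliding-max window length in samples.
#' @return vector of per-sample J3 values.
#' @export
j3_feature <- function(j1, j2, window = 25L) {
  stopifnot(length(j1) == length(j2))
  roll_max(j1, window) * roll_max(j2, window)^2
}

#' Batch feature computation over a recording
#'
#' Convenience wrapper running the full per-sample chain (decimation,
#' low-pass, differencing, Kalman smoothing, J1/J2/J3) with the same
#' primitives as the streaming detector.
#'
#' @param recording an [new_recording()] object at any supported rate.
#' @param kalman a [kalman_config()].
#' @param fs pipeline rate in Hz.
#' @param window feature window length in samples.
#' @return data frame with columns `index`, raw bits, filtered channels,
#'   states x1..x4, `bay`, `j1`, `j2`, `j3`.
#' @export
compute_features <- function(recording, kalman = kalman_config(), fs = 25,
                             window = 25L) {
  rec <- downsample(recording, fs)
  lp <- lowpass_filter(rec$frames, lowpass_init(design_lowpass(fs = fs)))
  filtered <- lp$y
  delta <- differentiate(filtered)
  kal <- run_kalman(filtered, kalman)
  j1 <- j1_feature(delta)
  j2 <- j2_feature(kal$states, window)
  j3 <- j3_feature(j1, j2, window)
  data.frame(index = seq_len(nrow(filtered)),
             ax = rec$frames[, 1], ay = rec$frames[, 2], az = rec$frames[, 3],
             f1 = filtered[, 1], f2 = filtered[, 2], f3 = filtered[, 3],
             x1 = kal$states[, 1], x2 = kal$states[, 2],
             x3 = kal$states[, 3], x4 = kal$states[, 4],
             bay = kal$bay, j1 = j1, j2 = j2, j3 = j3)
}

#' Per-activity feature report for feature composition
#'
#' Supports the feature-composition recipe: per-activity quartiles of each
#' candidate feature's per-file maxima (box-plot summary) plus the optimal
#' single-feature threshold and its balanced accuracy, so complementary
#' features (failing on disjoint activity sets) can be picked and multiplied.
#'
#' @param df data frame of per-file feature maxima.
#' @param feature_cols names of the candidate feature columns.
#' @param activity_col name of the activity-code column.
#' @param label_col name of the logical fall-label column.
#' @return list with `quartiles` (activity x feature five-number summaries)
#'   and `thresholds` (per feature: optimal threshold, balanced accuracy).
#' @export
feature_report <- function(df, feature_cols, activity_col = "activity",
                           label_col = "is_fall") {
  acts <- unique(df[[activity_col]])
  if (length(acts) < 2L) stop("need at least 2 activities for a report")
  q <- do.call(rbind, lapply(acts, function(a) {
    sub <- df[df[[activity_col]] == a, , drop = FALSE]
    do.call(rbind, lapply(feature_cols, function(fc) {
      s <- stats::quantile(sub[[fc]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(activity = a, feature = fc, is_fall = sub[[label_col]][1],
                 min = s[1], q1 = s[2], median = s[3], q3 = s[4], max = s[5])
    }))
  }))
  th <- do.call(rbind, lapply(feature_cols, function(fc) {
    t <- train_threshold(df[[fc]], df[[label_col]])
    data.frame(feature = fc, threshold = t$threshold,
               balanced_accuracy = t$balanced_accuracy)
  }))
  list(quartiles = q, thresholds = th)
}

#' Non-linear product composition of two features
#'
#' `a * b^2`: the square prioritizes the stronger feature. Large values on
#' both candidates stay large (falls); mixed values shrink (ADLs).
#'
#' @param a,b numeric vectors of per-file feature values.
#' @return the composed feature vector.
#' @export
compose_product <- function(a, b) a * b^2
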