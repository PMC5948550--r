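#' Default process / measurement noise covariances
#'
#' Diagonal covariances expressed as squared standard deviations: process
#' noise std 0.001 on all four states, measurement noise std 0.05 on the
#' three acceleration channels and 0.01 on the de-biased vertical channel.
#' Only the ratios matter for the steady-state gains; these values flatten
#' states x1..x3 into orientation estimates while leaving enough bandwidth in
#' x4 to follow gait-band oscillation.
#'
#' @return list with 4x4 matrices `Q` and `R`.
#' @export
default_noise <- function() {
  list(Q = diag(rep(0.001^2, 4L)),
       R = diag(c(0.05^2, 0.05^2, 0.05^2, 0.01^2)))
}

#' Kalman smoother configuration
#'
#' The state-space model is autonomous with identity transition and output
#' matrices: the filter is used purely as a smoother. States x1..x3 track the
#' three filtered acceleration channels (orientation); the fourth state tracks
#' the vertical channel minus its running bias, yielding a zero-bias
#' quasi-sinusoid during periodic activities.
#'
#' @param q_std process-noise standard deviation (scalar, all states).
#' @param r_std_xyz measurement-noise std of the three acceleration channels.
#' @param r_std_x4 measurement-noise std of the de-biased vertical channel.
#' @param bias_window vertical-bias window length in samples (25 = 1 s at
#'   25 Hz).
#' @param init `"rest"` starts the vertical state and bias at `rest_bits`
#'   (upright rest, -1 G); `"zero"` uses uninformative zeros.
#' @param rest_bits resting vertical acceleration in ADC bits (-256 = -1 G).
#' @param Q,R optional explicit 4x4 covariances overriding the stds.
#' @return object of class `kalman_config`.
#' @export
kalman_config <- function(q_std = 0.001, r_std_xyz = 0.05, r_std_x4 = 0.01,
                          bias_window = 25L, init = c("rest", "zero"),
                          rest_bits = -256, Q = NULL, R = NULL) {
  init <- match.arg(init)
  if (is.null(Q)) Q <- diag(rep(q_std^2, 4L))
  if (is.null(R)) R <- diag(c(rep(r_std_xyz^2, 3L), r_std_x4^2))
  check_psd <- function(M, name) {
    if (!isTRUE(all.equal(M, t(M)))) stop(name, " must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12) stop(name, " must be positive semi-definite")
  }
  check_psd(Q, "Q"); check_psd(R, "R")
  structure(
    list(A = diag(4L), C = diag(4L), Q = Q, R = R,
         bias_window = as.integer(bias_window), init = init,
         rest_bits = rest_bits),
    class = "kalman_config"
  )
}

#' Initialize the Kalman state and vertical-bias tracker
#'
#' With `init = "rest"` the vertical state x2 and the bias start at -1 G
#' (-256 bits) for fast convergence from upright rest; `init = "zero"` uses
#' the uninformative prior (zero state). In both cases `P[0] = Q`.
#'
#' @param config a [kalman_config()].
#' @return list with `x` (4-vector), `P` (4x4), `bay` (current vertical bias),
#'   and `x2_buf` (the bias window buffer, oldest first).
#' @export
kalman_init <- function(config = kalman_config()) {
  x0 <- c(0, if (config$init == "rest") config$rest_bits else 0, 0, 0)
  list(x = x0, P = config$Q,
       bay = if (config$init == "rest") config$rest_bits else 0,
       x2_buf = numeric(0))
}

#' One predict/correct step of the 4-state smoother
#'
#' Standard Kalman recursion with the full 4-vector measurement already
#' assembled: predict `x- = A x`, `P- = A P A' + Q`; gain
#' `G = P- C' (C P- C' + R)^-1`; correct `x = x- + G (y - C x-)`,
#' `P = (I - G C) P-`, re-symmetrized as `(P + P') / 2`.
#'
#' @param state list with `x` and `P` (other elements are passed through).
#' @param y measurement 4-vector `(ax, ay, az, ay - bay)`.
#' @param config a [kalman_config()].
#' @return the updated state.
#' @export
kalman_step <- function(state, y, config = kalman_config()) {
  A <- config$A; C <- config$C
  x_pred <- A %*% state$x
  P_pred <- A %*% state$P %*% t(A) + config$Q
  S <- C %*% P_pred %*% t(C) + config$R
  G <- P_pred %*% t(C) %*% solve(S)
  x_new <- x_pred + G %*% (y - C %*% x_pred)
  P_new <- (diag(4L) - G %*% C) %*% P_pred
  P_new <- (P_new + t(P_new)) / 2
  state$x <- as.vector(x_new)
  state$P <- P_new
  state$G <- G
  state
}

#' Advance the smoother by one filtered frame
#'
#' Assembles the measurement `y = (ax, ay, az, ay - bay)` from the previous
#' step's bias (strictly causal), runs [kalman_step()], then pushes the new
#' vertical state into the bias window and recomputes
#' `bay = mean(last bias_window values of x2)`. During warm-up the partially
#' filled window is averaged as-is.
#'
#' @param state state from [kalman_init()] (or a previous call).
#' @param frame filtered acceleration triple `(ax, ay, az)` in bits.
#' @param config a [kalman_config()].
#' @return the updated state.
#' @export
kalman_advance <- function(state, frame, config = kalman_config()) {
  y <- c(frame[1L], frame[2L], frame[3L], frame[2L] - state$bay)
  state <- kalman_step(state, y, config)
  buf <- c(state$x2_buf, state$x[2L])
  if (length(buf) > config$bias_window) {
    buf <- buf[(length(buf) - config$bias_window + 1L):length(buf)]
  }
  state$x2_buf <- buf
  state$bay <- sum(buf) / length(buf)
  state
}

#' Run the smoother over a whole filtered sequence
#'
#' @param filtered numeric matrix (samples x 3) of low-pass-filtered
#'   acceleration in bits.
#' @param config a [kalman_config()].
#' @return list with `states` (samples x 4 matrix x1..x4) and `bay`
#'   (per-sample vertical bias after the update).
#' @export
run_kalman <- function(filtered, config = kalman_config()) {
  filtered <- as.matrix(filtered)
  n <- nrow(filtered)
  states <- matrix(0, n, 4L)
  bay <- numeric(n)
  st <- kalman_init(config)
  for (k in seq_len(n)) {
    st <- kalman_advance(st, filtered[k, ], config)
    states[k, ] <- st$x
    bay[k] <- st$bay
  }
  colnames(states) <- c("x1", "x2", "x3", "x4")
  list(states = states, bay = bay)
}

#' Noise-covariance tuning heuristic report
#'
#' Advisory schedule mirroring the manual tuning recipe: starting from
#' identity covariances, the per-state standard deviations of Q and then R are
#' shrunk by factors 10, 5 and 2 (first for the orientation states, then for
#' the oscillation state), and after each step the report records a flatness
#' diagnostic (mean variance of x1..x3 over the walk segment, which should
#' fall as Q shrinks) and a sinusoid-quality diagnostic for x4 (coefficient of
#' variation of its zero-crossing half-periods over the walk segment, lower is
#' more regular). The function does not auto-select values.
#'
#' @param recording a recording containing walk and fall segments.
#' @param walk_window,fall_window sample ranges (at 25 Hz, after decimation)
#'   of the walk and fall segments; defaults: first half / last third.
#' @param fs pipeline rate in Hz.
#' @return data frame with one row per schedule step: the stage adjusted, the
#'   shrink factor, current stds, and the diagnostics.
#' @export
tune_heuristic <- function(recording, walk_window = NULL, fall_window = NULL,
                           fs = 25) {
  rec <- downsample(recording, fs)
  n <- nrow(rec$frames)
  if (n / fs < 10) stop("recording too short for tuning (< 10 s)")
  if (is.null(walk_window)) walk_window <- seq_len(floor(n / 2))
  if (is.null(fall_window)) fall_window <- seq(floor(2 * n / 3), n)
  lp <- lowpass_filter(rec$frames, lowpass_init(design_lowpass(fs = fs)))
  filtered <- lp$y

  diag_row <- function(q123, r123, q4, r4, stage, factor) {
    cfg <- kalman_config(Q = diag(c(rep(q123^2, 3L), q4^2)),
                         R = diag(c(rep(r123^2, 3L), r4^2)))
    kal <- run_kalman(filtered, cfg)
    walk_states <- kal$states[walk_window, 1:3, drop = FALSE]
    flatness <- mean(apply(walk_states, 2L, stats::var))
    hp <- diff(zero_crossings(kal$states[walk_window, 4L]))
    x4_cv <- if (length(hp) >= 2L) stats::sd(hp) / mean(hp) else NA_real_
    data.frame(stage = stage, factor = factor,
               q_std_xyz = q123, r_std_xyz = r123,
               q_std_x4 = q4, r_std_x4 = r4,
               flatness = flatness, x4_halfperiod_cv = x4_cv)
  }

  q123 <- r123 <- q4 <- r4 <- 1
  rows <- list(diag_row(q123, r123, q4, r4, "init", 1))
  for (f in c(10, 5, 2)) {
    q123 <- q123 / f
    rows <- c(rows, list(diag_row(q123, r123, q4, r4, "Q_xyz", f)))
    r123 <- r123 / f
    rows <- c(rows, list(diag_row(q123, r123, q4, r4, "R_xyz", f)))
  }
  for (f in c(10, 5, 2)) {
    q4 <- q4 / f
    rows <- c(rows, list(diag_row(q123, r123, q4, r4, "Q_x4", f)))
    r4 <- r4 / f
    rows <- c(rows, list(diag_row(q123, r123, q4, r4, "R_x4", f)))
  }
  do.call(rbind, rows)
}
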