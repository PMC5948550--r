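#' Decimate a recording to the pipeline rate
#'
#' Plain stride decimation: keeps every `sample_rate / target_rate`-th frame
#' starting at the first one, mirroring a device that natively samples at
#' 25 Hz (no anti-alias prefilter; the 5 Hz low-pass stage runs after
#' decimation).
#'
#' @param recording an [new_recording()] object.
#' @param target_rate target rate in Hz; must divide the recording rate.
#' @return the decimated recording (identity when already at `target_rate`).
#' @export
downsample <- function(recording, target_rate = 25) {
  fs <- recording$sample_rate
  if (fs == target_rate) return(recording)
  ratio <- fs / target_rate
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop(sprintf("sample rate %g Hz is not an integer multiple of %g Hz",
                 fs, target_rate))
  }
  ratio <- as.integer(round(ratio))
  idx <- seq(1L, nrow(recording$frames), by = ratio)
  out <- recording
  out$frames <- recording$frames[idx, , drop = FALSE]
  out$sample_rate <- target_rate
  out
}

#' Design the low-pass stage as cascaded biquads
#'
#' Butterworth IIR low-pass (default 4th order, 5 Hz cut-off at 25 Hz), split
#' into second-order sections for numerical stability. Each section is scaled
#' to unity DC gain, so the cascade has unity DC gain as well (the Butterworth
#' low-pass prototype has unit gain at DC).
#'
#' @param fc cut-off frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (even).
#' @return list with `sos` (n_sections x 6 matrix of b0,b1,b2,1,a1,a2),
#'   and the direct-form `b`, `a` vectors for reference/frequency evaluation.
#' @export
design_lowpass <- function(fc = 5, fs = 25, order = 4L) {
  stopifnot(order %% 2 == 0, order >= 2, fc > 0, fs > 2 * fc)
  ba <- signal::butter(order, 2 * fc / fs, type = "low")
  b <- as.numeric(ba$b)
  a <- as.numeric(ba$a)
  poles <- polyroot(rev(a))
  # pair each pole with its conjugate (Butterworth order-4 at this band has
  # two strictly complex pairs)
  up <- poles[Im(poles) > 1e-12]
  if (length(up) * 2L != length(poles)) {
    # fall back: sort by argument and pair adjacent (handles real poles)
    poles <- poles[order(Arg(poles))]
    up <- poles[seq(1L, length(poles), by = 2L)]
  }
  sos <- t(vapply(up, function(p) {
    a1 <- -2 * Re(p)
    a2 <- Mod(p)^2
    g <- (1 + a1 + a2) / 4  # unity DC gain per section
    c(g, 2 * g, g, 1, a1, a2)
  }, numeric(6)))
  list(sos = sos, b = b, a = a, fc = fc, fs = fs, order = order)
}

#' Initialize streaming filter state
#'
#' Zero initial conditions (no warm-start): the filter accepts a brief
#' transient at stream start, matching a deterministic embedded realization.
#'
#' @param design output of [design_lowpass()].
#' @param n_channels number of independent channels filtered in parallel.
#' @return list with the design and per-section, per-channel delay registers.
#' @export
lowpass_init <- function(design, n_channels = 3L) {
  list(design = design,
       z = array(0, dim = c(nrow(design$sos), 2L, n_channels)))
}

#' Stream samples through the biquad cascade
#'
#' Causal, sample-by-sample (direct form II transposed per section), applied
#' to each channel independently. Feeding a sequence in chunks produces the
#' same output as one batch call with the same initial state.
#'
#' @param x numeric vector (one channel) or matrix (samples x channels).
#' @param state filter state from [lowpass_init()].
#' @return list with `y` (filtered, same shape as `x`) and the updated `state`.
#' @export
lowpass_filter <- function(x, state) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  sos <- state$design$sos
  z <- state$z
  nsec <- nrow(sos)
  n <- nrow(xm)
  y <- xm
  for (ch in seq_len(ncol(xm))) {
    for (k in seq_len(n)) {
      v <- y[k, ch]
      for (s in seq_len(nsec)) {
        b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
        a1 <- sos[s, 5]; a2 <- sos[s, 6]
        out <- b0 * v + z[s, 1, ch]
        z[s, 1, ch] <- b1 * v - a1 * out + z[s, 2, ch]
        z[s, 2, ch] <- b2 * v - a2 * out
        v <- out
      }
      y[k, ch] <- v
    }
  }
  state$z <- z
  list(y = if (vec) y[, 1] else y, state = state)
}

#' Complex frequency response of the designed filter
#'
#' @param design output of [design_lowpass()].
#' @param f frequencies in Hz.
#' @return complex response H at each frequency.
#' @export
lowpass_response <- function(design, f) {
  w <- 2 * pi * f / design$fs
  z <- exp(-1i * w)
  num <- outer(z, seq_along(design$b) - 1L, `^`) %*% design$b
  den <- outer(z, seq_along(design$a) - 1L, `^`) %*% design$a
  as.vector(num / den)
}

#' Sample-to-sample differencing
#'
#' Removes the (slowly varying) gravity bias before the impact feature J1:
#' emits `a[k] - a[k-1]` per axis, with a zero triple at the first sample.
#'
#' @param x numeric matrix (samples x axes) of filtered acceleration.
#' @return matrix of the same shape with per-sample differences.
#' @export
differentiate <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 1L) return(x * 0)
  rbind(x[1L, , drop = FALSE] * 0, diff(x))
}
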