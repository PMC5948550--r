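#' Periodicity detector configuration
#'
#' Quantifies "stable periodicity" after a candidate fall: at least
#' `min_halfperiods` half-periods, all within `tol_frac` of their median,
#' an estimated period inside the gait band (0.4--2.0 s covers slow walking),
#' and an oscillation amplitude of at least `min_amplitude_bits` (so that
#' quasi-regular zero crossings of smoothed sensor noise on an otherwise flat
#' post-fall signal can never veto a true alarm).
#'
#' @param min_halfperiods minimum number of half-periods that must sit within
#'   the tolerance band of their median.
#' @param tol_frac relative tolerance around the median half-period.
#' @param gait_period_range_s admissible period range in seconds.
#' @param min_amplitude_bits minimum oscillation amplitude in bits.
#' @param veto_window_s length of the post-candidate analysis window.
#' @param local_debias remove a centered 1 s moving average from the analysis
#'   window before crossing detection. The global bias tracker removes the
#'   vertical bias dynamically, but the candidate impact itself perturbs it
#'   for a few seconds, leaving a decaying offset on x4; the local debias
#'   restores the zero-crossing geometry of any gait oscillation riding on
#'   that offset, while a monotone post-fall decay minus its own local mean
#'   never produces a regular gait-band crossing pattern.
#' @param debias_window_n moving-average width in samples (1 s).
#' @param edge_trim_n samples discarded at each end of the debiased window,
#'   where the partial-window average distorts crossing positions.
#' @param fs pipeline rate in Hz.
#' @return object of class `periodicity_config`.
#' @export
periodicity_config <- function(min_halfperiods = 4L, tol_frac = 0.25,
                               gait_period_range_s = c(0.4, 2.0),
                               min_amplitude_bits = 5, veto_window_s = 3,
                               local_debias = TRUE, debias_window_n = 25L,
                               edge_trim_n = 10L, fs = 25) {
  structure(
    list(min_halfperiods = as.integer(min_halfperiods), tol_frac = tol_frac,
         gait_period_range_s = gait_period_range_s,
         min_amplitude_bits = min_amplitude_bits,
         veto_window_s = veto_window_s, local_debias = local_debias,
         debias_window_n = as.integer(debias_window_n),
         edge_trim_n = as.integer(edge_trim_n), fs = fs),
    class = "periodicity_config"
  )
}

#' Zero crossings of the de-biased vertical state
#'
#' Indices `k` where `sign(x[k]) != sign(x[k-1])`. Exact zeros inherit the
#' previous sign (a leading zero counts as positive), so a sample that lands
#' exactly on zero is never counted as two crossings.
#'
#' @param x numeric vector (length >= 2) of x4 values.
#' @return integer vector of crossing indices (possibly empty).
#' @export
zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) stop("window must hold at least 2 samples")
  s <- sign(x)
  if (s[1L] == 0) s[1L] <- 1
  for (k in 2:n) if (s[k] == 0) s[k] <- s[k - 1L]
  which(s[-1L] != s[-n]) + 1L
}

#' Estimate the gait period from zero crossings
#'
#' Half-periods are the sample counts between consecutive sign changes of the
#' (locally debiased) x4 window; the period is twice a representative
#' half-period. The representative value is the mean of the half-periods that
#' lie within `tol_frac` of their median (the trim discards spurious
#' crossings injected by noise near zero), and the period is rounded to the
#' nearest integer sample count: on a noiseless sinusoid of integer period p
#' the crossing spacings alternate between floor(p/2) and ceil(p/2), and the
#' rounded doubled mean recovers p exactly.
#'
#' `stable` requires at least `min_halfperiods` half-periods inside the
#' tolerance band, a period inside the gait band, and sufficient oscillation
#' amplitude (the 0.9 quantile of the absolute deviation from the window
#' median).
#'
#' @param x numeric vector of x4 over the analysis span.
#' @param config a [periodicity_config()].
#' @return list with `half_periods`, `period_samples` (NA when
#'   undeterminable), `stable`, `n_crossings` and `amplitude`.
#' @export
estimate_period <- function(x, config = periodicity_config()) {
  if (isTRUE(config$local_debias) && length(x) >= 2L) {
    n <- length(x)
    h <- config$debias_window_n %/% 2L
    m <- vapply(seq_len(n), function(k) {
      mean(x[max(1L, k - h):min(n, k + h)])
    }, numeric(1))
    x <- x - m
    trim <- config$edge_trim_n
    if (n > 2L * trim + 4L) x <- x[(trim + 1L):(n - trim)]
  }
  cr <- zero_crossings(x)
  hp <- diff(cr)
  if (length(hp) < 1L) {
    amplitude <- as.numeric(stats::quantile(abs(x - stats::median(x)), 0.9))
    return(list(half_periods = integer(0), period_samples = NA_real_,
                stable = FALSE, n_crossings = length(cr),
                amplitude = amplitude))
  }
  # oscillation amplitude: the median over crossing intervals of the peak
  # excursion within the interval -- genuine gait sustains its amplitude on
  # every half cycle, whereas the decaying tail of an impact transient leaves
  # only sub-bit wiggles between its late crossings
  amplitude <- stats::median(vapply(seq_along(hp), function(i) {
    max(abs(x[cr[i]:(cr[i + 1L] - 1L)]))
  }, numeric(1)))
  med <- stats::median(hp)
  tol_lo <- (1 - config$tol_frac) * med
  tol_hi <- (1 + config$tol_frac) * med
  # a single displaced crossing splits one period into an out-of-tolerance
  # pair (e.g. 7,12 instead of 10,10) whose sum is still a full period;
  # merge such pairs back before judging regularity
  hp_adj <- as.numeric(hp)
  i <- 1L
  while (i < length(hp_adj)) {
    any_out <- hp_adj[i] < tol_lo || hp_adj[i] > tol_hi ||
      hp_adj[i + 1L] < tol_lo || hp_adj[i + 1L] > tol_hi
    if (any_out && abs(hp_adj[i] + hp_adj[i + 1L] - 2 * med) <=
        config$tol_frac * 2 * med) {
      hp_adj[i] <- hp_adj[i + 1L] <- (hp_adj[i] + hp_adj[i + 1L]) / 2
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  in_tol <- hp_adj >= tol_lo & hp_adj <= tol_hi
  period <- round(2 * mean(hp_adj[in_tol]))
  band <- config$gait_period_range_s * config$fs
  stable <- sum(in_tol) >= config$min_halfperiods &&
    !is.na(period) && period >= band[1L] && period <= band[2L] &&
    amplitude >= config$min_amplitude_bits
  list(half_periods = hp, period_samples = period, stable = stable,
       n_crossings = length(cr), amplitude = amplitude)
}

#' Periodicity veto for a candidate fall
#'
#' Analyzes the 3 s of x4 following a candidate: if the periodicity is kept
#' stable the wearer is still in a periodic activity (walk/jog) and the
#' candidate is vetoed; after a true fall the periodic signal disappears and
#' the candidate is confirmed. A post-window truncated by the end of the
#' stream confirms the candidate with a truncation flag (missing a real fall
#' is worse than a late false positive).
#'
#' @param x4_post x4 values after the candidate sample.
#' @param config a [periodicity_config()].
#' @return list with `vetoed`, `truncated` and the period `estimate`.
#' @export
veto_candidate <- function(x4_post, config = periodicity_config()) {
  expected <- round(config$veto_window_s * config$fs)
  truncated <- length(x4_post) < expected
  if (length(x4_post) < 2L) {
    return(list(vetoed = FALSE, truncated = TRUE,
                estimate = list(stable = FALSE, period_samples = NA_real_,
                                half_periods = integer(0), n_crossings = 0L,
                                amplitude = 0)))
  }
  est <- estimate_period(x4_post, config)
  list(vetoed = !truncated && est$stable, truncated = truncated,
       estimate = est)
}
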