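#' Specification for one synthetic accelerometry recording
#'
#' Seeded generator emulating the waist-worn device signal morphology the
#' detector assumes: a resting vertical bias of -1 G (-256 bits), periodic
#' activities as quasi-sinusoids riding on that bias, falls as a
#' high-amplitude impact followed by a sustained gravity rotation, posture
#' transitions as smooth gravity rotations without a large impact, and jumps
#' as impacts whose bias returns to rest. Amplitude defaults are calibrated so
#' that, with the default pipeline configuration, fall files reach J3 maxima
#' above the 40,000 operating threshold while ADL files stay well below it.
#'
#' @param activity one of `"rest"`, `"walk"`, `"jog"`, `"stairs"`,
#'   `"sit_transition"`, `"bed_turn"`, `"jump"`, `"fall_forward"`,
#'   `"fall_backward"`, `"jog_trip_fall"`.
#' @param duration_s recording length in seconds.
#' @param gait_period_s gait period (0.3--3 s) for periodic activities.
#' @param gait_amplitude_bits vertical gait oscillation amplitude in bits.
#' @param impact_amplitude_bits impact peak amplitude in bits.
#' @param post_fall_axis axis carrying gravity after a fall: `"x"`, `"-x"`,
#'   `"z"` or `"-z"`.
#' @param fall_angle_deg gravity rotation angle of the fall (90 = fully
#'   horizontal).
#' @param fall_time_s impact time; default 0.6 of the duration (0.4 for
#'   `jog_trip_fall`).
#' @param transition_angle_deg rotation angle of posture transitions.
#' @param transition_tau_s sigmoid time constant of the rotation (about a
#'   quarter of the transition span).
#' @param spike_amplitude_bits optional single-sample spike amplitude (0 =
#'   none), used to exercise the false-positive/veto path during gait.
#' @param spike_time_s spike time; default mid-recording.
#' @param noise_sd_bits i.i.d. Gaussian sensor noise, rounded to integer bits.
#' @param sample_rate 25 or 200 Hz.
#' @param seed RNG seed fixing the full sample path.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(activity, duration_s = 15, gait_period_s = NULL,
                       gait_amplitude_bits = NULL,
                       impact_amplitude_bits = NULL,
                       post_fall_axis = "x", fall_angle_deg = 90,
                       fall_time_s = NULL, transition_angle_deg = NULL,
                       transition_tau_s = NULL, spike_amplitude_bits = 0,
                       spike_time_s = NULL, noise_sd_bits = 3,
                       sample_rate = 25, seed = 1L) {
  activities <- c("rest", "walk", "jog", "stairs", "sit_transition",
                  "bed_turn", "jump", "fall_forward", "fall_backward",
                  "jog_trip_fall")
  if (!activity %in% activities) {
    stop("unknown activity: ", activity)
  }
  stopifnot(duration_s > 0, noise_sd_bits >= 0, sample_rate > 0)
  # per-activity morphology defaults
  def <- switch(activity,
    walk = list(period = 1.0, amp = 40),
    jog = list(period = 0.8, amp = 80),
    stairs = list(period = 0.9, amp = 55),
    jog_trip_fall = list(period = 0.8, amp = 80),
    list(period = 1.0, amp = 0))
  if (is.null(gait_period_s)) gait_period_s <- def$period
  if (is.null(gait_amplitude_bits)) gait_amplitude_bits <- def$amp
  if (is.null(impact_amplitude_bits)) {
    impact_amplitude_bits <- switch(activity,
      jump = 600, fall_forward = 1500, fall_backward = 1500,
      jog_trip_fall = 1500, 0)
  }
  if (is.null(fall_time_s)) {
    fall_time_s <- if (activity == "jog_trip_fall") 0.4 * duration_s
                   else 0.6 * duration_s
  }
  if (is.null(transition_angle_deg)) {
    transition_angle_deg <- switch(activity,
      sit_transition = 25, bed_turn = 90, 0)
  }
  if (is.null(transition_tau_s)) {
    transition_tau_s <- switch(activity,
      sit_transition = 0.4, bed_turn = 0.8, 0.1)
  }
  if (is.null(spike_time_s)) spike_time_s <- duration_s / 2
  stopifnot(gait_period_s >= 0.3, gait_period_s <= 3,
            gait_amplitude_bits >= 0, impact_amplitude_bits >= 0)
  structure(
    list(activity = activity, duration_s = duration_s,
         gait_period_s = gait_period_s,
         gait_amplitude_bits = gait_amplitude_bits,
         impact_amplitude_bits = impact_amplitude_bits,
         post_fall_axis = post_fall_axis, fall_angle_deg = fall_angle_deg,
         fall_time_s = fall_time_s,
         transition_angle_deg = transition_angle_deg,
         transition_tau_s = transition_tau_s,
         spike_amplitude_bits = spike_amplitude_bits,
         spike_time_s = spike_time_s, noise_sd_bits = noise_sd_bits,
         sample_rate = sample_rate, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# unit vector of a signed axis name
axis_vector <- function(name) {
  sgn <- if (startsWith(name, "-")) -1 else 1
  ax <- sub("^-", "", name)
  v <- c(x = 0, y = 0, z = 0)
  if (!ax %in% names(v)) stop("unknown axis: ", name)
  v[ax] <- sgn
  unname(v)
}

# biphasic impact envelope in 25 Hz sample units (linear interpolation, so
# 200 Hz grids sample the same continuous shape)
impact_envelope <- function(u) {
  pts <- c(0.3, 1, -0.7, 0.25)
  out <- numeric(length(u))
  inside <- u >= 0 & u <= 3
  out[inside] <- stats::approx(0:3, pts, xout = u[inside])$y
  out
}

#' Generate a synthetic recording
#'
#' Deterministic given the spec's seed (same seed, same bytes). The returned
#' recording carries a `ground_truth` attribute with the generator's own
#' deterministic bias path summary: per-axis sustained bias change (bits) and
#' whether an impact was injected, so structural invariants of the corpus can
#' be asserted without running the detector.
#'
#' @param spec a [synth_spec()].
#' @return an [new_recording()] object labelled via its activity code
#'   (`F9x` for falls, `D9x` for ADLs).
#' @export
gen_recording <- function(spec) {
  fs <- spec$sample_rate
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  g_rest <- c(0, -256, 0)

  # deterministic gravity-bias path
  bias <- matrix(rep(g_rest, each = n), n, 3L)
  has_impact <- spec$impact_amplitude_bits > 0
  rot_target <- NULL
  if (spec$activity %in% c("fall_forward", "fall_backward", "jog_trip_fall")) {
    tgt <- if (spec$activity == "fall_backward") "z" else spec$post_fall_axis
    rot_target <- axis_vector(tgt)
    theta <- spec$fall_angle_deg * pi / 180 *
      stats::plogis((t - spec$fall_time_s) / 0.08)
    bias <- outer(cos(theta), g_rest) + outer(sin(theta), 256 * rot_target)
  } else if (spec$activity %in% c("sit_transition", "bed_turn")) {
    tgt <- if (spec$activity == "bed_turn") "z" else "x"
    rot_target <- axis_vector(tgt)
    t0 <- spec$duration_s / 2
    theta <- spec$transition_angle_deg * pi / 180 *
      stats::plogis((t - t0) / spec$transition_tau_s)
    bias <- outer(cos(theta), c(0, -256, 0)) + outer(sin(theta), 256 * rot_target)
  }

  # gait oscillation (stops at the trip for jog_trip_fall)
  sig <- bias
  if (spec$gait_amplitude_bits > 0 &&
      spec$activity %in% c("walk", "jog", "stairs", "jog_trip_fall")) {
    A <- spec$gait_amplitude_bits
    Tg <- spec$gait_period_s
    phase <- with_seed(spec$seed + 1L, stats::runif(1, 0, 2 * pi))
    active <- if (spec$activity == "jog_trip_fall") t < spec$fall_time_s
              else rep(TRUE, n)
    sig[, 2] <- sig[, 2] + active * A * sin(2 * pi * t / Tg + phase)
    sig[, 1] <- sig[, 1] + active * 0.35 * A * sin(4 * pi * t / Tg + phase + 1.1)
    sig[, 3] <- sig[, 3] + active * 0.25 * A * sin(2 * pi * t / Tg + phase + 2.3)
  }

  # impact (falls and jumps): biphasic pulse, strongest on the vertical axis
  if (has_impact) {
    ti <- if (spec$activity == "jump") spec$duration_s / 2 else spec$fall_time_s
    env <- spec$impact_amplitude_bits * impact_envelope((t - ti) * 25)
    sig[, 2] <- sig[, 2] + env
    sig[, 1] <- sig[, 1] + 0.5 * env
    sig[, 3] <- sig[, 3] + 0.3 * env
  }

  # isolated spike (false-positive path exercise)
  if (spec$spike_amplitude_bits > 0) {
    ks <- round(spec$spike_time_s * fs) + 1L
    if (ks >= 1L && ks <= n) sig[ks, 2] <- sig[ks, 2] + spec$spike_amplitude_bits
  }

  if (spec$noise_sd_bits > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(3L * n, 0, spec$noise_sd_bits), n, 3L))
    sig <- sig + noise
  }
  frames <- matrix(as.integer(pmin(pmax(round(sig), -4096), 4095)), n, 3L)

  code <- synthetic_activity_code(spec$activity)
  rec <- new_recording(frames, fs, subject_code = "SY01",
                       activity_code = code, trial = 1L)
  attr(rec, "ground_truth") <- list(
    activity = spec$activity,
    bias_change_bits = abs(bias[n, ] - bias[1L, ]),
    has_impact = has_impact,
    gait_period_s = if (spec$gait_amplitude_bits > 0) spec$gait_period_s else NA_real_
  )
  rec
}

synthetic_activity_code <- function(activity) {
  switch(activity,
    rest = "D91", walk = "D92", jog = "D93", stairs = "D94",
    sit_transition = "D95", bed_turn = "D96", jump = "D97",
    fall_forward = "F91", fall_backward = "F92", jog_trip_fall = "F93",
    stop("unknown activity: ", activity))
}

# corpus presets: named parameter bundles over synth_spec
corpus_presets <- function() {
  list(
    rest = list(activity = "rest"),
    walk = list(activity = "walk"),
    jog = list(activity = "jog"),
    stairs = list(activity = "stairs"),
    sit_transition = list(activity = "sit_transition"),
    bed_turn = list(activity = "bed_turn"),
    jump = list(activity = "jump"),
    fall_forward = list(activity = "fall_forward"),
    fall_backward = list(activity = "fall_backward"),
    jog_trip_fall = list(activity = "jog_trip_fall"),
    # hard-corpus variants exercising the false-positive paths
    jog_spike = list(activity = "jog", spike_amplitude_bits = 3000),
    bed_turn_fast = list(activity = "bed_turn", transition_tau_s = 0.25),
    fall_soft = list(activity = "fall_forward", impact_amplitude_bits = 700,
                     fall_angle_deg = 70)
  )
}

#' Default separable corpus mix
#'
#' 40 ADL files across all ADL morphologies and 20 falls: with default
#' amplitudes the pipeline scores of falls and ADLs do not overlap.
#'
#' @return named integer vector of file counts per preset.
#' @export
default_corpus_mix <- function() {
  c(rest = 4L, walk = 8L, jog = 8L, stairs = 6L, sit_transition = 6L,
    bed_turn = 4L, jump = 4L, fall_forward = 8L, fall_backward = 6L,
    jog_trip_fall = 6L)
}

#' Hard corpus mix
#'
#' Exercises the false-positive paths: jogs with isolated spikes (candidates
#' the veto must suppress), fast bed turns, and soft low-impact partial-angle
#' falls whose scores overlap the spike artefacts unless the veto is on.
#'
#' @return named integer vector of file counts per preset.
#' @export
hard_corpus_mix <- function() {
  c(jog_spike = 8L, bed_turn_fast = 6L, stairs = 4L, jump = 4L, walk = 4L,
    fall_soft = 8L, fall_backward = 3L, jog_trip_fall = 3L)
}

#' Generate a labelled corpus of synthetic recordings
#'
#' Per-file seeds are derived reproducibly from the corpus seed, so the corpus
#' regenerates identically from `(mix, base, seed)`. When `dir` is given the
#' recordings are written as SisFall-dialect text files together with a
#' `manifest.csv`.
#'
#' @param mix named integer vector of counts per preset (see
#'   [default_corpus_mix()], [hard_corpus_mix()]).
#' @param base named list of [synth_spec()] overrides applied to every file.
#' @param seed corpus seed.
#' @param dir optional output directory.
#' @return list with `recordings` (list) and `manifest` (data frame with
#'   `file`, `preset`, `activity_code`, `is_fall`, `seed`).
#' @export
gen_corpus <- function(mix = default_corpus_mix(), base = list(), seed = 1L,
                       dir = NULL) {
  presets <- corpus_presets()
  unknown <- setdiff(names(mix), names(presets))
  if (length(unknown)) stop("unknown presets: ", paste(unknown, collapse = ", "))
  if (sum(mix) < 2L) stop("corpus needs at least 2 files")
  recs <- list()
  rows <- list()
  i <- 0L
  for (p in names(mix)) {
    for (r in seq_len(mix[[p]])) {
      i <- i + 1L
      args <- utils::modifyList(presets[[p]], base)
      args$seed <- (as.numeric(seed) * 7919 + i) %% 2147483647
      spec <- do.call(synth_spec, args)
      rec <- gen_recording(spec)
      fname <- sprintf("%s_SY01_R%02d.txt", rec$activity_code, i)
      recs[[i]] <- rec
      rows[[i]] <- data.frame(file = fname, preset = p,
                              activity_code = rec$activity_code,
                              is_fall = rec$is_fall, seed = args$seed,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$activity <- manifest$preset
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (j in seq_along(recs)) {
      write_recording(recs[[j]], file.path(dir, manifest$file[j]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
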