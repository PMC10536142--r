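#' Action templates of the synthetic signal generator
#'
#' Each of the four rehabilitation actions is emulated as a smooth 30-sample
#' (2 s at 15 Hz) three-channel curve of normalized pressure deviations built
#' from one or two localized Gaussian bumps, with an action-specific channel
#' weighting: the stretch-and-fist action loads all three channels with a
#' double bump; separating-and-merging fingers produces one broad mid-window
#' bump on the radial and dorsal channels; palm flexion/dorsiflexion loads the
#' palmar channel early and the dorsal channel late; ulnar deviation loads the
#' radial channel asymmetrically. Every template starts and ends exactly at
#' the resting level (endpoints are pinned by removing the linear trend
#' between the first and last sample) and has enough activity in the oldest
#' ten samples to pass the pre-detection gate at the default thresholds.
#'
#' @return A list of four 3 x 30 matrices of deviations from the resting
#'   ratio 1.0, named as in [action_labels()].
#' @export
action_templates <- function() {
  j <- 1:30
  bump <- function(center, width, amp) amp * exp(-0.5 * ((j - center) / width)^2)
  pin <- function(v) v - v[1] - (v[30] - v[1]) * (j - 1) / 29
  # Every channel carries an early (sample 9) and a late (sample 21) bump so
  # that (a) the oldest-ten-sample prefix is active, (b) mid-window truncation
  # leaves every channel well off baseline (the head-tail rule then rejects
  # incompletely entered actions on all three channels), and (c) the curve is
  # back at rest by sample ~28. Actions differ in their channel amplitude
  # signature; action 2 adds a broad mid-window bump.
  chan <- function(a_early, a_late, a_mid = 0)
    bump(9, 2.6, a_early) + bump(23, 2.2, a_late) + bump(15, 3.0, a_mid)
  tpl <- list(
    stretch_fist = rbind(           # double bump, all channels, palmar-heavy
      chan(0.50, 0.45),
      chan(0.40, 0.38),
      chan(0.35, 0.32)),
    separate_merge_fingers = rbind( # broad loading, radial early / dorsal late
      chan(0.18, 0.30, 0.10),
      chan(0.55, 0.35, 0.25),
      chan(0.30, 0.55, 0.22)),
    palm_flexion_dorsiflexion = rbind(  # palmar flexion early, dorsal late
      chan(0.60, 0.30),
      chan(0.25, 0.40),
      chan(0.20, 0.60)),
    ulnar_deviation = rbind(        # asymmetric radial loading
      chan(0.30, 0.35),
      chan(0.70, 0.55),
      chan(0.25, 0.30))
  )
  lapply(tpl, function(m) t(apply(m, 1, pin)))
}

#' Synthetic subject profile
#'
#' Captures the per-subject variability the generator emulates: resting
#' baselines (how tightly the wristband sits), an overall amplitude scale,
#' and the jitter/noise magnitudes applied to every generated sample.
#'
#' @param baseline Length-3 positive resting baselines in AD counts
#'   (12-bit convention, 0--4095).
#' @param amp_scale Overall multiplier on template amplitudes.
#' @param amp_jitter Half-width of the per-sample uniform amplitude jitter
#'   (default 0.2, i.e. +/-20 percent).
#' @param time_jitter Maximum per-sample integer timing shift (default 2).
#' @param noise_sd Additive Gaussian sensor-noise standard deviation in ratio
#'   units (default 0.01). The noise is a stationary AR(1) process with this
#'   marginal standard deviation: the analog front end and ADC averaging
#'   low-pass the signal, so consecutive 15 Hz readings are strongly
#'   correlated rather than white.
#' @param noise_rho Lag-1 autocorrelation of the sensor noise (default 0.9).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(baseline = c(1000, 1200, 1100), amp_scale = 1,
                            amp_jitter = 0.2, time_jitter = 2L,
                            noise_sd = 0.01, noise_rho = 0.9) {
  baseline <- as.numeric(baseline)
  if (length(baseline) != 3L || any(baseline <= 0))
    stop_input("baseline must be 3 positive AD counts")
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  if (noise_rho < 0 || noise_rho >= 1) stop_input("noise_rho must be in [0, 1)")
  structure(list(baseline = baseline, amp_scale = amp_scale,
                 amp_jitter = amp_jitter, time_jitter = as.integer(time_jitter),
                 noise_sd = noise_sd, noise_rho = noise_rho),
            class = "subject_profile")
}

# Stationary AR(1) sensor noise, one row per channel, marginal sd = sd.
sensor_noise <- function(n, sd, rho, channels = 3L) {
  out <- matrix(0, channels, n)
  if (sd == 0 || n == 0L) return(out)
  for (ch in seq_len(channels)) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd)
    if (n > 1L) {
      e <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - rho^2))
      for (i in 2:n) x[i] <- rho * x[i - 1L] + e[i - 1L]
    }
    out[ch, ] <- x
  }
  out
}

# Deviation curve for one sample: template scaled by the subject's amplitude
# scale, jittered in amplitude and (integer) timing, endpoints re-pinned.
jittered_deviation <- function(label, profile) {
  tpl <- action_templates()[[label]]
  amp <- profile$amp_scale
  if (profile$amp_jitter > 0)
    amp <- amp * stats::runif(1, 1 - profile$amp_jitter, 1 + profile$amp_jitter)
  dev <- tpl * amp
  if (profile$time_jitter > 0) {
    sh <- sample.int(2L * profile$time_jitter + 1L, 1L) - profile$time_jitter - 1L
    if (sh != 0) {
      shifted <- matrix(0, 3, 30)
      src <- (1:30) - sh
      ok <- src >= 1 & src <= 30
      shifted[, ok] <- dev[, src[ok]]
      dev <- shifted
    }
  }
  j <- 1:30
  t(apply(dev, 1, function(v) v - v[1] - (v[30] - v[1]) * (j - 1) / 29))
}

#' Generate one labeled synthetic action sample
#'
#' The action template for `label` is amplitude- and timing-jittered per the
#' subject profile, Gaussian sensor noise is added in ratio units, and the
#' curve is scaled by the subject's resting baselines back to integer AD
#' counts (12-bit, clamped to 0--4095). By construction a generated sample,
#' embedded in a full window, passes the pre-detection gate at the default
#' thresholds, and distinct labels remain distinguishable at the default
#' noise.
#'
#' @param label Action label 1--4 (or a name from [action_labels()]).
#' @param profile A [subject_profile()].
#' @param seed Optional integer seed.
#' @return A 3 x 30 `raw_sample` matrix of AD counts.
#' @export
generate_action_sample <- function(label, profile, seed = NULL) {
  if (is.character(label)) label <- action_labels()[[label]]
  label <- as.integer(label)
  if (is.na(label) || label < 1L || label > 4L)
    stop_input("label must be in 1..4")
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(seed, {
    dev <- jittered_deviation(label, profile)
    u <- 1 + dev + sensor_noise(30L, profile$noise_sd, profile$noise_rho)
    if (min(abs(u[, 1] - u[, 30])) >= 0.03)
      warning("noise violates the head~tail constraint for this sample")
    raw <- round(u * profile$baseline)
    raw_sample(pmin(pmax(raw, 0), 4095))
  })
}

# Capture one action the way deployment does: embed a jittered action curve
# in rest, slide the pre-detection gate over the normalized stream, and keep
# the first accepted window. This aligns the training-sample distribution
# with the windows the streaming detector will hand to the classifier. Falls
# back to the aligned window in the (rare) case the gate accepts nothing.
capture_action_sample <- function(label, profile, cfg = detection_config()) {
  pre <- 12L; post <- 10L
  dev <- jittered_deviation(label, profile)
  u <- cbind(matrix(0, 3, pre), dev, matrix(0, 3, post)) + 1 +
    sensor_noise(pre + 30L + post, profile$noise_sd, profile$noise_rho)
  ws <- cfg$window_size
  win <- NULL
  for (e in ws:ncol(u)) {
    w <- u[, (e - ws + 1L):e, drop = FALSE]
    if (is_action(w, cfg)) { win <- w; break }
  }
  if (is.null(win)) win <- u[, (pre + 1L):(pre + 30L), drop = FALSE]
  raw <- round(win * profile$baseline)
  raw_sample(pmin(pmax(raw, 0), 4095))
}

# Resting recording: baseline plus sensor noise, in AD counts.
generate_resting_sample <- function(profile, n = 30L) {
  u <- 1 + sensor_noise(n, profile$noise_sd, profile$noise_rho)
  raw <- round(u * profile$baseline)
  pmin(pmax(raw, 0), 4095)
}

#' Generate a labeled synthetic dataset
#'
#' Emulates a data-collection campaign: for each subject and round, a resting
#' recording is generated and its per-channel means become the subject's
#' resting reference; then `reps_per_action` samples of each of the four
#' actions are generated. Each action sample is captured through the
#' pre-detection gate exactly as deployment captures windows (the action is
#' embedded in rest and the first gate-accepted sliding window is kept), so
#' the training distribution matches what the streaming detector forwards to
#' the classifier. Subject baselines are drawn uniformly from 800--1600 AD
#' counts. Fully reproducible under `seed`.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param reps_per_action Repetitions of each action per subject and round
#'   (default 50).
#' @param n_rounds Rounds per subject (default 1).
#' @param noise_sd Sensor noise in ratio units (default 0.01).
#' @param config The [detection_config()] used to capture the samples.
#' @param seed Integer seed.
#' @return A list with `samples` (list of 3 x 30 matrices), `labels`,
#'   `subject`, `round` (parallel vectors) and `references` (data.frame
#'   `subject,round,ref1,ref2,ref3`), plus the subject `profiles`.
#' @export
generate_dataset <- function(n_subjects = 5L, reps_per_action = 50L,
                             n_rounds = 1L, noise_sd = 0.01,
                             config = detection_config(), seed = 1L) {
  if (n_subjects < 1L || reps_per_action < 1L || n_rounds < 1L)
    stop_input("counts must be positive")
  with_seed(seed, {
    profiles <- lapply(seq_len(n_subjects), function(s)
      subject_profile(baseline = stats::runif(3, 800, 1600),
                      amp_scale = stats::runif(1, 0.9, 1.1),
                      noise_sd = noise_sd))
    samples <- list(); labels <- integer(0)
    subject <- integer(0); round_ <- integer(0)
    refs <- NULL
    for (s in seq_len(n_subjects)) {
      for (r in seq_len(n_rounds)) {
        resting <- generate_resting_sample(profiles[[s]])
        ref <- compute_reference(resting)
        refs <- rbind(refs, data.frame(subject = s, round = r,
                                       ref1 = ref[1], ref2 = ref[2],
                                       ref3 = ref[3]))
        for (lab in 1:4) {
          for (rep in seq_len(reps_per_action)) {
            samples[[length(samples) + 1L]] <-
              capture_action_sample(lab, profiles[[s]], config)
            labels <- c(labels, lab)
            subject <- c(subject, s)
            round_ <- c(round_, r)
          }
        }
      }
    }
    list(samples = samples, labels = labels, subject = subject,
         round = round_, references = refs, profiles = profiles)
  })
}

#' Generate a continuous synthetic session stream
#'
#' Concatenates scheduled segments into one 15 Hz three-channel AD stream
#' with ground truth: `rest` segments hold the current posture level,
#' `action` segments superimpose a jittered action template, and `switch`
#' segments ramp the posture linearly to a new level (emulating the slope
#' produced by switching between actions with different initial postures).
#' Schedule entries are lists: `list(type = "rest", n = 45)`,
#' `list(type = "action", label = 2)`,
#' `list(type = "switch", delta = c(.15, .18, .2), n = 60)`.
#'
#' @param profile A [subject_profile()].
#' @param schedule Non-empty list of segment entries.
#' @param seed Integer seed.
#' @return A list with `stream` (data.frame `t,ch1,ch2,ch3`, `t` in sample
#'   indices) and `truth` (data.frame `onset,label`, onset = stream index of
#'   the first sample of each action).
#' @export
generate_session <- function(profile, schedule, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  if (length(schedule) == 0L) stop_input("schedule must be non-empty")
  with_seed(seed, {
    level <- c(0, 0, 0)
    cols <- NULL
    truth <- data.frame(onset = integer(0), label = integer(0))
    idx <- 0L
    for (seg in schedule) {
      if (seg$type == "rest") {
        n <- seg$n
        cols <- cbind(cols, matrix(1 + level, 3, n))
        idx <- idx + n
      } else if (seg$type == "action") {
        dev <- jittered_deviation(seg$label, profile)
        truth <- rbind(truth, data.frame(onset = idx + 1L,
                                         label = as.integer(seg$label)))
        cols <- cbind(cols, 1 + level + dev)
        idx <- idx + 30L
      } else if (seg$type == "switch") {
        n <- seg$n
        delta <- as.numeric(seg$delta)
        ramp <- sapply(seq_len(n), function(k) level + delta * k / n)
        cols <- cbind(cols, 1 + ramp)
        level <- level + delta
        idx <- idx + n
      } else stop_input("unknown schedule entry type: ", seg$type)
    }
    # one continuous sensor-noise stream so segment joins stay seamless
    cols <- cols + sensor_noise(ncol(cols), profile$noise_sd, profile$noise_rho)
    raw <- round(cols * profile$baseline)
    raw <- pmin(pmax(raw, 0), 4095)
    list(stream = data.frame(t = seq_len(ncol(raw)), ch1 = raw[1, ],
                             ch2 = raw[2, ], ch3 = raw[3, ]),
         truth = truth)
  })
}

#' Generate a hysteretic calibration sweep pair
#'
#' Samples the given ground-truth loading and unloading force curves over a
#' monotone AD grid, adding Gaussian noise in gf, emulating a calibration rig
#' run where pressure is gradually increased and then gradually decreased.
#'
#' @param true_up Function AD -> force (gf) for the loading branch.
#' @param true_down Function AD -> force (gf) for the unloading branch.
#' @param ad_range Length-2 AD range covered by both curves.
#' @param n_points Points per sweep (default 300).
#' @param noise_gf Gaussian noise standard deviation in gf (default 0).
#' @param seed Integer seed.
#' @return List with elements `up` and `down`, both [calibration_sweep()].
#' @export
generate_calibration_sweep <- function(true_up, true_down,
                                       ad_range = c(200, 3800),
                                       n_points = 300L, noise_gf = 0,
                                       seed = 1L) {
  with_seed(seed, {
    ad_up <- seq(ad_range[1], ad_range[2], length.out = n_points)
    ad_dn <- rev(ad_up)
    f_up <- pmax(true_up(ad_up) + stats::rnorm(n_points, 0, noise_gf), 0)
    f_dn <- pmax(true_down(ad_dn) + stats::rnorm(n_points, 0, noise_gf), 0)
    list(up = calibration_sweep(ad_up, f_up, "loading"),
         down = calibration_sweep(ad_dn, f_dn, "unloading"))
  })
}
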