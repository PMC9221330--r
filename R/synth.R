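# Synthetic cohort generator. Every downstream stage is testable against this
# module's ground truth: R-peak times, per-behavior parameter values, and the
# monotone difficulty->physiology mappings (heart rate up / RR down, slow HRV
# power down, LF/HF down, respiration rate up, skin conductance up, EMG
# activation down as subjective difficulty rises).

#' Behavior profile: the generator-side causes of the observed trends
#'
#' @param behavior one of [behavior_labels()].
#' @param difficulty target subjective rating, 1-10.
#' @param mean_rr_ms mean inter-beat interval (400-1500 ms).
#' @param rr_sd_ms white beat-to-beat jitter SD.
#' @param ulf_amp_ms,lf_amp_ms,hf_amp_ms amplitudes (ms) of the slow
#'   (<0.003 Hz), 0.04-0.15 Hz and respiration-coupled RR modulators.
#' @param resp_rate_hz breathing frequency (0.1-1.0 Hz).
#' @param scl_level_uS tonic skin conductance level, microsiemens.
#' @param scr_rate_per_min Poisson rate of phasic skin-conductance responses.
#' @param emg_activation muscle activation in \[0,1\] scaling EMG amplitude.
#' @param skt_base_C baseline skin temperature, Celsius.
#' @return An object of class `pf_profile`.
#' @export
behavior_profile <- function(behavior, difficulty,
                             mean_rr_ms, rr_sd_ms = 3,
                             ulf_amp_ms = 15, lf_amp_ms = 12, hf_amp_ms = 10,
                             resp_rate_hz = 0.3, scl_level_uS = 5,
                             scr_rate_per_min = 4, emg_activation = 0.5,
                             skt_base_C = 33) {
  behavior <- match.arg(behavior, behavior_labels())
  stopifnot(mean_rr_ms >= 400, mean_rr_ms <= 1500,
            resp_rate_hz >= 0.1, resp_rate_hz <= 1.0,
            emg_activation >= 0, emg_activation <= 1)
  structure(list(behavior = behavior, difficulty = difficulty,
                 mean_rr_ms = mean_rr_ms, rr_sd_ms = rr_sd_ms,
                 ulf_amp_ms = ulf_amp_ms, lf_amp_ms = lf_amp_ms,
                 hf_amp_ms = hf_amp_ms, resp_rate_hz = resp_rate_hz,
                 scl_level_uS = scl_level_uS,
                 scr_rate_per_min = scr_rate_per_min,
                 emg_activation = emg_activation, skt_base_C = skt_base_C),
            class = "pf_profile")
}

#' Map a subjective difficulty rating to a behavior profile
#'
#' Linear (or log-linear) parameter curves over difficulty `d` in \[1,10\]:
#' RR interval, slow/LF RR modulation and EMG activation decrease with `d`;
#' respiration rate, skin conductance level, response rate and the HF RR
#' modulation increase. Magnitudes are design choices (detectable but
#' physiologic); see the methods vignette.
#'
#' @param behavior one of [behavior_labels()].
#' @param d difficulty rating (1-10).
#' @return a [behavior_profile()].
#' @export
profile_from_difficulty <- function(behavior, d) {
  behavior_profile(
    behavior, difficulty = d,
    mean_rr_ms = 1000 - 40 * d,
    rr_sd_ms = 3,
    ulf_amp_ms = 40 * exp(-0.25 * d),
    lf_amp_ms = 22 - 1.4 * d,
    hf_amp_ms = 6 + 0.9 * d,
    resp_rate_hz = 0.15 + 0.022 * d,
    scl_level_uS = 2 + 0.8 * d,
    scr_rate_per_min = 2 + 0.5 * d,
    emg_activation = min(1, max(0.05, 0.85 - 0.06 * d)),
    skt_base_C = 33.5 - 0.05 * d)
}

#' Default per-behavior profiles
#'
#' One profile per behavior whose difficulty equals the packaged table's
#' per-behavior mean rating (takeoff 3.43, level flight 3.50, turn-and-hover
#' 5.14, roll 3.36, somersault 7.36, stall 7.29).
#'
#' @return named list of six [behavior_profile()]s in canonical label order.
#' @export
default_profiles <- function() {
  tab <- load_difficulty_fixture()
  means <- round(colMeans(tab), 2)
  profs <- lapply(behavior_labels(), function(b) {
    profile_from_difficulty(b, means[[b]])
  })
  names(profs) <- behavior_labels()
  profs
}

#' EMG sensor noise floor (RMS, raw units) used by the simulator
#' @return scalar constant.
#' @export
emg_noise_floor <- function() 0.02

# RR-interval value (ms) at time t (s) for a profile with fixed phases.
rr_at <- function(profile, t, phases) {
  profile$mean_rr_ms +
    profile$ulf_amp_ms * (0.7 * sin(2 * pi * 0.0015 * t + phases[1]) +
                          0.7 * sin(2 * pi * 0.0025 * t + phases[2])) +
    profile$lf_amp_ms * sin(2 * pi * 0.095 * t + phases[3]) +
    profile$hf_amp_ms * sin(2 * pi * profile$resp_rate_hz * t + phases[4])
}

#' Simulate an ECG channel
#'
#' Quasi-periodic PQRST waveform built from Gaussian bumps, with inter-beat
#' intervals drawn from a stationary process: mean `mean_rr_ms`, white SD
#' `rr_sd_ms`, plus band-structured modulation (two slow tones below 0.003 Hz,
#' one 0.095 Hz tone, one respiration-coupled tone) so spectral HRV features
#' have known ground truth. The true R-peak times are attached as
#' `attr(x, "r_peak_times_s")`.
#'
#' @param profile a [behavior_profile()].
#' @param duration_s segment length, seconds.
#' @param rate_hz sampling rate (default native 512 Hz).
#' @param noise_sd additive measurement noise SD (raw units).
#' @param subject_id,start_time passed to [channel_recording()].
#' @return a `pf_channel` with ground-truth attribute.
#' @export
simulate_ecg <- function(profile, duration_s, rate_hz = 512, noise_sd = 0.01,
                         subject_id = "S1", start_time = 0) {
  stopifnot(duration_s > 0)
  phases <- runif(4, 0, 2 * pi)
  beats <- numeric(0)
  t <- runif(1, 0, 0.5)
  while (t < duration_s) {
    beats <- c(beats, t)
    rr <- rr_at(profile, t, phases) + rnorm(1, 0, profile$rr_sd_ms)
    rr <- max(300, min(2000, rr))
    t <- t + rr / 1000
  }
  n <- round(duration_s * rate_hz)
  x <- rnorm(n, 0, noise_sd)
  # PQRST Gaussian bumps: (offset ms, width ms, amplitude)
  bumps <- list(c(-180, 35, 0.12), c(-25, 10, -0.12), c(0, 14, 1.1),
                c(25, 10, -0.18), c(250, 60, 0.25))
  half <- round(0.45 * rate_hz)
  for (tb in beats) {
    ic <- round(tb * rate_hz) + 1
    idx <- max(1, ic - half):min(n, ic + half)
    tt <- (idx - 1) / rate_hz - tb
    for (b in bumps) {
      x[idx] <- x[idx] + b[3] * exp(-0.5 * ((tt - b[1] / 1000) / (b[2] / 1000))^2)
    }
  }
  ch <- channel_recording(1.8 + x, rate_hz, "ECG", subject_id, start_time)
  attr(ch, "r_peak_times_s") <- beats + start_time
  ch
}

#' Simulate the remaining channels
#'
#' GSR: tonic level plus Poisson-arriving phasic responses with ~0.7 s rise and
#' ~3 s exponential decay. EMG: zero-mean white noise with RMS
#' `noise_floor + activation * gain`. RESP: sinusoid at `resp_rate_hz` with
#' slow amplitude jitter. SKT: baseline plus a bounded random walk slower than
#' 0.1 degC/s.
#'
#' @inheritParams simulate_ecg
#' @param noise_sd additive measurement noise SD.
#' @return a `pf_channel`.
#' @export
simulate_gsr <- function(profile, duration_s, rate_hz = 64, noise_sd = 0.02,
                         subject_id = "S1", start_time = 0) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- rep(profile$scl_level_uS, n)
  n_scr <- rpois(1, profile$scr_rate_per_min * duration_s / 60)
  if (n_scr > 0) {
    onsets <- sort(runif(n_scr, 0, duration_s))
    amps <- rexp(n_scr, rate = 1 / 0.3)
    for (k in seq_len(n_scr)) {
      d <- t - onsets[k]
      keep <- d >= 0 & d < 20
      shape <- exp(-d[keep] / 3) - exp(-d[keep] / 0.7)
      x[keep] <- x[keep] + amps[k] * shape / 0.6548  # peak-normalized
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  channel_recording(x, rate_hz, "GSR", subject_id, start_time)
}

#' @rdname simulate_gsr
#' @export
simulate_emg <- function(profile, duration_s, rate_hz = 1024,
                         subject_id = "S1", start_time = 0) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * rate_hz)
  amp <- emg_noise_floor() + profile$emg_activation * 0.5
  channel_recording(rnorm(n, 0, amp), rate_hz, "EMG", subject_id, start_time)
}

#' @rdname simulate_gsr
#' @export
simulate_resp <- function(profile, duration_s, rate_hz = 64, noise_sd = 0.01,
                          subject_id = "S1", start_time = 0) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  ph <- runif(2, 0, 2 * pi)
  amp <- 1 + 0.1 * sin(2 * pi * 0.01 * t + ph[2])
  x <- 5 + amp * sin(2 * pi * profile$resp_rate_hz * t + ph[1])
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  channel_recording(x, rate_hz, "RESP", subject_id, start_time)
}

#' @rdname simulate_gsr
#' @export
simulate_skt <- function(profile, duration_s, rate_hz = 32, noise_sd = 0.005,
                         subject_id = "S1", start_time = 0) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * rate_hz)
  steps <- rnorm(n, 0, 0.001)
  steps <- pmax(-0.1 / rate_hz, pmin(0.1 / rate_hz, steps))  # < 0.1 degC/s
  walk <- cumsum(steps)
  walk <- pmax(-0.5, pmin(0.5, walk))
  x <- profile$skt_base_C + walk
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  channel_recording(x, rate_hz, "SKT", subject_id, start_time)
}

#' Simulation plan for a cohort
#'
#' @param n_subjects number of subjects.
#' @param schedule data.frame with columns `behavior`, `duration_s`; default is
#'   the six behaviors in canonical order, 240 s each except stall (180 s),
#'   matching the protocol's ~4 min maneuvers / ~3 min stall.
#' @param profiles named list of per-behavior profiles used when
#'   `difficulty_table` is NULL; default [default_profiles()].
#' @param difficulty_table optional `pf_difficulty` matrix; when given, each
#'   subject's per-behavior parameters are driven by that subject's own rating
#'   via [profile_from_difficulty()] (individual-differences model). Default:
#'   the packaged table when `n_subjects` matches its rows.
#' @param jitter_sdlog SD of the per-subject, per-parameter multiplicative
#'   log-normal jitter (one factor per subject x parameter, so within-subject
#'   monotonicity is preserved).
#' @param seed RNG seed.
#' @param window_s feature window length used to validate segment durations
#'   (each segment must be at least `3 * window_s`).
#' @param artifact_rate expected number of injected spike artifacts per minute
#'   per channel (exercises the ectopic-handling path; 0 disables).
#' @return An object of class `pf_sim_plan`.
#' @export
sim_plan <- function(n_subjects = 14, schedule = NULL, profiles = NULL,
                     difficulty_table = NULL, jitter_sdlog = 0.08, seed = 1L,
                     window_s = 30, artifact_rate = 0) {
  if (is.null(schedule)) {
    schedule <- data.frame(
      behavior = behavior_labels(),
      duration_s = c(240, 240, 240, 240, 240, 180))
  }
  if (any(schedule$duration_s < 3 * window_s)) stop("segment too short")
  behavior_code(schedule$behavior)
  if (is.null(profiles)) profiles <- default_profiles()
  if (is.null(difficulty_table) && n_subjects == 14) {
    difficulty_table <- load_difficulty_fixture()
  }
  structure(list(n_subjects = as.integer(n_subjects), schedule = schedule,
                 profiles = profiles, difficulty_table = difficulty_table,
                 jitter_sdlog = jitter_sdlog, seed = as.integer(seed),
                 artifact_rate = artifact_rate),
            class = "pf_sim_plan")
}

# One multiplicative log-normal factor per jitterable parameter; clamps keep
# every parameter inside its physiologic/validity range.
jitter_profile <- function(profile, factors) {
  p <- profile
  p$mean_rr_ms <- min(1500, max(400, p$mean_rr_ms * factors[["mean_rr_ms"]]))
  p$ulf_amp_ms <- p$ulf_amp_ms * factors[["ulf_amp_ms"]]
  p$lf_amp_ms <- p$lf_amp_ms * factors[["lf_amp_ms"]]
  p$hf_amp_ms <- p$hf_amp_ms * factors[["hf_amp_ms"]]
  p$resp_rate_hz <- min(0.39, max(0.16, p$resp_rate_hz * factors[["resp_rate_hz"]]))
  p$scl_level_uS <- p$scl_level_uS * factors[["scl_level_uS"]]
  p$emg_activation <- min(1, p$emg_activation * factors[["emg_activation"]])
  p$skt_base_C <- p$skt_base_C * factors[["skt_base_C"]]
  p
}

jitterable_params <- c("mean_rr_ms", "ulf_amp_ms", "lf_amp_ms", "hf_amp_ms",
                       "resp_rate_hz", "scl_level_uS", "emg_activation",
                       "skt_base_C")

# Correction turning a piecewise-constant per-segment level into a smooth
# trajectory: returns (ramped - stepped) sampled on the channel grid.
smooth_level_steps <- function(levels, durations, rate, ramp_s = 10) {
  ends <- cumsum(durations)
  n <- round(ends[length(ends)] * rate)
  t <- (seq_len(n) - 1) / rate
  seg <- findInterval(t, c(0, ends), rightmost.closed = TRUE)
  stepped <- levels[pmin(seg, length(levels))]
  k <- length(levels)
  inner <- head(ends, -1)
  knots_t <- c(0, as.vector(rbind(inner - ramp_s / 2, inner + ramp_s / 2)),
               ends[k])
  knots_v <- c(levels[1],
               as.vector(rbind(levels[-k], levels[-1])),
               levels[k])
  ramped <- approx(knots_t, knots_v, xout = t, rule = 2)$y
  ramped - stepped
}

# Inject multiplicative spike artifacts (x2-3) at Poisson-arriving samples.
inject_artifacts <- function(ch, rate_per_min) {
  if (rate_per_min <= 0) return(ch)
  n <- length(ch$samples)
  k <- rpois(1, rate_per_min * n / ch$rate / 60)
  if (k > 0) {
    idx <- sample(n, min(k, n))
    ch$samples[idx] <- ch$samples[idx] * runif(length(idx), 2, 3)
  }
  ch
}

#' Simulate one subject's labeled multi-channel recording
#'
#' @param plan a [sim_plan()].
#' @param subject_index 1-based subject index within the plan.
#' @return a `pf_recording_set` with ground-truth attributes
#'   (`r_peak_times_s`, `profiles`).
#' @keywords internal
simulate_subject <- function(plan, subject_index) {
  sid <- as.character(subject_index)
  factors <- setNames(exp(rnorm(length(jitterable_params), 0,
                                plan$jitter_sdlog)), jitterable_params)
  profile_for <- function(behavior) {
    base <- if (!is.null(plan$difficulty_table)) {
      profile_from_difficulty(behavior,
                              plan$difficulty_table[subject_index, behavior])
    } else {
      plan$profiles[[behavior]]
    }
    jitter_profile(base, factors)
  }
  t0 <- 0
  parts <- list()
  truth_peaks <- numeric(0)
  used_profiles <- list()
  for (i in seq_len(nrow(plan$schedule))) {
    beh <- plan$schedule$behavior[i]
    dur <- plan$schedule$duration_s[i]
    prof <- profile_for(beh)
    used_profiles[[beh]] <- prof
    seg <- list(
      ECG = simulate_ecg(prof, dur, subject_id = sid, start_time = t0),
      GSR = simulate_gsr(prof, dur, subject_id = sid, start_time = t0),
      EMG = simulate_emg(prof, dur, subject_id = sid, start_time = t0),
      RESP = simulate_resp(prof, dur, subject_id = sid, start_time = t0),
      SKT = simulate_skt(prof, dur, subject_id = sid, start_time = t0))
    truth_peaks <- c(truth_peaks, attr(seg$ECG, "r_peak_times_s"))
    parts[[i]] <- seg
    t0 <- t0 + dur
  }
  channels <- lapply(channel_kinds(), function(kind) {
    ch <- channel_recording(
      unlist(lapply(parts, function(p) p[[kind]]$samples)),
      rate = parts[[1]][[kind]]$rate, kind = kind, subject_id = sid,
      start_time = 0)
    inject_artifacts(ch, plan$artifact_rate)
  })
  names(channels) <- channel_kinds()
  # Tonic skin conductance drifts rather than steps between maneuvers: replace
  # the piecewise-constant segment level with a 10 s linear ramp at boundaries.
  scl <- vapply(plan$schedule$behavior,
                function(b) used_profiles[[b]]$scl_level_uS, numeric(1))
  channels$GSR$samples <- channels$GSR$samples +
    smooth_level_steps(scl, plan$schedule$duration_s,
                       channels$GSR$rate, ramp_s = 10)
  ends <- cumsum(plan$schedule$duration_s)
  track <- label_track(c(0, head(ends, -1)), ends, plan$schedule$behavior)
  set <- labeled_recording_set(channels, track, subject_id = sid)
  attr(set, "r_peak_times_s") <- truth_peaks
  attr(set, "profiles") <- used_profiles
  set
}

#' Simulate a full cohort
#'
#' Fully reproducible from `plan$seed`: two calls with the same plan return
#' bit-identical recordings.
#'
#' @param plan a [sim_plan()].
#' @return list of `pf_recording_set`, one per subject.
#' @export
simulate_cohort <- function(plan) {
  stopifnot(inherits(plan, "pf_sim_plan"))
  if (plan$n_subjects == 0) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(plan$seed)
  sets <- lapply(seq_len(plan$n_subjects), function(i) simulate_subject(plan, i))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  sets
}
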