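#' Cohort generation settings
#'
#' Bundles the study-design parameters of a two-phase smoking-cessation
#' sensing study: a pre-quit phase in which every cigarette is logged
#' (`smoke` events) and a post-quit phase in which lapses and craving
#' reports (level 1--5) are logged, while the phone records accelerometer,
#' gyroscope and magnetometer triaxial streams plus ambient light and a
#' time-of-day channel at a fixed cadence.
#'
#' Defaults mirror the study design the generator emulates: 17 participants,
#' a two-week pre-quit phase and a three-month post-quit phase, five sensor
#' rows per minute (so 25 rows span one 5-minute analysis window), sparse
#' lapses (about one per week), craving reports a little more than once a
#' day, and 3/17 of participants reporting nothing after quitting.
#'
#' @param n_participants number of participants in the cohort.
#' @param phase1_days,phase2_days duration of the pre-quit and post-quit
#'   phases, in days (each at least 1).
#' @param samples_per_minute sensor rows recorded per minute.
#' @param smokes_per_day expected smoking events per day in Phase 1.
#' @param lapse_rate expected lapses per week in Phase 2.
#' @param craving_rate expected craving reports per day in Phase 2; at
#'   least one report per day is always emitted, matching the reporting
#'   protocol.
#' @param craving_level_probs length-5 probability vector for craving
#'   levels 1 (very low) to 5 (very high); must sum to 1.
#' @param motif_amplitude strength of the pre-event movement motif added to
#'   the inertial channels (arbitrary signal units; 0 disables the signal
#'   entirely while keeping the label structure).
#' @param subject_jitter log-scale standard deviation of the per-participant
#'   motif amplitude multiplier, plus a random per-participant motif phase;
#'   0 makes all participants share one identical motif.
#' @param missing_prob per-row probability that a sensor row is dropped
#'   (timestamp kept, channel values null); must be in `[0, 1)`.
#' @param frac_no_phase2 fraction of participants whose Phase 2 event log is
#'   empty (they stopped reporting after quitting).
#' @param seed master integer seed; all participant-level randomness is
#'   derived from it deterministically.
#'
#' @return An object of class `cohort_config`.
#' @seealso [motif_spec()], [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 17,
                          phase1_days = 14,
                          phase2_days = 90,
                          samples_per_minute = 5,
                          smokes_per_day = 10,
                          lapse_rate = 1,
                          craving_rate = 1.3,
                          craving_level_probs = c(0.15, 0.20, 0.25, 0.20, 0.20),
                          motif_amplitude = 1,
                          subject_jitter = 0.2,
                          missing_prob = 0.05,
                          frac_no_phase2 = 3 / 17,
                          seed = 1L) {
  if (!is_count(n_participants)) stopf("n_participants must be a positive integer")
  if (!is_count(phase1_days) || !is_count(phase2_days))
    stopf("phase durations must be whole numbers of days, at least 1")
  if (!is_count(samples_per_minute)) stopf("samples_per_minute must be >= 1")
  for (nm in c("smokes_per_day", "lapse_rate", "craving_rate", "motif_amplitude",
               "subject_jitter")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stopf("%s must be a non-negative number", nm)
  }
  if (length(craving_level_probs) != 5 || any(craving_level_probs < 0) ||
      abs(sum(craving_level_probs) - 1) > 1e-9)
    stopf("craving_level_probs must be 5 non-negative values summing to 1")
  if (!is_prob(missing_prob) || missing_prob >= 1)
    stopf("missing_prob must be in [0, 1)")
  if (!is_prob(frac_no_phase2)) stopf("frac_no_phase2 must be in [0, 1]")
  structure(list(
    n_participants = as.integer(n_participants),
    phase1_days = as.integer(phase1_days),
    phase2_days = as.integer(phase2_days),
    samples_per_minute = as.integer(samples_per_minute),
    smokes_per_day = smokes_per_day,
    lapse_rate = lapse_rate,
    craving_rate = craving_rate,
    craving_level_probs = craving_level_probs,
    motif_amplitude = motif_amplitude,
    subject_jitter = subject_jitter,
    missing_prob = missing_prob,
    frac_no_phase2 = frac_no_phase2,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Pre-event movement motif specification
#'
#' The generator plants a cohort-shared movement signature on the inertial
#' channels in the minutes leading up to each logged event, operationalising
#' the premise that smoking-related behaviour is preceded by characteristic
#' micro-movements. The motif is an additive sinusoidal burst (a proxy for a
#' repetitive hand-to-mouth cadence) plus an inflation of high-frequency
#' variance, both scaled by `motif_amplitude` from the cohort configuration
#' and by the per-participant jitter.
#'
#' @param pre_event_window minutes before an event's timestamp during which
#'   the motif is active; must be positive.
#' @param burst_period period of the sinusoidal burst, in seconds.
#' @param variance_gain multiplier (>= 1) on the high-frequency variance of
#'   the inertial channels inside the motif window.
#' @param channel_weights named involvement weights for the three inertial
#'   sensors (`acc`, `gyr`, `mag`).
#'
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(pre_event_window = 5,
                       burst_period = 3,
                       variance_gain = 3,
                       channel_weights = c(acc = 1, gyr = 1, mag = 0.6)) {
  if (!is.numeric(pre_event_window) || pre_event_window <= 0)
    stopf("pre_event_window must be > 0 minutes")
  if (!is.numeric(burst_period) || burst_period <= 0)
    stopf("burst_period must be > 0 seconds")
  if (!is.numeric(variance_gain) || variance_gain < 1)
    stopf("variance_gain must be >= 1")
  w <- channel_weights
  if (is.null(names(w)) || !all(c("acc", "gyr", "mag") %in% names(w)))
    stopf("channel_weights must name acc, gyr and mag")
  if (any(w < 0)) stopf("channel_weights must be non-negative")
  structure(list(
    pre_event_window = pre_event_window,
    burst_period = burst_period,
    variance_gain = variance_gain,
    channel_weights = w[c("acc", "gyr", "mag")]
  ), class = "motif_spec")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat(sprintf("  %d participants; Phase 1 %d d, Phase 2 %d d; %d rows/min\n",
              x$n_participants, x$phase1_days, x$phase2_days,
              x$samples_per_minute))
  cat(sprintf("  events: %.3g smokes/day, %.3g lapses/week, %.3g cravings/day\n",
              x$smokes_per_day, x$lapse_rate, x$craving_rate))
  cat(sprintf("  motif amplitude %.3g (jitter %.3g); missing prob %.3g; seed %d\n",
              x$motif_amplitude, x$subject_jitter, x$missing_prob, x$seed))
  invisible(x)
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf(
    "Pre-event motif: %.3g min window, %.3g s burst period, variance gain %.3g\n",
    x$pre_event_window, x$burst_period, x$variance_gain))
  invisible(x)
}
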