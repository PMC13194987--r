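COHORT_EPOCH <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")

# Stationary AR(1) noise with unit marginal variance.
ar1_noise <- function(n, phi = 0.8) {
  as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive"))
}

# Poisson event times within waking hours (07:00-23:00) of each day,
# rounded to whole seconds so logs survive text round-trips exactly.
waking_event_times <- function(start, days, per_day_counts) {
  out <- vector("list", days)
  for (d in seq_len(days)) {
    k <- per_day_counts[d]
    if (k > 0) {
      day0 <- as.numeric(start) + (d - 1) * 86400
      out[[d]] <- day0 + round(runif(k, 7 * 3600, 23 * 3600))
    }
  }
  secs <- sort(unlist(out))
  as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
}

generate_phase_stream <- function(start, days, spm) {
  n <- days * 1440L * spm
  dt <- 60 / spm
  times <- start + (seq_len(n) - 1) * dt
  secs_of_day <- as.numeric(times) %% 86400
  tod <- secs_of_day / 86400
  daylight <- pmax(0, sin(2 * pi * (tod - 0.25)))
  light <- (20 + 800 * daylight) * exp(rnorm(n, 0, 0.25))
  df <- data.frame(timestamp = times)
  for (col in c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                "mag_x", "mag_y", "mag_z"))
    df[[col]] <- ar1_noise(n)
  df$light <- light
  df$tod <- tod
  df$missing <- FALSE
  df
}

# Superimpose the pre-event motif on the inertial channels: a sinusoidal
# burst (hand-to-mouth cadence proxy) plus extra white noise inflating the
# high-frequency variance, active in [event - pre_event_window, event).
# Each event expresses the motif with its own random split of involvement
# across the three sensors (movements differ between occasions), so no
# single sensor observes every event at full strength and the combined
# 9-channel input carries strictly more evidence than any sensor alone.
add_motif <- function(df, start, events, motif, amplitude, amp_mult,
                      phase_shift, dt) {
  if (amplitude <= 0 || !length(events)) return(df)
  pre <- motif$pre_event_window * 60
  n <- nrow(df)
  axis_off <- c(0, 2 * pi / 3, 4 * pi / 3)
  sensors <- list(acc = c("acc_x", "acc_y", "acc_z"),
                  gyr = c("gyr_x", "gyr_y", "gyr_z"),
                  mag = c("mag_x", "mag_y", "mag_z"))
  noise_sd_unit <- sqrt(motif$variance_gain - 1)
  for (te in as.numeric(events)) {
    off <- te - as.numeric(start)
    i_lo <- max(1L, as.integer(ceiling((off - pre) / dt + 1 - 1e-9)))
    i_hi <- min(n, as.integer(floor((off - 1e-9) / dt) + 1))
    raw <- rgamma(3, shape = 0.7)
    involvement <- 3 * raw / sum(raw)
    names(involvement) <- names(sensors)
    if (i_hi < i_lo) next
    idx <- i_lo:i_hi
    tsec <- (idx - 1) * dt
    for (s in names(sensors)) {
      a <- amplitude * amp_mult * motif$channel_weights[[s]] * involvement[[s]]
      if (a <= 0) next
      for (ax in 1:3) {
        col <- sensors[[s]][ax]
        burst <- a * sin(2 * pi * tsec / motif$burst_period +
                           phase_shift + axis_off[ax])
        df[[col]][idx] <- df[[col]][idx] + burst +
          rnorm(length(idx), 0, a * noise_sd_unit)
      }
    }
  }
  df
}

#' Generate one participant's streams and event logs
#'
#' Simulates both study phases for a single participant: baseline inertial
#' channels as stationary AR(1) noise, a diurnal light channel, a
#' time-of-day channel (minutes since midnight scaled to `[0, 1)`), Poisson
#' event schedules within waking hours (07:00--23:00), the cohort-shared
#' pre-event motif with per-participant amplitude/phase jitter drawn once,
#' and independent per-row missingness. Fully deterministic for a fixed
#' `(config$seed, participant_id)` pair.
#'
#' @param config a [cohort_config()].
#' @param motif a [motif_spec()].
#' @param participant_id participant identifier, unique within a cohort.
#' @param empty_phase2 if `TRUE`, the Phase 2 event log is empty, emulating
#'   a participant who stopped reporting after quitting.
#' @return A `participant_bundle`: list with elements `participant_id`,
#'   `phase1`/`phase2` ([sensor_stream()]s), `events1`/`events2`
#'   ([event_log()]s), and the jitter draws `amp_mult`, `phase_shift`.
#' @export
generate_participant <- function(config, motif, participant_id,
                                 empty_phase2 = FALSE) {
  stopifnot(inherits(config, "cohort_config"), inherits(motif, "motif_spec"))
  pseed <- child_seed(config$seed, "participant", participant_id)
  spm <- config$samples_per_minute
  dt <- 60 / spm
  p1_start <- COHORT_EPOCH
  p2_start <- p1_start + (config$phase1_days + 5) * 86400

  bundle <- with_seed(pseed, {
    amp_mult <- exp(rnorm(1, 0, config$subject_jitter))
    phase_shift <- if (config$subject_jitter > 0) runif(1, 0, 2 * pi) else 0

    df1 <- generate_phase_stream(p1_start, config$phase1_days, spm)
    smoke_times <- waking_event_times(
      p1_start, config$phase1_days,
      rpois(config$phase1_days, config$smokes_per_day))
    df1 <- add_motif(df1, p1_start, smoke_times, motif,
                     config$motif_amplitude, amp_mult, phase_shift, dt)

    df2 <- generate_phase_stream(p2_start, config$phase2_days, spm)
    lapse_times <- waking_event_times(
      p2_start, config$phase2_days,
      rpois(config$phase2_days, config$lapse_rate / 7))
    craving_counts <- pmax(1L, rpois(config$phase2_days, config$craving_rate))
    craving_times <- waking_event_times(p2_start, config$phase2_days,
                                        craving_counts)
    levels <- sample.int(5, length(craving_times), replace = TRUE,
                         prob = config$craving_level_probs)
    p2_events <- c(as.numeric(lapse_times), as.numeric(craving_times))
    df2 <- add_motif(df2, p2_start,
                     as.POSIXct(p2_events, origin = "1970-01-01", tz = "UTC"),
                     motif, config$motif_amplitude, amp_mult, phase_shift, dt)

    ev1 <- data.frame(timestamp = smoke_times,
                      kind = rep("smoke", length(smoke_times)),
                      level = rep(NA_integer_, length(smoke_times)))
    ev2 <- data.frame(
      timestamp = as.POSIXct(p2_events, origin = "1970-01-01", tz = "UTC"),
      kind = c(rep("lapse", length(lapse_times)),
               rep("craving", length(craving_times))),
      level = c(rep(NA_integer_, length(lapse_times)), levels))
    ev2 <- ev2[order(ev2$timestamp), , drop = FALSE]
    if (empty_phase2) ev2 <- ev2[0, , drop = FALSE]
    list(df1 = df1, df2 = df2, ev1 = ev1, ev2 = ev2,
         amp_mult = amp_mult, phase_shift = phase_shift)
  })

  s1 <- sensor_stream(bundle$df1, participant_id, 1L)
  s2 <- sensor_stream(bundle$df2, participant_id, 2L)
  if (config$missing_prob > 0) {
    s1 <- inject_missingness(s1, config$missing_prob,
                             child_seed(pseed, "miss", 1))
    s2 <- inject_missingness(s2, config$missing_prob,
                             child_seed(pseed, "miss", 2))
  }
  structure(list(participant_id = as.character(participant_id),
                 phase1 = s1, phase2 = s2,
                 events1 = event_log(bundle$ev1, participant_id, 1L),
                 events2 = event_log(bundle$ev2, participant_id, 2L),
                 amp_mult = bundle$amp_mult,
                 phase_shift = bundle$phase_shift),
            class = "participant_bundle")
}

#' Generate a synthetic cohort
#'
#' Participants share the cohort motif (so cross-subject generalisation is
#' learnable) but differ in their jittered motif amplitude/phase and event
#' schedules. A configurable fraction of participants (default 3/17) report
#' no Phase 2 events at all.
#'
#' @inheritParams generate_participant
#' @return A `sensor_cohort`: list with `participants` (list of
#'   `participant_bundle`s), `config` and `motif`.
#' @export
generate_cohort <- function(config, motif = motif_spec()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  k_empty <- round(config$frac_no_phase2 * n)
  empty_ids <- if (k_empty > 0) {
    with_seed(child_seed(config$seed, "no-phase2"), sample(ids, k_empty))
  } else character()
  participants <- lapply(ids, function(id) {
    generate_participant(config, motif, id, empty_phase2 = id %in% empty_ids)
  })
  names(participants) <- ids
  structure(list(participants = participants, config = config, motif = motif),
            class = "sensor_cohort")
}

#' @export
print.sensor_cohort <- function(x, ...) {
  n2 <- sum(vapply(x$participants, function(p) nrow(p$events2) > 0, TRUE))
  cat(sprintf("Synthetic cohort: %d participants (%d with Phase 2 reports)\n",
              length(x$participants), n2))
  invisible(x)
}

#' @export
print.participant_bundle <- function(x, ...) {
  cat(sprintf(
    "Participant %s: %d Phase 1 rows / %d smoke events; %d Phase 2 rows / %d reports\n",
    x$participant_id, nrow(x$phase1), nrow(x$events1), nrow(x$phase2),
    nrow(x$events2)))
  invisible(x)
}

#' Flag rows of a stream as missing
#'
#' Each row is independently flagged missing with probability
#' `missing_prob`; flagged rows keep their timestamp but have their channel
#' values nulled, exercising the downstream majority-missing window filter.
#'
#' @param stream a [sensor_stream()].
#' @param missing_prob per-row dropout probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The stream with dropout applied.
#' @export
inject_missingness <- function(stream, missing_prob, seed = 1L) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is_prob(missing_prob) || missing_prob >= 1)
    stopf("missing_prob must be in [0, 1)")
  if (missing_prob == 0 || nrow(stream) == 0) return(stream)
  drop <- with_seed(seed, runif(nrow(stream)) < missing_prob)
  df <- as.data.frame(stream)
  df[drop, CHANNEL_COLUMNS] <- NA_real_
  df$missing <- df$missing | drop
  sensor_stream(df, attr(stream, "participant_id"), attr(stream, "phase"))
}
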