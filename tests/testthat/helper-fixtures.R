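# Small generated fixtures, cached per test run so several test files can
# share one realisation without regenerating it.
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# One participant with a clearly detectable pre-event motif.
small_participant <- function(amplitude = 2, seed = 11L, phase1_days = 2L,
                              phase2_days = 2L, smokes_per_day = 20,
                              jitter = 0.1, missing_prob = 0.05) {
  cfg <- cohort_config(n_participants = 1, phase1_days = phase1_days,
                       phase2_days = phase2_days,
                       smokes_per_day = smokes_per_day,
                       lapse_rate = 7, craving_rate = 3,
                       motif_amplitude = amplitude, subject_jitter = jitter,
                       missing_prob = missing_prob, seed = seed)
  generate_participant(cfg, motif_spec(), "P01")
}

# A bare-metal stream with constant channels, for pipeline unit tests.
flat_stream <- function(n_rows, participant_id = "T01", phase = 1L,
                        value = 0) {
  ts <- as.POSIXct("2026-03-01 00:00:00", tz = "UTC") + (seq_len(n_rows) - 1) * 12
  df <- data.frame(timestamp = ts)
  for (col in c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                "mag_x", "mag_y", "mag_z", "light"))
    df[[col]] <- rep(value, n_rows)
  df$tod <- (as.numeric(ts) %% 86400) / 86400
  df$missing <- rep(FALSE, n_rows)
  sensor_stream(df, participant_id, phase)
}

events_at <- function(times, kind, levels = NULL, participant_id = "T01",
                      phase = 1L) {
  if (is.null(levels)) levels <- rep(NA_integer_, length(times))
  event_log(data.frame(timestamp = times,
                       kind = as.character(kind),
                       level = levels),
            participant_id, phase)
}

# quick-training model settings used by evaluation tests
quick_model <- function(epochs = 20L, ...) {
  c(list(n_filters = 16L, kernel_span = 7L, hidden_size = 8L,
         dense_sizes = c(16L, 8L, 1L), epochs = as.integer(epochs),
         patience = 6L, batch_size = 32L), list(...))
}
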