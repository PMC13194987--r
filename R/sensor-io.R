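#' @importFrom data.table fread fwrite as.data.table
NULL

format_iso <- function(ts) format(ts, TIME_FORMAT, tz = "UTC")

parse_iso <- function(x) as.POSIXct(x, format = TIME_FORMAT, tz = "UTC")

#' Construct a validated sensor stream
#'
#' A sensor stream is one participant-phase's ordered sequence of sensor
#' rows: a timestamp, triaxial accelerometer / gyroscope / magnetometer
#' readings, ambient light, a time-of-day channel scaled to `[0, 1)`, and a
#' missingness flag. Rows flagged missing keep their timestamp but carry
#' null channel values.
#'
#' @param data data.frame with columns
#'   `timestamp, acc_x..acc_z, gyr_x..gyr_z, mag_x..mag_z, light, tod, missing`.
#' @param participant_id participant identifier.
#' @param phase study phase, 1 (pre-quit) or 2 (post-quit).
#' @return A `sensor_stream`: a data.frame with participant/phase attributes.
#' @export
sensor_stream <- function(data, participant_id, phase) {
  phase <- as.integer(phase)
  if (!phase %in% c(1L, 2L)) stopf("phase must be 1 or 2")
  data <- as.data.frame(data)
  miss_cols <- setdiff(STREAM_COLUMNS, names(data))
  if (length(miss_cols))
    stopf("stream is missing columns: %s", paste(miss_cols, collapse = ", "))
  data <- data[STREAM_COLUMNS]
  if (!inherits(data$timestamp, "POSIXct"))
    stopf("timestamp must be POSIXct")
  n <- nrow(data)
  if (n > 1) {
    dt <- diff(as.numeric(data$timestamp))
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stopf("timestamps must be strictly increasing (violated at row %d)", bad)
    }
  }
  data$missing <- as.logical(data$missing)
  miss <- data$missing
  vals <- as.matrix(data[CHANNEL_COLUMNS])
  if (n > 0) {
    if (any(miss & rowSums(!is.na(vals)) > 0))
      stopf("rows flagged missing must have null channel values")
    if (any(!miss & rowSums(is.na(vals)) > 0))
      stopf("rows not flagged missing must have complete channel values")
    tod <- data$tod[!miss]
    if (length(tod) && (any(tod < 0) || any(tod > 1)))
      stopf("tod channel must lie in [0, 1]")
  }
  structure(data,
            participant_id = as.character(participant_id),
            phase = phase,
            class = c("sensor_stream", "data.frame"))
}

#' Construct a validated event log
#'
#' Behavioural events logged by a participant: `smoke` events in Phase 1;
#' `lapse` events and `craving` reports (with a level from 1, very low, to
#' 5, very high) in Phase 2. A level is present if and only if the event is
#' a craving report.
#'
#' @param data data.frame with columns `timestamp, kind, level`.
#' @inheritParams sensor_stream
#' @return An `event_log`: a data.frame with participant/phase attributes.
#' @export
event_log <- function(data, participant_id, phase) {
  phase <- as.integer(phase)
  if (!phase %in% c(1L, 2L)) stopf("phase must be 1 or 2")
  data <- as.data.frame(data)
  need <- c("timestamp", "kind", "level")
  if (!all(need %in% names(data)))
    stopf("event log needs columns: %s", paste(need, collapse = ", "))
  data <- data[need]
  if (nrow(data)) {
    if (!inherits(data$timestamp, "POSIXct")) stopf("timestamp must be POSIXct")
    if (is.unsorted(as.numeric(data$timestamp)))
      data <- data[order(data$timestamp), , drop = FALSE]
    data$kind <- as.character(data$kind)
    bad <- setdiff(unique(data$kind), EVENT_KINDS)
    if (length(bad)) stopf("unknown event kind: %s", paste(bad, collapse = ", "))
    if (phase == 1L && any(data$kind != "smoke"))
      stopf("Phase 1 logs may contain only smoke events")
    if (phase == 2L && any(data$kind == "smoke"))
      stopf("smoke events belong to Phase 1; Phase 2 uses lapse/craving")
    data$level <- suppressWarnings(as.integer(data$level))
    crav <- data$kind == "craving"
    if (any(crav & is.na(data$level)))
      stopf("craving events must carry a level")
    if (any(!crav & !is.na(data$level)))
      stopf("only craving events may carry a level")
    if (any(crav & !data$level %in% 1:5))
      stopf("craving level must be in 1..5")
  } else {
    data <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                       kind = character(), level = integer())
  }
  rownames(data) <- NULL
  structure(data,
            participant_id = as.character(participant_id),
            phase = phase,
            class = c("event_log", "data.frame"))
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("Sensor stream: participant %s, phase %d, %d rows (%d missing)\n",
              attr(x, "participant_id"), attr(x, "phase"), nrow(x),
              sum(x$missing)))
  if (nrow(x))
    cat(sprintf("  %s .. %s\n", format_iso(x$timestamp[1]),
                format_iso(x$timestamp[nrow(x)])))
  invisible(x)
}

#' @export
print.event_log <- function(x, ...) {
  tab <- table(factor(x$kind, levels = EVENT_KINDS))
  cat(sprintf("Event log: participant %s, phase %d, %d events (%s)\n",
              attr(x, "participant_id"), attr(x, "phase"), nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a sensor stream from its columnar text format
#'
#' Parses the package's CSV dialect (header
#' `timestamp,acc_x,...,light,tod,missing`, ISO-8601 timestamps, empty
#' channel fields for missing rows) and returns a validated
#' [sensor_stream()]. Malformed files produce a diagnostic error naming the
#' offending line.
#'
#' @param path path to a stream CSV file.
#' @inheritParams sensor_stream
#' @return A `sensor_stream`.
#' @export
read_stream <- function(path, participant_id, phase) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- fread(path, sep = ",", header = TRUE, colClasses = list(
    character = "timestamp"), showProgress = FALSE)
  miss_cols <- setdiff(STREAM_COLUMNS, names(dt))
  if (length(miss_cols))
    stopf("%s: missing columns: %s", path, paste(miss_cols, collapse = ", "))
  df <- as.data.frame(dt)[STREAM_COLUMNS]
  ts <- parse_iso(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stopf("%s: unparseable timestamp at line %d: '%s'", path, bad + 1L,
          df$timestamp[bad])
  }
  df$timestamp <- ts
  for (col in CHANNEL_COLUMNS) {
    if (!is.numeric(df[[col]])) {
      v <- suppressWarnings(as.numeric(ifelse(df[[col]] == "", NA, df[[col]])))
      bad <- which(is.na(v) & !(df[[col]] %in% c("", NA)))
      if (length(bad))
        stopf("%s: unparseable %s at line %d", path, col, bad[1] + 1L)
      df[[col]] <- v
    }
  }
  if (!is.logical(df$missing)) {
    m <- df$missing %in% c("TRUE", "true", "1")
    ok <- df$missing %in% c("TRUE", "true", "1", "FALSE", "false", "0")
    if (!all(ok)) stopf("%s: unparseable missing flag at line %d", path,
                        which(!ok)[1] + 1L)
    df$missing <- m
  }
  if (nrow(df) > 1) {
    dts <- diff(as.numeric(df$timestamp))
    if (any(dts <= 0))
      stopf("%s: non-increasing timestamp at line %d", path,
            which(dts <= 0)[1] + 2L)
  }
  sensor_stream(df, participant_id, phase)
}

#' Write a sensor stream to its columnar text format
#'
#' @param stream a [sensor_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- as.data.frame(stream)
  df$timestamp <- format_iso(df$timestamp)
  for (col in CHANNEL_COLUMNS) {
    # 17 significant digits: lossless decimal round-trip for doubles
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  fwrite(df, path, sep = ",", na = "", quote = FALSE, showProgress = FALSE)
  invisible(path)
}

#' Read an event log from CSV
#'
#' Parses `timestamp,kind,level` rows with kind in smoke/lapse/craving and
#' level 1..5 present exactly for craving reports.
#'
#' @param path path to an event CSV file.
#' @inheritParams sensor_stream
#' @return An `event_log`.
#' @export
read_events <- function(path, participant_id, phase) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- fread(path, sep = ",", header = TRUE, colClasses = list(
    character = c("timestamp", "kind")), showProgress = FALSE)
  need <- c("timestamp", "kind", "level")
  if (!all(need %in% names(dt)))
    stopf("%s: missing columns: %s", path,
          paste(setdiff(need, names(dt)), collapse = ", "))
  df <- as.data.frame(dt)[need]
  if (nrow(df)) {
    ts <- parse_iso(df$timestamp)
    if (anyNA(ts))
      stopf("%s: unparseable timestamp at line %d", path, which(is.na(ts))[1] + 1L)
    df$timestamp <- ts
  } else {
    df$timestamp <- as.POSIXct(character(), tz = "UTC")
  }
  tryCatch(event_log(df, participant_id, phase),
           error = function(e) stopf("%s: %s", path, conditionMessage(e)))
}

#' Write an event log to CSV
#'
#' @param events an [event_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  df <- as.data.frame(events)
  df$timestamp <- format_iso(df$timestamp)
  fwrite(df, path, sep = ",", na = "", quote = FALSE, showProgress = FALSE)
  invisible(path)
}
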