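WINDOW_ROWS <- 25L
WINDOW_SECONDS <- 300

CHANNEL_SETS <- list(
  "ACC" = c("acc_x", "acc_y", "acc_z"),
  "GYR" = c("gyr_x", "gyr_y", "gyr_z"),
  "MAG" = c("mag_x", "mag_y", "mag_z"),
  "L"   = "light",
  "T"   = "tod",
  "ACC-GYR-MAG" = c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                    "mag_x", "mag_y", "mag_z"),
  "ACC-GYR-MAG-L-T" = CHANNEL_COLUMNS
)

#' Slice a stream into non-overlapping 5-minute windows
#'
#' Cuts the stream into consecutive 25-row windows aligned to the stream
#' start (25 rows at 5 rows/minute span exactly 5 minutes); a trailing
#' remainder shorter than 25 rows is dropped. Each window records its start
#' time and hour of day.
#'
#' @param stream a [sensor_stream()].
#' @return A `window_set`: list with `x` (windows x 25 x 11 channel array),
#'   `missing` (windows x 25 logical matrix) and `meta` (one row per window:
#'   participant, phase, start time, hour of day).
#' @export
slice_windows <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- nrow(stream)
  w <- n %/% WINDOW_ROWS
  ch <- as.matrix(as.data.frame(stream)[CHANNEL_COLUMNS])
  used <- w * WINDOW_ROWS
  # row (i, t) of window j sits at stream row (j-1)*25 + t
  x <- array(NA_real_, c(w, WINDOW_ROWS, length(CHANNEL_COLUMNS)),
             dimnames = list(NULL, NULL, CHANNEL_COLUMNS))
  miss <- matrix(FALSE, w, WINDOW_ROWS)
  if (w > 0) {
    for (t in seq_len(WINDOW_ROWS)) {
      rows <- seq(t, used, by = WINDOW_ROWS)
      x[, t, ] <- ch[rows, , drop = FALSE]
      miss[, t] <- stream$missing[rows]
    }
  }
  starts <- if (w > 0) stream$timestamp[seq(1, used, by = WINDOW_ROWS)] else
    as.POSIXct(character(), tz = "UTC")
  meta <- data.frame(
    participant_id = rep(attr(stream, "participant_id"), w),
    phase = rep(attr(stream, "phase"), w),
    start_time = starts,
    hour_of_day = as.integer(format(starts, "%H", tz = "UTC")),
    stringsAsFactors = FALSE)
  structure(list(x = x, missing = miss, meta = meta), class = "window_set")
}

#' Remove majority-missing windows and impute the rest
#'
#' Windows in which a majority of the 25 rows (13 or more) are missing are
#' removed as uninformative. In retained windows, remaining missing rows are
#' filled by last-observation-carried-forward within the window, with a
#' leading-edge back-fill, so no information leaks across window boundaries.
#'
#' @param windows a `window_set` from [slice_windows()].
#' @param max_missing maximum number of missing rows a window may have and
#'   still be retained (default 12, i.e. strictly less than a majority).
#' @return The filtered and imputed `window_set`.
#' @export
drop_incomplete <- function(windows, max_missing = 12L) {
  stopifnot(inherits(windows, "window_set"))
  n_miss <- rowSums(windows$missing)
  keep <- which(n_miss <= max_missing)
  x <- windows$x[keep, , , drop = FALSE]
  miss <- windows$missing[keep, , drop = FALSE]
  meta <- windows$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  to_fix <- which(rowSums(miss) > 0)
  for (i in to_fix) {
    obs <- which(!miss[i, ])
    # index of the last observed row at or before t; 0 -> leading back-fill
    src <- obs[findInterval(seq_len(WINDOW_ROWS), obs)]
    lead <- seq_len(WINDOW_ROWS) < obs[1]
    src <- c(rep(obs[1], sum(lead)), src)
    x[i, , ] <- x[i, src, ]
  }
  structure(list(x = x, missing = matrix(FALSE, length(keep), WINDOW_ROWS),
                 meta = meta), class = "window_set")
}

#' Label windows from an event log
#'
#' A window receives label 1 exactly when at least one event timestamp
#' falls inside its half-open interval `[start, start + 5 min)`; the event
#' kind and craving level of the earliest contained event are copied into
#' the window metadata. All other windows are labelled 0. Events outside
#' the stream's covered time range are ignored with a warning.
#'
#' @param windows a `window_set`.
#' @param events an [event_log()] for the same participant and phase.
#' @return A `labeled_dataset`: list with `x` (windows x 25 x C array),
#'   `meta` (labels and window metadata) and `channels`.
#' @export
label_windows <- function(windows, events) {
  stopifnot(inherits(windows, "window_set"), inherits(events, "event_log"))
  meta <- windows$meta
  n <- nrow(meta)
  meta$label <- 0L
  meta$event_kind <- "none"
  meta$craving_level <- NA_integer_
  if (n > 0 && nrow(events) > 0) {
    starts <- as.numeric(meta$start_time)
    ev <- as.numeric(events$timestamp)
    idx <- findInterval(ev, starts)
    inside <- idx >= 1 & (ev - starts[pmax(idx, 1)]) < WINDOW_SECONDS
    if (any(!inside))
      warnf("%d event(s) fall outside the windowed time range and were ignored",
            sum(!inside))
    for (j in which(inside)) {
      w <- idx[j]
      if (meta$label[w] == 0L) {      # earliest event wins (log is sorted)
        meta$label[w] <- 1L
        meta$event_kind[w] <- events$kind[j]
        meta$craving_level[w] <- events$level[j]
      }
    }
  }
  structure(list(x = windows$x, meta = meta,
                 channels = dimnames(windows$x)[[3]]),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d windows x %d channels (%d positive)\n",
              nrow(x$meta), length(x$channels), sum(x$meta$label)))
  invisible(x)
}

#' Combine labeled datasets
#'
#' @param ... `labeled_dataset` objects sharing one channel spec.
#' @return A single `labeled_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "labeled_dataset")) parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, TRUE, "labeled_dataset")))
  ch <- parts[[1]]$channels
  for (p in parts) {
    if (!identical(p$channels, ch)) stopf("channel specs differ")
  }
  x <- do.call(abind_first, lapply(parts, `[[`, "x"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta, channels = ch), class = "labeled_dataset")
}

# rbind for 3-d arrays along the first (window) axis
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(NA_real_, c(n, d[2], d[3]),
               dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

subset_dataset <- function(ds, idx) {
  meta <- ds$meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(x = ds$x[idx, , , drop = FALSE], meta = meta,
                 channels = ds$channels), class = "labeled_dataset")
}

#' Reclassify positive windows
#'
#' The `binary` scheme is the identity. The `lapse_vs_craving` scheme
#' splits Phase 2 positive windows into two classes by their event kind
#' (actual lapses vs craving reports of any level), leaving negatives
#' unchanged, to support the split ROC analysis.
#'
#' @param dataset a `labeled_dataset`.
#' @param scheme `"binary"` or `"lapse_vs_craving"`.
#' @return The dataset; under `lapse_vs_craving` the metadata gains a
#'   `class2` column (`none`, `lapse` or `craving`).
#' @export
reclassify <- function(dataset, scheme = c("binary", "lapse_vs_craving")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  scheme <- match.arg(scheme)
  if (scheme == "binary") return(dataset)
  if (any(dataset$meta$phase != 2L))
    stopf("lapse_vs_craving reclassification applies to Phase 2 data only")
  meta <- dataset$meta
  meta$class2 <- ifelse(meta$label == 1L, meta$event_kind, "none")
  structure(list(x = dataset$x, meta = meta, channels = dataset$channels),
            class = "labeled_dataset")
}

# Mean within-window variance across channels; the "noisiness" score used
# by the noise-removal rule and by the model-free variance discriminant.
window_variance_scores <- function(dataset) {
  x <- if (inherits(dataset, "labeled_dataset")) dataset$x else dataset
  n <- dim(x)[1]
  if (n == 0) return(numeric())
  vapply(seq_len(n), function(i) {
    m <- x[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    mean(apply(m, 2, var))
  }, 0)
}

#' Balance classes by seeded random downsampling with noise removal
#'
#' Majority-class windows in the top tail of within-window channel variance
#' (above `noise_quantile` among majority windows) are excluded first as
#' noise; the remaining majority windows are then randomly subsampled
#' without replacement to the minority-class count, yielding exactly equal
#' class sizes.
#'
#' @param dataset a `labeled_dataset` containing both classes.
#' @param seed integer seed for the subsample.
#' @param noise_quantile variance quantile above which majority windows are
#'   excluded before subsampling (default 0.95).
#' @return A balanced `labeled_dataset`.
#' @export
balance_downsample <- function(dataset, seed = 1L, noise_quantile = 0.95) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$meta$label
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0)
    stopf(paste("both classes must be present to balance;",
                "use the non-balanced evaluation mode instead"))
  maj <- if (n_pos >= n_neg) 1L else 0L
  maj_idx <- which(y == maj); min_idx <- which(y != maj)
  v <- window_variance_scores(subset_dataset(dataset, maj_idx))
  keep <- maj_idx[v <= quantile(v, noise_quantile)]
  k <- length(min_idx)
  if (length(keep) < k) keep <- maj_idx[order(v)][seq_len(min(k, length(maj_idx)))]
  sel <- with_seed(child_seed(seed, "balance"),
                   sample(keep, min(k, length(keep))))
  subset_dataset(dataset, sort(c(min_idx, sel)))
}

#' Select a sensor channel subset
#'
#' Reduces the window matrices to one of the study's input types:
#' each inertial sensor alone (`ACC`, `GYR`, `MAG`, 3 channels each),
#' ambient light `L` or time-of-day `T` (1 channel each), the combined
#' 9-channel `ACC-GYR-MAG` input, or all 11 channels
#' (`ACC-GYR-MAG-L-T`).
#'
#' @param dataset a `labeled_dataset`.
#' @param subset one of `names(smokesense::channel_subsets())`.
#' @return The dataset restricted to the ordered channel subset.
#' @export
select_channels <- function(dataset, subset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  subset <- toupper(subset)
  if (!subset %in% names(CHANNEL_SETS))
    stopf("unknown channel subset '%s'; valid: %s", subset,
          paste(names(CHANNEL_SETS), collapse = ", "))
  cols <- CHANNEL_SETS[[subset]]
  if (!all(cols %in% dataset$channels))
    stopf("requested channels not present in dataset")
  structure(list(x = dataset$x[, , cols, drop = FALSE],
                 meta = dataset$meta, channels = cols),
            class = "labeled_dataset")
}

#' Available channel subsets
#'
#' @return Named list mapping subset names to channel columns.
#' @export
channel_subsets <- function() CHANNEL_SETS

#' Seeded shuffled train/test split
#'
#' Shuffles windows (avoiding temporal leakage from the non-overlapping
#' slicing order) and splits them per participant into a training and a
#' test part, stratified by label so that both classes appear on both sides
#' whenever each class has at least two windows.
#'
#' @param dataset a `labeled_dataset`.
#' @param train_frac fraction of each participant's windows used for
#'   training (default 0.9).
#' @param seed integer seed.
#' @return List with `train` and `test` datasets (disjoint, exhaustive).
#' @export
shuffle_split <- function(dataset, train_frac = 0.9, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$meta)
  if (n < 10) stopf("need at least 10 samples to split")
  meta <- dataset$meta
  train_idx <- integer()
  with_seed(child_seed(seed, "split"), {
    for (pid in unique(meta$participant_id)) {
      for (cls in unique(meta$label[meta$participant_id == pid])) {
        idx <- which(meta$participant_id == pid & meta$label == cls)
        if (length(idx) < 2) {
          warnf("class %s of participant %s has < 2 windows; unstratified",
                cls, pid)
          train_idx <- c(train_idx, idx)
          next
        }
        idx <- sample(idx)
        n_tr <- round(train_frac * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        train_idx <- c(train_idx, idx[seq_len(n_tr)])
      }
    }
  })
  list(train = subset_dataset(dataset, sort(train_idx)),
       test = subset_dataset(dataset, sort(setdiff(seq_len(n), train_idx))))
}

#' Run the full preprocessing pipeline for one participant-phase
#'
#' Convenience wrapper: slice, drop/impute majority-missing windows, label
#' from the event log, and select channels.
#'
#' @param stream a [sensor_stream()].
#' @param events the matching [event_log()].
#' @param channels channel subset name (see [channel_subsets()]).
#' @return A `labeled_dataset`.
#' @export
prepare_windows <- function(stream, events, channels = "ACC-GYR-MAG") {
  ws <- drop_incomplete(slice_windows(stream))
  select_channels(label_windows(ws, events), channels)
}
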