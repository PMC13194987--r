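make_cfg <- function(arch, n_channels, seed, options = list()) {
  args <- c(list(arch = arch, n_channels = n_channels, seed = seed), options)
  do.call(model_config, args)
}

stratum_accuracy <- function(pred_label, true_label, by) {
  out <- lapply(split(seq_along(by), by), function(idx) {
    list(n = length(idx), accuracy = mean(pred_label[idx] == true_label[idx]))
  })
  out[order(as.numeric(names(out)))]
}

#' Assemble an evaluation report
#'
#' Computes the confusion matrix, accuracy, PPV/NPV, ROC points and AUC for
#' one scored test set, plus accuracy stratified by hour of day, by event
#' kind (lapse vs craving) and by craving level where the metadata carries
#' them.
#'
#' @param scores per-window scores in `[0, 1]`.
#' @param meta the test-set window metadata (with `label`, `hour_of_day`,
#'   `event_kind`, `craving_level`).
#' @param design one of `"within_subject"`, `"phase_transfer"`, `"lopo"`.
#' @param arch,channels identifiers recorded in the report.
#' @param threshold decision threshold.
#' @param extra named list merged into the report (e.g. audit fields).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(scores, meta, design, arch, channels,
                        threshold = 0.5, extra = list()) {
  labels <- meta$label
  cm <- confusion_counts(scores, labels, threshold)
  roc <- if (length(unique(labels)) == 2) roc_auc(scores, labels) else NULL
  pred <- as.integer(scores >= threshold)
  strata <- list(hour_of_day = stratum_accuracy(pred, labels,
                                                meta$hour_of_day))
  pos <- which(labels == 1L)
  if (length(pos) && any(meta$event_kind[pos] %in% c("lapse", "craving"))) {
    strata$event_kind <- lapply(
      split(pos, meta$event_kind[pos]),
      function(idx) list(n = length(idx),
                         accuracy = mean(pred[idx] == labels[idx])))
    crav <- pos[meta$event_kind[pos] == "craving"]
    if (length(crav))
      strata$craving_level <- stratum_accuracy(pred[crav], labels[crav],
                                               meta$craving_level[crav])
  }
  structure(c(list(design = design, arch = arch, channels = channels,
                   n = length(scores),
                   accuracy = cm$accuracy,
                   confusion = cm[c("tp", "fp", "tn", "fn")],
                   ppv = cm$ppv, npv = cm$npv,
                   roc = roc$points, auc = roc$auc %||% NA_real_,
                   threshold = threshold,
                   scores = scores, labels = labels,
                   strata = strata),
              extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report [%s] %s / %s\n", x$design, toupper(x$arch),
              x$channels))
  cat(sprintf("  n = %d, accuracy = %.3f, AUC = %.3f\n", x$n, x$accuracy,
              x$auc))
  cat(sprintf("  confusion TP %d FP %d TN %d FN %d; PPV %.3f NPV %.3f\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn,
              x$ppv, x$npv))
  invisible(x)
}

# Train on a balanced split and score its held-out part.
fit_and_score <- function(train_ds, test_ds, arch, seed, model_options) {
  cfg <- make_cfg(arch, length(train_ds$channels),
                  child_seed(seed, "model", arch), model_options)
  model <- train_model(build_model(cfg), train_ds)
  list(model = model, pred = predict(model, test_ds))
}

#' Within-subject evaluation on pre-quit data
#'
#' The first evaluation design: one participant's Phase 1 windows are
#' balanced, shuffled and split 90/10; the model trains on the 90% and
#' predicts smoking events in the held-out 10%.
#'
#' @param bundle a `participant_bundle` from [generate_participant()].
#' @param arch model architecture (see [model_config()]).
#' @param channels channel subset name (see [channel_subsets()]).
#' @param seed master seed for balancing, splitting and training.
#' @param model_options named overrides passed to [model_config()]
#'   (e.g. smaller `n_filters`/`hidden_size`/`epochs` for quick runs).
#' @param train_frac training fraction of the balanced windows.
#' @param noise_quantile noise-removal quantile for [balance_downsample()].
#' @return An `eval_report`.
#' @export
within_subject_eval <- function(bundle, arch = "1dcnn-bilstm",
                                channels = "ACC-GYR-MAG", seed = 1L,
                                model_options = list(), train_frac = 0.9,
                                noise_quantile = 0.95) {
  stopifnot(inherits(bundle, "participant_bundle"))
  ds <- prepare_windows(bundle$phase1, bundle$events1, channels)
  bal <- balance_downsample(ds, seed = child_seed(seed, "bal"),
                            noise_quantile = noise_quantile)
  sp <- shuffle_split(bal, train_frac, seed = child_seed(seed, "split"))
  fs <- fit_and_score(sp$train, sp$test, arch, seed, model_options)
  eval_report(fs$pred$score, sp$test$meta, "within_subject", arch, channels,
              extra = list(participant_id = bundle$participant_id,
                           n_train = nrow(sp$train$meta),
                           n_test = nrow(sp$test$meta)))
}

#' Phase-transfer evaluation: pre-quit training, post-quit testing
#'
#' The second design: the model trains on 100% of the participant's
#' balanced Phase 1 windows and predicts their Phase 2 lapses and craving
#' reports, supporting the lapse/craving, craving-level and hour-of-day
#' stratifications.
#'
#' @inheritParams within_subject_eval
#' @param balance_test balance the Phase 2 test windows as well (default);
#'   `FALSE` keeps the natural class imbalance, the variant under which
#'   PPV/NPV are the informative summaries.
#' @return An `eval_report`, or `NULL` (with a warning) when the
#'   participant reported no Phase 2 events.
#' @export
phase_transfer_eval <- function(bundle, arch = "1dcnn-bilstm",
                                channels = "ACC-GYR-MAG", seed = 1L,
                                model_options = list(), balance_test = TRUE,
                                noise_quantile = 0.95) {
  stopifnot(inherits(bundle, "participant_bundle"))
  if (nrow(bundle$events2) == 0) {
    warnf("participant %s reported no Phase 2 events; skipped",
          bundle$participant_id)
    return(NULL)
  }
  train_ds <- balance_downsample(
    prepare_windows(bundle$phase1, bundle$events1, channels),
    seed = child_seed(seed, "bal1"), noise_quantile = noise_quantile)
  test_ds <- prepare_windows(bundle$phase2, bundle$events2, channels)
  test_ds <- reclassify(test_ds, "lapse_vs_craving")
  if (balance_test)
    test_ds <- balance_downsample(test_ds, seed = child_seed(seed, "bal2"),
                                  noise_quantile = noise_quantile)
  fs <- fit_and_score(train_ds, test_ds, arch, seed, model_options)
  eval_report(fs$pred$score, test_ds$meta, "phase_transfer", arch, channels,
              extra = list(participant_id = bundle$participant_id,
                           n_train = nrow(train_ds$meta),
                           n_test = nrow(test_ds$meta),
                           balanced_test = balance_test))
}

split_kind_auc <- function(scores, meta, kind) {
  keep <- meta$label == 0L | meta$event_kind == kind
  if (!any(meta$label[keep] == 1L)) return(NA_real_)
  roc_auc(scores[keep], meta$label[keep])$auc
}

#' Leave-one-participant-out evaluation
#'
#' The cross-subject design: for each participant with Phase 2 reports,
#' the model trains on the pooled, balanced Phase 1 windows of all *other*
#' participants and scores the held-out participant's Phase 2 windows.
#' Produces per-participant ROC/AUC, their mean, and lapse-only /
#' craving-only AUC splits (participants with no events of a kind are
#' excluded from that split).
#'
#' @param cohort a `sensor_cohort` from [generate_cohort()].
#' @inheritParams within_subject_eval
#' @return A `lopo_result`: list with per-participant `reports`,
#'   `mean_auc`, `mean_auc_lapse`, `mean_auc_craving`.
#' @export
lopo_eval <- function(cohort, arch = "1dcnn-bilstm",
                      channels = "ACC-GYR-MAG", seed = 1L,
                      model_options = list(), noise_quantile = 0.95) {
  stopifnot(inherits(cohort, "sensor_cohort"))
  eligible <- Filter(function(p) nrow(p$events2) > 0, cohort$participants)
  if (length(eligible) < 3)
    stopf("need at least 3 participants with Phase 2 events (have %d)",
          length(eligible))
  all_ids <- names(cohort$participants)
  train_sets <- lapply(cohort$participants, function(p)
    prepare_windows(p$phase1, p$events1, channels))
  reports <- list()
  for (pid in names(eligible)) {
    held <- eligible[[pid]]
    train_ids <- setdiff(all_ids, pid)
    pool <- bind_datasets(train_sets[train_ids])
    pool <- balance_downsample(pool, seed = child_seed(seed, "bal", pid),
                               noise_quantile = noise_quantile)
    test_ds <- reclassify(
      prepare_windows(held$phase2, held$events2, channels),
      "lapse_vs_craving")
    fs <- fit_and_score(pool, test_ds, arch, child_seed(seed, "fit", pid),
                        model_options)
    rep <- eval_report(fs$pred$score, test_ds$meta, "lopo", arch, channels,
                       extra = list(
                         participant_id = pid,
                         train_participants = train_ids,
                         auc_lapse = split_kind_auc(fs$pred$score,
                                                    test_ds$meta, "lapse"),
                         auc_craving = split_kind_auc(fs$pred$score,
                                                      test_ds$meta, "craving"),
                         n_train = nrow(pool$meta),
                         n_test = nrow(test_ds$meta)))
    reports[[pid]] <- rep
  }
  aucs <- vapply(reports, `[[`, 0, "auc")
  lap <- vapply(reports, `[[`, 0, "auc_lapse")
  crv <- vapply(reports, `[[`, 0, "auc_craving")
  structure(list(reports = reports,
                 mean_auc = mean(aucs, na.rm = TRUE),
                 mean_auc_lapse = if (all(is.na(lap))) NA_real_
                                  else mean(lap, na.rm = TRUE),
                 mean_auc_craving = if (all(is.na(crv))) NA_real_
                                    else mean(crv, na.rm = TRUE),
                 arch = arch, channels = channels),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("LOPO evaluation (%s, %s): %d held-out participants\n",
              toupper(x$arch), x$channels, length(x$reports)))
  cat(sprintf("  mean AUC %.3f (lapse-only %.3f, craving-only %.3f)\n",
              x$mean_auc, x$mean_auc_lapse, x$mean_auc_craving))
  invisible(x)
}

#' Accuracy grid over input types and architectures
#'
#' Runs the within-subject and/or phase-transfer design for every
#' combination of sensor input type and architecture, averages accuracy
#' over participants (unweighted), flags the best cell, and applies the
#' Friedman rank test per architecture across input types (participants as
#' blocks).
#'
#' @param cohort a `sensor_cohort`.
#' @param archs architectures to evaluate.
#' @param subsets channel subsets (rows of the grid).
#' @param designs which designs to run.
#' @inheritParams within_subject_eval
#' @return A `grid_result`: per design an input-type x architecture
#'   accuracy matrix, per-participant cell values, the best cell, and
#'   per-architecture `friedman_result`s.
#' @export
grid_experiment <- function(cohort,
                            archs = c("lstm", "1dcnn", "bilstm",
                                      "1dcnn-bilstm"),
                            subsets = c("ACC", "GYR", "MAG", "L", "T",
                                        "ACC-GYR-MAG"),
                            designs = c("within_subject", "phase_transfer"),
                            seed = 1L, model_options = list(),
                            noise_quantile = 0.95) {
  stopifnot(inherits(cohort, "sensor_cohort"))
  designs <- match.arg(designs, c("within_subject", "phase_transfer"),
                       several.ok = TRUE)
  out <- list()
  for (design in designs) {
    parts <- cohort$participants
    if (design == "phase_transfer")
      parts <- Filter(function(p) nrow(p$events2) > 0, parts)
    cells <- array(NA_real_,
                   c(length(subsets), length(archs), length(parts)),
                   dimnames = list(subsets, archs, names(parts)))
    for (pid in names(parts)) {
      for (ss in subsets) {
        for (arch in archs) {
          rep <- if (design == "within_subject") {
            within_subject_eval(parts[[pid]], arch, ss,
                                seed = child_seed(seed, design, pid, ss),
                                model_options = model_options,
                                noise_quantile = noise_quantile)
          } else {
            phase_transfer_eval(parts[[pid]], arch, ss,
                                seed = child_seed(seed, design, pid, ss),
                                model_options = model_options,
                                noise_quantile = noise_quantile)
          }
          if (!is.null(rep)) cells[ss, arch, pid] <- rep$accuracy
        }
      }
    }
    acc <- apply(cells, c(1, 2), mean, na.rm = TRUE)
    best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
    friedman <- lapply(archs, function(a) {
      g <- t(cells[, a, , drop = TRUE])   # participants x input types
      if (is.null(dim(g))) g <- matrix(g, ncol = length(subsets))
      friedman_rank_test(g)
    })
    names(friedman) <- archs
    out[[design]] <- list(accuracy = acc, per_participant = cells,
                          best = list(subset = subsets[best[1]],
                                      arch = archs[best[2]],
                                      accuracy = max(acc)),
                          friedman = friedman)
  }
  structure(out, class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  for (design in names(x)) {
    cat(sprintf("-- %s accuracy grid --\n", design))
    print(round(x[[design]]$accuracy, 3))
    cat(sprintf("best: %s / %s = %.3f\n", x[[design]]$best$subset,
                toupper(x[[design]]$best$arch), x[[design]]$best$accuracy))
  }
  invisible(x)
}
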