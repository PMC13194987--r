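test_that("within-subject evaluation produces a coherent report", {
  p <- cached_fixture("eval_participant",
                      small_participant(seed = 121L, phase1_days = 3L))
  rep <- cached_fixture("ws_report",
                        within_subject_eval(p, "1dcnn-bilstm", "ACC-GYR-MAG",
                                            seed = 5L,
                                            model_options = quick_model()))
  expect_s3_class(rep, "eval_report")
  cm <- rep$confusion
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, rep$n_test)
  expect_equal(rep$accuracy, (cm$tp + cm$tn) / rep$n_test)
  expect_gte(rep$auc, 0)
  expect_lte(rep$auc, 1)
  # strong-signal participant is well separated
  expect_gt(rep$accuracy, 0.7)
  # hour-of-day strata partition the test set
  hours <- rep$strata$hour_of_day
  expect_equal(sum(vapply(hours, `[[`, 0, "n")), rep$n_test)
})

test_that("stratified accuracies aggregate to the overall accuracy", {
  rep <- cached_fixture("ws_report", stop("fixture missing"))
  hours <- rep$strata$hour_of_day
  ns <- vapply(hours, `[[`, 0, "n")
  accs <- vapply(hours, `[[`, 0, "accuracy")
  expect_equal(sum(ns * accs) / sum(ns), rep$accuracy, tolerance = 1e-12)
})

test_that("phase-transfer evaluation stratifies by kind and level", {
  p <- cached_fixture("eval_participant", stop("fixture missing"))
  rep <- phase_transfer_eval(p, "1dcnn-bilstm", "ACC-GYR-MAG", seed = 5L,
                             model_options = quick_model())
  expect_s3_class(rep, "eval_report")
  expect_true(all(c("lapse", "craving") %in% names(rep$strata$event_kind)) ||
                length(rep$strata$event_kind) >= 1)
  # confusion identities hold here too
  cm <- rep$confusion
  expect_equal(rep$accuracy, (cm$tp + cm$tn) / rep$n)
  # a participant with no phase-2 reports is skipped with a warning
  p0 <- generate_participant(
    cohort_config(n_participants = 1, phase1_days = 1, phase2_days = 1,
                  seed = 9), motif_spec(), "P01", empty_phase2 = TRUE)
  expect_warning(out <- phase_transfer_eval(p0, model_options = quick_model()),
                 "skipped")
  expect_null(out)
})

test_that("LOPO holds each participant out of training (audited)", {
  coh <- cached_fixture("eval_cohort", generate_cohort(
    cohort_config(n_participants = 3, phase1_days = 2, phase2_days = 2,
                  smokes_per_day = 15, craving_rate = 3, lapse_rate = 7,
                  subject_jitter = 0.05, motif_amplitude = 2,
                  frac_no_phase2 = 0, seed = 13),
    motif_spec()))
  res <- lopo_eval(coh, seed = 5L, model_options = quick_model(12L))
  expect_s3_class(res, "lopo_result")
  expect_length(res$reports, 3L)
  for (rep in res$reports) {
    expect_false(rep$participant_id %in% rep$train_participants)
    expect_setequal(c(rep$participant_id, rep$train_participants),
                    names(coh$participants))
  }
  expect_gte(res$mean_auc, 0)
  expect_lte(res$mean_auc, 1)
  # too few eligible participants errors
  tiny <- coh
  tiny$participants <- coh$participants[1:2]
  expect_error(lopo_eval(tiny), "at least 3")
})

test_that("the experiment grid covers all input types and architectures", {
  coh <- cached_fixture("grid_cohort", generate_cohort(
    cohort_config(n_participants = 2, phase1_days = 2, phase2_days = 1,
                  smokes_per_day = 15, motif_amplitude = 2,
                  frac_no_phase2 = 0, seed = 23),
    motif_spec()))
  subsets <- c("ACC", "GYR", "MAG", "L", "T", "ACC-GYR-MAG")
  grid <- grid_experiment(coh, subsets = subsets,
                          designs = "within_subject", seed = 3L,
                          model_options = quick_model(4L))
  acc <- grid$within_subject$accuracy
  expect_equal(dim(acc), c(6L, 4L))
  expect_true(all(acc >= 0 & acc <= 1))
  expect_true(grid$within_subject$best$accuracy == max(acc))
  fr <- grid$within_subject$friedman
  expect_length(fr, 4L)
  for (f in fr) expect_s3_class(f, "friedman_result")
})
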