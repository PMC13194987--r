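test_that("configuration objects validate their invariants", {
  expect_error(cohort_config(phase1_days = 0), "phase durations")
  expect_error(cohort_config(samples_per_minute = 0), "samples_per_minute")
  expect_error(cohort_config(craving_level_probs = rep(0.25, 4)),
               "craving_level_probs")
  expect_error(cohort_config(craving_level_probs = c(0.3, 0.3, 0.3, 0.05, 0.1)),
               "craving_level_probs")
  expect_error(cohort_config(missing_prob = 1), "missing_prob")
  expect_error(cohort_config(smokes_per_day = -1), "non-negative")
  expect_error(motif_spec(pre_event_window = 0), "pre_event_window")
  expect_error(motif_spec(variance_gain = 0.5), "variance_gain")
})

test_that("participant generation is deterministic for fixed seed and id", {
  a <- small_participant(seed = 33L, phase1_days = 1L, phase2_days = 1L)
  b <- small_participant(seed = 33L, phase1_days = 1L, phase2_days = 1L)
  expect_identical(as.data.frame(a$phase1), as.data.frame(b$phase1))
  expect_identical(as.data.frame(a$phase2), as.data.frame(b$phase2))
  expect_identical(as.data.frame(a$events1), as.data.frame(b$events1))
  expect_identical(as.data.frame(a$events2), as.data.frame(b$events2))
})

test_that("stream geometry and event schedules match the configuration", {
  cfg <- cohort_config(n_participants = 1, phase1_days = 14, phase2_days = 1,
                       samples_per_minute = 1, smokes_per_day = 10,
                       missing_prob = 0, seed = 5)
  p <- generate_participant(cfg, motif_spec(), "P01")
  expect_equal(nrow(p$phase1), 14 * 1440)
  # Phase 1 smoke count ~ Poisson(140); 99% interval
  bounds <- qpois(c(0.005, 0.995), 14 * 10)
  expect_gte(nrow(p$events1), bounds[1])
  expect_lte(nrow(p$events1), bounds[2])
  # all events inside their phase's time range
  expect_true(all(p$events1$timestamp >= p$phase1$timestamp[1]))
  expect_true(all(p$events1$timestamp <=
                    p$phase1$timestamp[nrow(p$phase1)]))
  expect_true(all(p$events2$timestamp >= p$phase2$timestamp[1]))
  expect_true(all(p$events2$timestamp <=
                    p$phase2$timestamp[nrow(p$phase2)]))
  # craving reports at least daily
  expect_gte(sum(p$events2$kind == "craving"), cfg$phase2_days)
})

test_that("zero motif amplitude leaves event windows indistinguishable", {
  p <- small_participant(amplitude = 0, seed = 17L, missing_prob = 0)
  ds <- prepare_windows(p$phase1, p$events1, "ACC-GYR-MAG")
  v <- smokesense:::window_variance_scores(ds)
  pos <- v[ds$meta$label == 1]
  neg <- v[ds$meta$label == 0]
  expect_gt(suppressWarnings(ks.test(pos, neg)$p.value), 0.05)
  # but label structure still exists
  expect_gt(length(pos), 0)
})

test_that("variance-discriminant AUC is non-decreasing in motif amplitude", {
  aucs <- vapply(c(0, 0.7, 2), function(amp) {
    p <- small_participant(amplitude = amp, seed = 29L, missing_prob = 0)
    ds <- prepare_windows(p$phase1, p$events1, "ACC-GYR-MAG")
    roc_auc(smokesense:::window_variance_scores(ds), ds$meta$label)$auc
  }, 0)
  expect_true(all(diff(aucs) >= 0))
  expect_lt(abs(aucs[1] - 0.5), 0.1)   # no signal -> chance
  expect_gt(aucs[3], 0.9)              # strong signal -> separable
})

test_that("cohort generation shares the motif but jitters participants", {
  cfg <- cohort_config(n_participants = 4, phase1_days = 1, phase2_days = 1,
                       subject_jitter = 0.3, frac_no_phase2 = 0.25, seed = 2)
  coh <- generate_cohort(cfg, motif_spec())
  expect_length(coh$participants, 4)
  expect_equal(sum(vapply(coh$participants,
                          function(p) nrow(p$events2) == 0, TRUE)), 1)
  amps <- vapply(coh$participants, `[[`, 0, "amp_mult")
  expect_gt(length(unique(amps)), 1)
  # distinct event schedules
  e1 <- coh$participants[[1]]$events1$timestamp
  e2 <- coh$participants[[2]]$events1$timestamp
  expect_false(identical(e1, e2))

  # zero jitter -> identical motif parameters across participants
  cfg0 <- cohort_config(n_participants = 2, phase1_days = 1, phase2_days = 1,
                        subject_jitter = 0, frac_no_phase2 = 0, seed = 2)
  coh0 <- generate_cohort(cfg0, motif_spec())
  expect_equal(coh0$participants[[1]]$amp_mult, 1)
  expect_equal(coh0$participants[[2]]$amp_mult, 1)
  expect_equal(coh0$participants[[1]]$phase_shift,
               coh0$participants[[2]]$phase_shift)

  # different master seeds -> different schedules
  cfgb <- cohort_config(n_participants = 2, phase1_days = 1, phase2_days = 1,
                        subject_jitter = 0, frac_no_phase2 = 0, seed = 3)
  cohb <- generate_cohort(cfgb, motif_spec())
  expect_false(identical(coh0$participants[[1]]$events1$timestamp,
                         cohb$participants[[1]]$events1$timestamp))
})

test_that("craving levels follow the configured distribution", {
  probs <- c(0.15, 0.20, 0.25, 0.20, 0.20)
  cfg <- cohort_config(n_participants = 4, phase1_days = 1, phase2_days = 20,
                       samples_per_minute = 1, craving_rate = 8,
                       craving_level_probs = probs, frac_no_phase2 = 0,
                       missing_prob = 0, motif_amplitude = 0, seed = 19)
  coh <- generate_cohort(cfg, motif_spec())
  levels <- unlist(lapply(coh$participants, function(p)
    p$events2$level[p$events2$kind == "craving"]))
  expect_gt(length(levels), 400)
  counts <- tabulate(levels, 5)
  expect_gt(chisq.test(counts, p = probs)$p.value, 0.01)
})

test_that("missingness injection hits its target rate and zeroes channels", {
  s <- flat_stream(10000)
  expect_identical(inject_missingness(s, 0, seed = 1), s)
  s2 <- inject_missingness(s, 0.5, seed = 7)
  frac <- mean(s2$missing)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  expect_true(all(is.na(s2$acc_x[s2$missing])))
  expect_identical(s2$timestamp, s$timestamp)
  expect_error(inject_missingness(s, 1), "missing_prob")
})
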