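report_to_list <- function(rep) {
  if (is.null(rep)) return(NULL)
  keep <- setdiff(names(rep), c("scores", "labels", "roc"))
  out <- rep[keep]
  out$strata <- rep$strata
  out
}

#' Run a configured end-to-end experiment
#'
#' Generates a synthetic cohort from the configuration, runs the requested
#' evaluation designs, and (optionally) writes JSON reports plus a manifest
#' recording the seeds and configuration, so a rerun with the same master
#' seed reproduces the report.
#'
#' @param plan either a path to a YAML file or a named list, with elements
#'   `cohort` (arguments for [cohort_config()]), `motif` (arguments for
#'   [motif_spec()]), `designs` (subset of `within_subject`,
#'   `phase_transfer`, `lopo`, `grid`), `arch`, `channels`, `model` (named
#'   [model_config()] overrides) and `seed`.
#' @param out_dir optional output directory for JSON reports.
#' @return List of design results, invisibly when `out_dir` is given.
#' @export
run_experiment_plan <- function(plan, out_dir = NULL) {
  if (is.character(plan)) {
    if (!file.exists(plan)) stopf("no such config file: %s", plan)
    plan <- yaml::read_yaml(plan)
  }
  stopifnot(is.list(plan))
  seed <- as.integer(plan$seed %||% 1L)
  cohort_args <- plan$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  config <- do.call(cohort_config, cohort_args)
  motif <- do.call(motif_spec, plan$motif %||% list())
  designs <- plan$designs %||% "within_subject"
  arch <- plan$arch %||% "1dcnn-bilstm"
  channels <- plan$channels %||% "ACC-GYR-MAG"
  model_options <- plan$model %||% list()

  cohort <- generate_cohort(config, motif)
  results <- list()
  for (design in designs) {
    results[[design]] <- switch(
      design,
      within_subject = lapply(cohort$participants, within_subject_eval,
                              arch = arch, channels = channels, seed = seed,
                              model_options = model_options),
      phase_transfer = lapply(cohort$participants, phase_transfer_eval,
                              arch = arch, channels = channels, seed = seed,
                              model_options = model_options),
      lopo = lopo_eval(cohort, arch = arch, channels = channels,
                       seed = seed, model_options = model_options),
      grid = grid_experiment(cohort, seed = seed,
                             model_options = model_options),
      stopf("unknown design '%s'", design))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (design in names(results)) {
      r <- results[[design]]
      serial <- if (inherits(r, "lopo_result")) {
        list(mean_auc = r$mean_auc, mean_auc_lapse = r$mean_auc_lapse,
             mean_auc_craving = r$mean_auc_craving,
             reports = lapply(r$reports, report_to_list))
      } else if (inherits(r, "grid_result")) {
        lapply(unclass(r), function(d) list(
          accuracy = d$accuracy, best = d$best,
          friedman = lapply(d$friedman, unclass)))
      } else {
        lapply(r, report_to_list)
      }
      jsonlite::write_json(serial,
                           file.path(out_dir, paste0(design, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE, na = "null")
    }
    manifest <- list(package_version = as.character(utils::packageVersion("smokesense")),
                     seed = seed, designs = designs, arch = arch,
                     channels = channels,
                     cohort = unclass(config), motif = unclass(motif),
                     model = model_options)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, na = "null")
    return(invisible(results))
  }
  results
}

#' Write toy cohort fixtures to disk
#'
#' Generates a small deterministic cohort and writes each participant's
#' streams and event logs in the package's CSV dialect, for use as test and
#' demonstration inputs. `tiny` is 2 participants with 1-day phases; `demo`
#' is 6 participants with 7-day phases.
#'
#' @param out_dir writable output directory (created if needed).
#' @param size `"tiny"` or `"demo"`.
#' @param seed master seed.
#' @return Invisibly, the cohort that was written.
#' @export
make_fixtures <- function(out_dir, size = c("tiny", "demo"), seed = 421L) {
  size <- match.arg(size)
  dims <- switch(size,
                 tiny = list(n = 2L, d1 = 1L, d2 = 1L),
                 demo = list(n = 6L, d1 = 7L, d2 = 7L))
  config <- cohort_config(n_participants = dims$n, phase1_days = dims$d1,
                          phase2_days = dims$d2, smokes_per_day = 15,
                          craving_rate = 3, lapse_rate = 7,
                          frac_no_phase2 = 0, missing_prob = 0.05,
                          seed = seed)
  cohort <- generate_cohort(config, motif_spec())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    id <- p$participant_id
    write_stream(p$phase1, file.path(out_dir, sprintf("%s_phase1_stream.csv", id)))
    write_stream(p$phase2, file.path(out_dir, sprintf("%s_phase2_stream.csv", id)))
    write_events(p$events1, file.path(out_dir, sprintf("%s_phase1_events.csv", id)))
    write_events(p$events2, file.path(out_dir, sprintf("%s_phase2_events.csv", id)))
  }
  jsonlite::write_json(list(size = size, seed = seed,
                            participants = names(cohort$participants)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}
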