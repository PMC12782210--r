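# Run configuration and pipeline entry points (simulate -> run -> report).
# The same functions back the command-line wrapper in
# `inst/scripts/motionprint.R`.

#' Build and validate a pipeline run configuration
#'
#' Collects every knob of the pipeline in one validated object; defaults
#' mirror the study protocol (10 + 5 minutes at 100 Hz, 36 users, 4
#' decoys, the stated hyperparameter grids). All violations are reported
#' together.
#'
#' @param n_users,cohort_seed,separation Cohort settings.
#' @param laying_minutes,sitting_minutes,sample_rate_hz Protocol settings.
#' @param n_decoys Decoy count.
#' @param models Character vector of model kinds to run.
#' @param experiments Character vector of experiment families to run
#'   (subset of `"rq1"`, `"rq2_forward"`, `"rq3_backward"`, `"rq4"`).
#' @param grid A [hyperparameter_grid()].
#' @param transformer A [transformer_config()].
#' @param targets Optional cap on the number of targets per family
#'   (reduced-scale mode); `NULL` runs every non-decoy target.
#' @param out_dir Output directory.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(n_users = 36L, cohort_seed = 1L, separation = 1,
                       laying_minutes = 10L, sitting_minutes = 5L,
                       sample_rate_hz = 100L, n_decoys = 4L,
                       models = c("knn", "rf", "nn"),
                       experiments = "rq1",
                       grid = hyperparameter_grid(),
                       transformer = transformer_config(),
                       targets = NULL, out_dir = "motionprint_out") {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  if (!is_count(n_users, 2L)) note("n_users must be an integer >= 2")
  if (!is.numeric(separation) || separation < 0)
    note("separation must be non-negative")
  if (!is_count(laying_minutes) || !is_count(sitting_minutes))
    note("protocol minutes must be whole numbers >= 1")
  if (!is_count(n_decoys, 1L) ||
      (is_count(n_users, 2L) && n_users < n_decoys + 2L))
    note("n_decoys must leave at least 2 non-decoy users")
  bad_models <- setdiff(models, c("knn", "rf", "nn", "swipeformer"))
  if (length(bad_models) > 0L)
    note("unknown model kind(s): %s", paste(bad_models, collapse = ", "))
  valid_exp <- c("rq1", "rq2_forward", "rq3_backward", "rq4")
  bad_exp <- setdiff(experiments, valid_exp)
  if (length(bad_exp) > 0L)
    note("unknown experiment(s): %s (valid: %s)",
         paste(bad_exp, collapse = ", "), paste(valid_exp, collapse = ", "))
  if (!is.null(targets) && !is_count(targets, 1L))
    note("targets must be NULL or a whole number >= 1")
  if (length(problems) > 0L)
    stopf("invalid configuration:\n%s",
          paste("  -", problems, collapse = "\n"))
  structure(
    list(n_users = as.integer(n_users), cohort_seed = as.integer(cohort_seed),
         separation = as.numeric(separation),
         protocol = protocol_spec(laying_minutes, sitting_minutes,
                                  sample_rate_hz),
         n_decoys = as.integer(n_decoys), models = models,
         experiments = experiments, grid = grid, transformer = transformer,
         targets = targets, out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_config()]
#'   (nested `grid:` and `transformer:` blocks are passed through to
#'   [hyperparameter_grid()] and [transformer_config()]).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$grid)) raw$grid <- do.call(hyperparameter_grid, raw$grid)
  if (!is.null(raw$transformer))
    raw$transformer <- do.call(transformer_config, raw$transformer)
  do.call(run_config, raw)
}

#' Simulate a cohort to disk
#'
#' Writes one SensorLog-style CSV per synthetic user plus a
#' `cohort_manifest.yaml` recording the configuration; rerunning with the
#' same configuration reproduces identical files.
#'
#' @param config A [run_config()].
#' @param cohort_dir Output directory (default `<out_dir>/cohort`).
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(config, cohort_dir = file.path(config$out_dir,
                                                        "cohort")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(cohort_dir, showWarnings = FALSE, recursive = TRUE)
  sigs <- sample_cohort(config$n_users, config$cohort_seed, config$separation)
  paths <- character(length(sigs))
  for (i in seq_along(sigs)) {
    rec <- simulate_recording(sigs[[i]], config$protocol,
                              seed = mix_seed(config$cohort_seed, 11L, i))
    paths[i] <- file.path(cohort_dir, paste0(sigs[[i]]$user_id, ".csv"))
    write_sensorlog_csv(rec, paths[i])
  }
  manifest <- list(
    n_users = config$n_users, cohort_seed = config$cohort_seed,
    separation = config$separation,
    protocol = unclass(config$protocol),
    files = basename(paths)
  )
  man_path <- file.path(cohort_dir, "cohort_manifest.yaml")
  yaml::write_yaml(manifest, man_path)
  invisible(man_path)
}

# Load a cohort directory written by cmd_simulate back into cohort_data.
read_cohort_dir <- function(cohort_dir, sequences = FALSE) {
  man_path <- file.path(cohort_dir, "cohort_manifest.yaml")
  if (!file.exists(man_path))
    stopf("no cohort manifest in '%s'; run cmd_simulate first", cohort_dir)
  man <- yaml::read_yaml(man_path)
  protocol <- protocol_spec(man$protocol$laying_minutes,
                            man$protocol$sitting_minutes,
                            man$protocol$sample_rate_hz)
  sigs <- sample_cohort(man$n_users, man$cohort_seed, man$separation)
  feats <- vector("list", length(man$files))
  metas <- vector("list", length(man$files))
  seqs <- if (sequences) vector("list", length(man$files)) else NULL
  for (i in seq_along(man$files)) {
    rec <- read_sensorlog_csv(file.path(cohort_dir, man$files[[i]]))
    wf <- window_feature_matrix(rec)
    feats[[i]] <- wf$features
    metas[[i]] <- wf$meta
    if (sequences) seqs[[i]] <- window_raw_sequences(rec)
  }
  meta <- do.call(rbind, metas)
  meta$row <- seq_len(nrow(meta))
  out <- list(signatures = sigs,
              users = vapply(metas, function(m) m$user_id[1], character(1)),
              protocol = protocol, seed = man$cohort_seed,
              separation = man$separation,
              features = do.call(rbind, feats), meta = meta)
  if (sequences) {
    L <- dim(seqs[[1]])[2]
    all_seq <- array(0, dim = c(nrow(meta), L, 6L))
    at <- 0L
    for (i in seq_along(seqs)) {
      nb <- dim(seqs[[i]])[1]
      all_seq[at + seq_len(nb), , ] <- seqs[[i]]
      at <- at + nb
    }
    out$sequences <- all_seq
  }
  structure(out, class = "cohort_data")
}

# Enumerate the (family, spec-builder) units requested by a config.
config_specs <- function(config, users) {
  seed <- config$cohort_seed
  protocol <- config$protocol
  targets <- cohort_targets(users, seed, config$n_decoys)
  if (!is.null(config$targets)) targets <- utils::head(targets, config$targets)
  specs <- list()
  for (fam in config$experiments) {
    for (target in targets) {
      if (fam == "rq1") {
        specs[[length(specs) + 1L]] <-
          build_rq1_split(users, target, seed, protocol, config$n_decoys)
      } else if (fam %in% c("rq2_forward", "rq3_backward")) {
        dir <- if (fam == "rq2_forward") "forward_from_start" else "backward_trim"
        for (m in 1:12) {
          specs[[length(specs) + 1L]] <-
            build_length_sweep(users, target, dir, m, seed, protocol,
                               n_decoys = config$n_decoys)
        }
      } else if (fam == "rq4") {
        combos <- expand.grid(train = c("laying2", "sitting2", "mixed1+1"),
                              test = c("laying2", "sitting2"),
                              stringsAsFactors = FALSE)
        for (ci in seq_len(nrow(combos))) {
          offs <- position_offsets(combos$train[ci], combos$test[ci], protocol)
          for (o in offs$offset) {
            specs[[length(specs) + 1L]] <-
              build_position_split(users, target, combos$train[ci],
                                   combos$test[ci], o, seed, protocol,
                                   config$n_decoys)
          }
        }
      }
    }
  }
  specs
}

unit_filename <- function(spec, model_kind) {
  ex <- spec$extra
  tag <- paste(c(spec$rq_id, model_kind, spec$target_user_id,
                 if (!is.null(ex$minutes)) paste0("m", ex$minutes),
                 if (!is.null(ex$offset)) paste0("o", ex$offset)),
               collapse = "_")
  paste0(tag, ".json")
}

#' Run the configured experiments over a cohort directory
#'
#' Executes every requested (experiment family, target, model) unit,
#' writing one JSON result per unit into `<out_dir>/results`. Units whose
#' result file already exists are skipped, so an interrupted run resumes
#' where it left off. Finishes by rendering summary tables and figures.
#'
#' @param config A [run_config()].
#' @param cohort_dir Cohort directory from [cmd_simulate()].
#' @param quiet Suppress per-unit progress lines.
#' @return The results directory, invisibly.
#' @export
cmd_run <- function(config, cohort_dir = file.path(config$out_dir, "cohort"),
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  need_seq <- "swipeformer" %in% config$models
  cohort <- read_cohort_dir(cohort_dir, sequences = need_seq)
  res_dir <- file.path(config$out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- config_specs(config, cohort$users)
  results <- list()
  for (spec in specs) {
    for (kind in config$models) {
      path <- file.path(res_dir, unit_filename(spec, kind))
      if (file.exists(path)) {
        if (!quiet) message("skip (done): ", basename(path))
        next
      }
      res <- run_experiment(spec, kind, cohort, grid = config$grid,
                            transformer_cfg = config$transformer)
      write_result_json(res, path)
      results[[length(results) + 1L]] <- res
      if (!quiet)
        message(sprintf("%s  F1=%.3f", basename(path), res$metrics$f1))
    }
  }
  cmd_report(res_dir, file.path(config$out_dir, "report"))
  invisible(res_dir)
}

# Rebuild a lightweight experiment_result from its serialized JSON.
read_result_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$rq_id) || is.null(raw$metrics))
    stopf("corrupt results file: %s", path)
  spec <- structure(
    list(rq_id = raw$rq_id, target_user_id = raw$target_user_id,
         decoy_user_ids = raw$decoy_user_ids,
         train_selection = raw$train_selection,
         test_selection = raw$test_selection,
         seed = raw$seed, gap_to_test = raw$gap_to_test %||% NA_real_,
         extra = raw$extra),
    class = "experiment_spec"
  )
  structure(
    list(spec = spec, model_kind = raw$model_kind,
         hyperparameters = raw$hyperparameters, cv_table = NULL,
         n_train = raw$n_train, n_test = raw$n_test,
         predictions = raw$predictions,
         metrics = structure(raw$metrics, class = "metrics_set")),
    class = "experiment_result"
  )
}

#' Re-render tables and figures from serialized results
#'
#' Reads every unit JSON under `results_dir` and regenerates all reports
#' without recomputation.
#'
#' @param results_dir Directory of unit JSONs from [cmd_run()].
#' @param out_dir Report output directory.
#' @return Files written, invisibly.
#' @export
cmd_report <- function(results_dir, out_dir) {
  files <- list.files(results_dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L)
    stopf("no result files in '%s'", results_dir)
  results <- lapply(files, read_result_json)
  render_reports(results, out_dir)
}
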