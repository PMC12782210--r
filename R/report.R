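# Tables, figures and serialization for experiment result sets.

result_to_list <- function(res) {
  stopifnot(inherits(res, "experiment_result"))
  sp <- res$spec
  list(
    rq_id = sp$rq_id, model_kind = res$model_kind,
    target_user_id = sp$target_user_id,
    decoy_user_ids = sp$decoy_user_ids,
    seed = sp$seed, gap_to_test = sp$gap_to_test, extra = sp$extra,
    train_selection = sp$train_selection, test_selection = sp$test_selection,
    hyperparameters = res$hyperparameters,
    n_train = res$n_train, n_test = res$n_test,
    predictions = res$predictions,
    metrics = unclass(res$metrics)
  )
}

#' Serialize one experiment result to JSON
#'
#' Writes the full provenance: spec, chosen hyperparameters, per-window
#' predictions and metrics. Deterministic bytes for deterministic inputs
#' (full-precision numbers, stable key order).
#'
#' @param res An `experiment_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(res, path) {
  jsonlite::write_json(result_to_list(res), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

# Sweep/condition key of one result, used to group rows in tables.
result_condition <- function(res) {
  ex <- res$spec$extra
  data.frame(
    rq = res$spec$rq_id, model = res$model_kind,
    minutes = ex$minutes %||% NA_integer_,
    gap = res$spec$gap_to_test %||% NA_real_,
    train_type = ex$train_type %||% NA_character_,
    test_type = ex$test_type %||% NA_character_,
    offset = ex$offset %||% NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Summary table of a result set: one row per experimental condition
#'
#' Groups results by (rq, model, minutes, gap, train type, test type,
#' offset) and reports the median and 25th/75th percentiles of each metric
#' across targets within each group.
#'
#' @param results List of `experiment_result`s.
#' @return A data.frame with one row per condition.
#' @export
results_table <- function(results) {
  if (length(results) == 0L) stopf("no results to tabulate")
  conds <- do.call(rbind, lapply(results, result_condition))
  key <- apply(conds, 1, paste, collapse = "|")
  rows <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    summ <- summarize_metrics(lapply(results[idx], `[[`, "metrics"))
    wide <- data.frame(n_targets = summ$n_targets[1])
    for (i in seq_len(nrow(summ))) {
      m <- summ$metric[i]
      wide[[paste0(m, "_median")]] <- summ$median[i]
      wide[[paste0(m, "_q25")]] <- summ$q25[i]
      wide[[paste0(m, "_q75")]] <- summ$q75[i]
    }
    cbind(conds[idx[1], , drop = FALSE], wide)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- order(out$rq, out$model, out$minutes, out$gap, out$offset,
               method = "radix", na.last = TRUE)
  out[ord, ]
}

#' Render tables and figures for a set of experiment results
#'
#' Writes, per experiment family: a CSV summary table
#' (`table_<family>.csv`), a figure (`fig_<family>.png`; box plots of the
#' four metrics for the decoy protocol, median lines with shaded IQR for
#' sweeps), and a `manifest.json` linking every file to the conditions and
#' seeds it came from. Rendering the same results twice produces
#' byte-identical CSVs.
#'
#' @param results Non-empty list of `experiment_result`s.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(results, out_dir) {
  if (length(results) == 0L) stopf("no results to render")
  stopifnot(all(vapply(results, inherits, logical(1), "experiment_result")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fams <- vapply(results, function(r) r$spec$rq_id, character(1))
  files <- character(0)
  manifest <- list()

  for (fam in unique(fams)) {
    sub <- results[fams == fam]
    tab <- results_table(sub)
    tab_path <- file.path(out_dir, paste0("table_", fam, ".csv"))
    utils::write.csv(tab, tab_path, row.names = FALSE)
    fig_path <- file.path(out_dir, paste0("fig_", fam, ".png"))
    p <- plot_family(sub, tab)
    grDevices::png(fig_path, width = 1400, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
    files <- c(files, tab_path, fig_path)
    manifest[[fam]] <- list(
      table = basename(tab_path), figure = basename(fig_path),
      models = unique(vapply(sub, `[[`, character(1), "model_kind")),
      targets = unique(vapply(sub, function(r) r$spec$target_user_id,
                              character(1))),
      seeds = unique(vapply(sub, function(r) r$spec$seed, numeric(1)))
    )
  }
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, man_path))
}

# One figure per family: box plots for the decoy protocol, median + IQR
# ribbon against minutes/gap/offset for sweeps.
plot_family <- function(results, tab) {
  fam <- results[[1]]$spec$rq_id
  if (startsWith(fam, "rq1")) {
    per <- do.call(rbind, lapply(results, function(r) {
      data.frame(model = r$model_kind,
                 precision = r$metrics$precision, recall = r$metrics$recall,
                 f1 = r$metrics$f1, accuracy = r$metrics$accuracy)
    }))
    long <- stats::reshape(per, direction = "long",
                           varying = c("precision", "recall", "f1", "accuracy"),
                           v.names = "value", timevar = "metric",
                           times = c("precision", "recall", "f1", "accuracy"))
    return(ggplot2::ggplot(long,
                           ggplot2::aes(x = .data$model, y = .data$value)) +
             ggplot2::geom_boxplot() +
             ggplot2::facet_wrap(~metric) +
             ggplot2::ylim(0, 1) +
             ggplot2::labs(title = "Decoy protocol: per-target metrics",
                           x = NULL, y = NULL) +
             ggplot2::theme_bw())
  }
  xvar <- if (!all(is.na(tab$minutes))) "minutes" else
          if (!all(is.na(tab$gap))) "gap" else "offset"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xvar]], y = .data$f1_median,
                                    colour = .data$model, fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$f1_q25,
                                      ymax = .data$f1_q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = paste0(fam, ": median F1 with IQR across targets"),
                  x = xvar, y = "F1") +
    ggplot2::theme_bw()
}
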