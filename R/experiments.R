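# Experiment construction and execution: the decoy (unseen-negative)
# protocol, training-length and time-proximity sweeps, and the
# position-type cross-over, all expressed as per-target train/test split
# recipes over protocol minutes.

# ---- cohort container ------------------------------------------------------

#' Simulate a cohort and precompute windows, features and sequences
#'
#' Builds everything the experiment runners need for one synthetic cohort:
#' signatures, per-user recordings, the stacked `windows x 56` feature
#' matrix with window metadata, and (optionally) the raw per-window
#' sequences for the transformer.
#'
#' @param n_users Cohort size (default 36).
#' @param seed Master cohort seed.
#' @param separation Cohort separation multiplier (see [sample_cohort()]).
#' @param protocol A [protocol_spec()].
#' @param sequences If `TRUE`, also precompute raw window sequences
#'   (needed for the transformer; costs memory).
#' @return An object of class `cohort_data` with elements `signatures`,
#'   `users`, `protocol`, `seed`, `features` (matrix), `meta` (data.frame
#'   with one row per window), and optionally `sequences` (array
#'   `windows x L x 6`, rows aligned with `meta`).
#' @export
build_cohort <- function(n_users = 36L, seed = 1L, separation = 1,
                         protocol = protocol_spec(), sequences = FALSE) {
  sigs <- sample_cohort(n_users, seed, separation)
  feats <- vector("list", n_users)
  metas <- vector("list", n_users)
  seqs <- if (sequences) vector("list", n_users) else NULL
  for (i in seq_len(n_users)) {
    rec <- simulate_recording(sigs[[i]], protocol, seed = mix_seed(seed, 11L, i))
    wf <- window_feature_matrix(rec)
    feats[[i]] <- wf$features
    metas[[i]] <- wf$meta
    if (sequences) seqs[[i]] <- window_raw_sequences(rec)
  }
  meta <- do.call(rbind, metas)
  meta$row <- seq_len(nrow(meta))
  out <- list(signatures = sigs,
              users = vapply(sigs, function(s) s$user_id, character(1)),
              protocol = protocol, seed = seed, separation = separation,
              features = do.call(rbind, feats), meta = meta)
  if (sequences) {
    L <- dim(seqs[[1]])[2]
    all_seq <- array(0, dim = c(nrow(meta), L, 6L))
    at <- 0L
    for (i in seq_len(n_users)) {
      nb <- dim(seqs[[i]])[1]
      all_seq[at + seq_len(nb), , ] <- seqs[[i]]
      at <- at + nb
    }
    out$sequences <- all_seq
  }
  structure(out, class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d users, %d windows, separation %.2f, seed %d\n",
              length(x$users), nrow(x$meta), x$separation, x$seed))
  invisible(x)
}

# Protocol-minute bookkeeping. Minutes are 1-based; laying occupies
# 1..laying_minutes, sitting the rest.
laying_minutes_of <- function(protocol) seq_len(protocol$laying_minutes)
sitting_minutes_of <- function(protocol) {
  protocol$laying_minutes + seq_len(protocol$sitting_minutes)
}

#' Choose the cohort's decoy users
#'
#' Decoys are users excluded from every training set but present in every
#' test set; they are drawn once per cohort seed and held constant across
#' all analyses.
#'
#' @param users Character vector of user ids.
#' @param seed Cohort seed.
#' @param n_decoys Number of decoys (default 4).
#' @return Character vector of decoy ids.
#' @export
choose_decoys <- function(users, seed, n_decoys = 4L) {
  if (length(users) < n_decoys + 2L)
    stopf("cohort of %d users cannot spare %d decoys and keep >= 2 trainees",
          length(users), n_decoys)
  with_seed(mix_seed(seed, 21L), sort(sample(users, n_decoys)))
}

# ---- experiment specs ------------------------------------------------------

#' Construct and validate an experiment split recipe
#'
#' A spec names the target, the decoys, and the training and testing
#' selections as (user, protocol minute) pairs. Validation enforces the
#' core contracts: decoys never appear in the training selection, the
#' target appears in both selections, per-user train and test minutes are
#' disjoint, and all minutes lie within the protocol.
#'
#' @param rq_id Experiment family label (e.g. `"rq1"`, `"rq2_forward"`).
#' @param target_user_id The target user.
#' @param decoy_user_ids Character vector of decoy ids.
#' @param train_selection,test_selection Data frames with columns
#'   `user_id`, `minute`.
#' @param seed Integer seed recorded for provenance.
#' @param protocol A [protocol_spec()].
#' @param gap_to_test Optional minutes between the end of training and the
#'   start of testing (recorded for sweep reporting).
#' @param extra Optional named list of additional bookkeeping fields.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(rq_id, target_user_id, decoy_user_ids,
                            train_selection, test_selection, seed,
                            protocol = protocol_spec(),
                            gap_to_test = NA_real_, extra = list()) {
  stopifnot(is.data.frame(train_selection), is.data.frame(test_selection),
            all(c("user_id", "minute") %in% names(train_selection)),
            all(c("user_id", "minute") %in% names(test_selection)))
  max_min <- total_minutes(protocol)
  if (any(train_selection$minute < 1) || any(train_selection$minute > max_min) ||
      any(test_selection$minute < 1) || any(test_selection$minute > max_min))
    stopf("selection minutes must lie within the %d-minute protocol", max_min)
  if (any(decoy_user_ids %in% train_selection$user_id))
    stopf("decoy users must never appear in the training selection")
  if (!target_user_id %in% train_selection$user_id ||
      !target_user_id %in% test_selection$user_id)
    stopf("the target user must appear in both selections")
  both <- merge(train_selection, test_selection, by = c("user_id", "minute"))
  if (nrow(both) > 0L)
    stopf("train and test minutes overlap for user(s): %s",
          paste(unique(both$user_id), collapse = ", "))
  structure(
    list(rq_id = rq_id, target_user_id = target_user_id,
         decoy_user_ids = as.character(decoy_user_ids),
         train_selection = train_selection[order(train_selection$user_id,
                                                 train_selection$minute), ],
         test_selection = test_selection[order(test_selection$user_id,
                                               test_selection$minute), ],
         seed = seed, protocol = protocol, gap_to_test = gap_to_test,
         extra = extra),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %s target=%s decoys={%s} train=%d test=%d gap=%s\n",
              x$rq_id, x$target_user_id,
              paste(x$decoy_user_ids, collapse = ","),
              nrow(x$train_selection), nrow(x$test_selection),
              format(x$gap_to_test)))
  invisible(x)
}

#' Decoy-protocol split (unseen negatives)
#'
#' Training takes one seeded-random laying minute and one seeded-random
#' sitting minute from every non-decoy user (target included); decoys are
#' excluded from training entirely. Testing is the last 3 sitting minutes
#' of the target plus the same minutes of all decoys. To keep per-user
#' train/test minutes disjoint, the random sitting minute is drawn from the
#' sitting minutes preceding the test block.
#'
#' @param users Character vector of cohort user ids (at least 6).
#' @param target Target user id (must not be a decoy).
#' @param seed Cohort seed; drives both decoy choice and the random
#'   minutes, so all targets of one cohort share decoys and training
#'   minutes.
#' @param protocol A [protocol_spec()]; needs at least 4 sitting minutes.
#' @param n_decoys Number of decoys (default 4).
#' @return An [experiment_spec()].
#' @export
build_rq1_split <- function(users, target, seed, protocol = protocol_spec(),
                            n_decoys = 4L) {
  if (length(users) < 6L)
    stopf("the decoy protocol needs at least 6 users")
  decoys <- choose_decoys(users, seed, n_decoys)
  if (target %in% decoys) stopf("target '%s' is a decoy in this cohort", target)
  sit <- sitting_minutes_of(protocol)
  if (length(sit) < 4L)
    stopf("protocol too short: need >= 4 sitting minutes (3 test + 1 train pool)")
  test_minutes <- utils::tail(sit, 3L)
  train_sit_pool <- setdiff(sit, test_minutes)
  trainees <- setdiff(users, decoys)
  train <- do.call(rbind, lapply(trainees, function(u) {
    i <- match(u, users)
    with_seed(mix_seed(seed, 31L, i), {
      data.frame(user_id = u,
                 minute = c(sample(laying_minutes_of(protocol), 1L),
                            sample(train_sit_pool, 1L)))
    })
  }))
  test <- expand.grid(user_id = c(target, decoys), minute = test_minutes,
                      stringsAsFactors = FALSE)
  experiment_spec("rq1", target, decoys, train, test, seed, protocol)
}

#' Training-length / proximity sweep splits
#'
#' The available training timeline is 12 protocol minutes: the last 9
#' laying minutes plus the first 3 sitting minutes (which laying minute is
#' dropped is configurable; default the first). Testing is always the last
#' 2 sitting minutes. `forward_from_start` with `m` minutes selects
#' timeline minutes `1..m`, so the training trailing edge approaches the
#' test block as `m` grows (gap-to-test = `12 - m`). `backward_trim`
#' selects minutes `(12-m+1)..12`, keeping the trailing edge adjacent to
#' the test block (gap-to-test = 0).
#'
#' @param users Cohort user ids.
#' @param target Target user id.
#' @param direction `"forward_from_start"` or `"backward_trim"`.
#' @param minutes Training length `m` in 1..12.
#' @param seed Cohort seed (decoy choice).
#' @param protocol A [protocol_spec()] (defaults match the 10 + 5 design).
#' @param dropped_laying_minute Which laying minute to leave out of the
#'   timeline (default 1, the first).
#' @param n_decoys Number of decoys.
#' @return An [experiment_spec()] with `gap_to_test` filled in.
#' @export
build_length_sweep <- function(users, target,
                               direction = c("forward_from_start",
                                             "backward_trim"),
                               minutes, seed, protocol = protocol_spec(),
                               dropped_laying_minute = 1L, n_decoys = 4L) {
  direction <- match.arg(direction)
  lay <- laying_minutes_of(protocol)
  sit <- sitting_minutes_of(protocol)
  timeline <- c(setdiff(lay, dropped_laying_minute), utils::head(sit, 3L))
  n_tl <- length(timeline)  # 12 under the default protocol
  if (!is_count(minutes) || minutes > n_tl)
    stopf("minutes must be a whole number in 1..%d", n_tl)
  test_minutes <- utils::tail(sit, 2L)
  sel <- if (direction == "forward_from_start") seq_len(minutes)
         else (n_tl - minutes + 1L):n_tl
  gap <- n_tl - max(sel)
  decoys <- choose_decoys(users, seed, n_decoys)
  if (target %in% decoys) stopf("target '%s' is a decoy in this cohort", target)
  trainees <- setdiff(users, decoys)
  train <- expand.grid(user_id = trainees, minute = timeline[sel],
                       stringsAsFactors = FALSE)
  test <- expand.grid(user_id = c(target, decoys), minute = test_minutes,
                      stringsAsFactors = FALSE)
  experiment_spec(if (direction == "forward_from_start") "rq2_forward"
                  else "rq3_backward", target, decoys,
                  train, test, seed, protocol, gap_to_test = gap,
                  extra = list(direction = direction, minutes = minutes,
                               timeline = timeline))
}

#' Enumerate candidate training blocks for the position cross-over
#'
#' For a train/test position combination, lists every admissible training
#' block: consecutive 2-minute blocks of one position (`laying2`,
#' `sitting2`), or all (laying minute, sitting minute) pairs for
#' `mixed1+1`. Blocks may not overlap the test block; minutes of the
#' position not under test may lie anywhere in the protocol.
#'
#' @param train_type `"laying2"`, `"sitting2"` or `"mixed1+1"`.
#' @param test_type `"laying2"` or `"sitting2"`.
#' @param protocol A [protocol_spec()].
#' @return A data.frame with one row per offset: `offset`, `minute1`,
#'   `minute2`, `gap_to_test` (minutes between the nearest edges of the
#'   training and test blocks).
#' @export
position_offsets <- function(train_type = c("laying2", "sitting2", "mixed1+1"),
                             test_type = c("laying2", "sitting2"),
                             protocol = protocol_spec()) {
  train_type <- match.arg(train_type)
  test_type <- match.arg(test_type)
  lay <- laying_minutes_of(protocol)
  sit <- sitting_minutes_of(protocol)
  test_minutes <- if (test_type == "laying2") utils::tail(lay, 2L)
                  else utils::tail(sit, 2L)
  avail <- function(pool) setdiff(pool, test_minutes)
  # gap between block edges; for mixed blocks proximity is carried by the
  # training minute that shares the test position (the other minute sits in
  # a different orientation regime and does not shorten the distance)
  gap_of <- function(m1, m2) {
    if (train_type == "mixed1+1") {
      m <- if (test_type == "laying2") m1 else m2
      return(if (m < min(test_minutes)) min(test_minutes) - m - 1L
             else m - max(test_minutes) - 1L)
    }
    if (max(m2) < min(test_minutes)) min(test_minutes) - max(m2) - 1L
    else min(m1) - max(test_minutes) - 1L
  }
  if (train_type == "mixed1+1") {
    la <- avail(lay); sa <- avail(sit)
    grid <- expand.grid(minute1 = la, minute2 = sa)
  } else {
    pool <- avail(if (train_type == "laying2") lay else sit)
    # consecutive pairs within the pool
    ok <- pool[-length(pool)][diff(pool) == 1L]
    grid <- data.frame(minute1 = ok, minute2 = ok + 1L)
  }
  if (nrow(grid) == 0L)
    stopf("no admissible %s training block before the %s test block",
          train_type, test_type)
  grid$offset <- seq_len(nrow(grid))
  grid$gap_to_test <- mapply(gap_of, grid$minute1, grid$minute2)
  grid[, c("offset", "minute1", "minute2", "gap_to_test")]
}

#' Position cross-over split (train/test position combinations)
#'
#' Expresses the six position analyses: training on 2 minutes laying, 2
#' minutes sitting, or 1 minute of each, tested on the last 2 laying or
#' last 2 sitting minutes, with a sliding `offset` enumerating every
#' admissible training block (see [position_offsets()]).
#'
#' @inheritParams position_offsets
#' @param users Cohort user ids.
#' @param target Target user id.
#' @param offset Row index into [position_offsets()].
#' @param seed Cohort seed (decoy choice).
#' @param n_decoys Number of decoys.
#' @return An [experiment_spec()] with `gap_to_test` filled in.
#' @export
build_position_split <- function(users, target,
                                 train_type = c("laying2", "sitting2",
                                                "mixed1+1"),
                                 test_type = c("laying2", "sitting2"),
                                 offset = 1L, seed = 1L,
                                 protocol = protocol_spec(), n_decoys = 4L) {
  train_type <- match.arg(train_type)
  test_type <- match.arg(test_type)
  offs <- position_offsets(train_type, test_type, protocol)
  if (!offset %in% offs$offset)
    stopf("offset must be in 1..%d for %s -> %s", nrow(offs), train_type,
          test_type)
  row <- offs[offs$offset == offset, ]
  lay <- laying_minutes_of(protocol)
  sit <- sitting_minutes_of(protocol)
  test_minutes <- if (test_type == "laying2") utils::tail(lay, 2L)
                  else utils::tail(sit, 2L)
  decoys <- choose_decoys(users, seed, n_decoys)
  if (target %in% decoys) stopf("target '%s' is a decoy in this cohort", target)
  trainees <- setdiff(users, decoys)
  train <- expand.grid(user_id = trainees,
                       minute = c(row$minute1, row$minute2),
                       stringsAsFactors = FALSE)
  test <- expand.grid(user_id = c(target, decoys), minute = test_minutes,
                      stringsAsFactors = FALSE)
  experiment_spec(sprintf("rq4_%sx%s", train_type, test_type), target, decoys,
                  train, test, seed, protocol, gap_to_test = row$gap_to_test,
                  extra = list(train_type = train_type, test_type = test_type,
                               offset = offset))
}

# ---- runner ----------------------------------------------------------------

select_rows <- function(meta, selection) {
  key <- paste(meta$user_id, meta$minute)
  want <- paste(selection$user_id, selection$minute)
  rows <- which(key %in% want)
  if (length(rows) == 0L) stopf("selection matches no cohort windows")
  rows
}

#' Run one per-target experiment end to end
#'
#' Maps the spec's selections to cohort windows, asserts decoy purity and
#' train/test disjointness, normalizes features on the training windows
#' only, fits the requested model, predicts on the test windows, and
#' computes the target's metrics.
#'
#' @param spec An [experiment_spec()].
#' @param model_kind `"knn"`, `"rf"`, `"nn"` or `"swipeformer"`.
#' @param cohort A [build_cohort()] result (with `sequences = TRUE` for the
#'   transformer).
#' @param grid A [hyperparameter_grid()] for classical kinds.
#' @param transformer_cfg A [transformer_config()] for the transformer.
#' @return An object of class `experiment_result`: the spec, the fitted
#'   model's provenance, per-window `predictions` (user, window, truth,
#'   score, decision) and the target's `metrics`.
#' @export
run_experiment <- function(spec, model_kind, cohort,
                           grid = hyperparameter_grid(),
                           transformer_cfg = transformer_config()) {
  stopifnot(inherits(spec, "experiment_spec"), inherits(cohort, "cohort_data"))
  model_kind <- match.arg(model_kind, c("knn", "rf", "nn", "swipeformer"))
  tr_rows <- select_rows(cohort$meta, spec$train_selection)
  te_rows <- select_rows(cohort$meta, spec$test_selection)
  # decoy purity and train/test disjointness, asserted on every run
  if (any(cohort$meta$user_id[tr_rows] %in% spec$decoy_user_ids))
    stopf("internal error: decoy window entered a training matrix")
  if (length(intersect(tr_rows, te_rows)) > 0L)
    stopf("internal error: train and test windows overlap")
  y_tr <- as.integer(cohort$meta$user_id[tr_rows] == spec$target_user_id)
  y_te <- as.integer(cohort$meta$user_id[te_rows] == spec$target_user_id)

  if (model_kind == "swipeformer") {
    if (is.null(cohort$sequences))
      stopf("cohort was built without sequences; use build_cohort(sequences = TRUE)")
    cfg <- transformer_cfg
    cfg$seed <- mix_seed(spec$seed, 41L, match(spec$target_user_id, cohort$users))
    model <- fit_swipeformer(cohort$sequences[tr_rows, , , drop = FALSE],
                             y_tr, cfg, target_user_id = spec$target_user_id)
    pred <- predict(model, cohort$sequences[te_rows, , , drop = FALSE])
    norm <- NULL
  } else {
    norm <- fit_minmax(cohort$features[tr_rows, , drop = FALSE])
    X_tr <- apply_minmax(norm, cohort$features[tr_rows, , drop = FALSE])
    X_te <- apply_minmax(norm, cohort$features[te_rows, , drop = FALSE])
    model <- fit_classical(model_kind, X_tr, y_tr, grid = grid,
                           seed = mix_seed(spec$seed, 41L,
                                           match(spec$target_user_id,
                                                 cohort$users)),
                           target_user_id = spec$target_user_id)
    pred <- predict(model, X_te)
  }

  predictions <- data.frame(
    user_id = cohort$meta$user_id[te_rows],
    window_index = cohort$meta$window_index[te_rows],
    minute = cohort$meta$minute[te_rows],
    truth = y_te, score = pred$score, decision = pred$decision,
    stringsAsFactors = FALSE
  )
  structure(
    list(spec = spec, model_kind = model_kind,
         hyperparameters = model$hyperparameters,
         cv_table = model$cv_table,
         n_train = length(tr_rows), n_test = length(te_rows),
         predictions = predictions,
         metrics = compute_metrics(y_te, pred$decision)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s target=%s F1=%.3f (n_train=%d, n_test=%d)\n",
              x$spec$rq_id, x$model_kind, x$spec$target_user_id,
              x$metrics$f1, x$n_train, x$n_test))
  invisible(x)
}

#' Evaluate one experiment cell for many targets with a shared k-NN
#'
#' All per-target specs of one experimental cell (one sweep length, one
#' position/offset combination, or the decoy protocol) share an identical
#' training selection -- only the target label and the test windows differ.
#' This evaluator exploits that: it normalizes and indexes the training
#' windows once, finds the k nearest training windows for the union of all
#' test windows, and then scores every target from the shared neighbor
#' lists. Mathematically identical to calling [run_experiment()] with a
#' single-`k` grid per target (asserted in the test suite), but roughly an
#' order of magnitude faster for a 32-target cohort.
#'
#' @param specs List of [experiment_spec()]s sharing one training
#'   selection.
#' @param cohort A [build_cohort()] result.
#' @param k Neighbour count (no grid search; one fixed k).
#' @return A named list (by target) of [compute_metrics()] results.
#' @export
run_knn_cell <- function(specs, cohort, k = 5L) {
  stopifnot(length(specs) >= 1L, inherits(cohort, "cohort_data"))
  tr0 <- specs[[1]]$train_selection
  for (sp in specs[-1]) {
    if (!identical(sp$train_selection[, c("user_id", "minute")],
                   tr0[, c("user_id", "minute")]))
      stopf("run_knn_cell requires specs sharing one training selection")
  }
  tr_rows <- select_rows(cohort$meta, tr0)
  for (sp in specs) {
    if (any(cohort$meta$user_id[tr_rows] %in% sp$decoy_user_ids))
      stopf("internal error: decoy window entered a training matrix")
  }
  norm <- fit_minmax(cohort$features[tr_rows, , drop = FALSE])
  Xtr <- apply_minmax(norm, cohort$features[tr_rows, , drop = FALSE])
  if (k >= nrow(Xtr)) stopf("k = %d must be below %d training rows", k, nrow(Xtr))

  te_rows_list <- lapply(specs, function(sp) select_rows(cohort$meta,
                                                         sp$test_selection))
  union_rows <- sort(unique(unlist(te_rows_list)))
  if (length(intersect(tr_rows, union_rows)) > 0L)
    stopf("internal error: train and test windows overlap")
  Xte <- apply_minmax(norm, cohort$features[union_rows, , drop = FALSE])
  nb <- .knn_neighbors(Xtr, Xte, k)
  nb_user <- matrix(cohort$meta$user_id[tr_rows][nb], nrow(nb), ncol(nb))

  out <- lapply(seq_along(specs), function(si) {
    sp <- specs[[si]]
    pos <- match(te_rows_list[[si]], union_rows)
    truth <- as.integer(cohort$meta$user_id[te_rows_list[[si]]] ==
                          sp$target_user_id)
    score <- rowMeans(nb_user[pos, , drop = FALSE] == sp$target_user_id)
    compute_metrics(truth, as.integer(score >= 0.5))
  })
  names(out) <- vapply(specs, function(sp) sp$target_user_id, character(1))
  out
}

#' Non-decoy targets of a cohort
#'
#' @param users Cohort user ids.
#' @param seed Cohort seed.
#' @param n_decoys Number of decoys.
#' @return Character vector of the users that serve as targets (cohort
#'   minus decoys).
#' @export
cohort_targets <- function(users, seed, n_decoys = 4L) {
  setdiff(users, choose_decoys(users, seed, n_decoys))
}
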