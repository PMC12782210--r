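# Experiment split construction (decoy protocol, sweeps, position
# cross-over) and the end-to-end runner.

test_that("the decoy protocol builds 32 per-target specs over a 36-user cohort", {
  users <- cohort_ids(36)
  targets <- cohort_targets(users, seed = 7)
  expect_length(targets, 32L)
  specs <- lapply(targets, function(tg) build_rq1_split(users, tg, seed = 7))
  expect_length(specs, 32L)
  decoys <- choose_decoys(users, seed = 7)
  for (sp in specs) {
    expect_identical(sp$decoy_user_ids, decoys)
    expect_length(intersect(sp$train_selection$user_id, decoys), 0L)
    expect_identical(sort(unique(sp$train_selection$user_id)), sort(targets))
    expect_identical(nrow(sp$train_selection), 64L)  # 32 users x 2 minutes
    # per user: one laying minute (1..10) and one pre-test sitting minute
    per_user <- split(sp$train_selection$minute, sp$train_selection$user_id)
    for (mins in per_user) {
      expect_length(mins, 2L)
      expect_true(min(mins) %in% 1:10)
      expect_true(max(mins) %in% 11:12)
    }
    expect_identical(sort(unique(sp$test_selection$minute)), c(13L, 14L, 15L))
    expect_identical(sort(unique(sp$test_selection$user_id)),
                     sort(c(sp$target_user_id, decoys)))
  }
  # seeded determinism of the random-minute draws
  expect_identical(build_rq1_split(users, targets[1], seed = 7),
                   build_rq1_split(users, targets[1], seed = 7))
})

test_that("length sweeps walk a 12-minute timeline with correct gaps", {
  users <- cohort_ids(36)
  tg <- cohort_targets(users, seed = 1)[1]
  fwd1 <- build_length_sweep(users, tg, "forward_from_start", 1, seed = 1)
  expect_identical(fwd1$gap_to_test, 11L)
  expect_identical(unique(fwd1$train_selection$minute), 2L)  # first timeline minute
  bwd1 <- build_length_sweep(users, tg, "backward_trim", 1, seed = 1)
  expect_identical(bwd1$gap_to_test, 0L)
  expect_identical(unique(bwd1$train_selection$minute), 13L) # minute preceding test
  expect_identical(unique(bwd1$test_selection$minute), c(14L, 15L))
  # the timeline is the last 9 laying plus first 3 sitting minutes
  full <- build_length_sweep(users, tg, "forward_from_start", 12, seed = 1)
  expect_identical(sort(unique(full$train_selection$minute)), c(2:10, 11:13))
  # forward and backward coincide at the full length
  bwd12 <- build_length_sweep(users, tg, "backward_trim", 12, seed = 1)
  expect_identical(full$train_selection, bwd12$train_selection)
  expect_identical(full$test_selection, bwd12$test_selection)
  expect_error(build_length_sweep(users, tg, "forward_from_start", 13, seed = 1),
               "1\\.\\.12")
})

test_that("position cross-over offsets enumerate admissible blocks", {
  offs_ll <- position_offsets("laying2", "laying2")
  expect_identical(nrow(offs_ll), 7L)            # 8 laying minutes -> 7 pairs
  expect_identical(offs_ll$gap_to_test, 7:1 - 1L)
  offs_ss <- position_offsets("sitting2", "sitting2")
  expect_lt(nrow(offs_ss), nrow(offs_ll))        # shorter sitting segment
  expect_identical(nrow(offs_ss), 2L)
  offs_ls <- position_offsets("laying2", "sitting2")
  expect_identical(nrow(offs_ls), 9L)            # all 10 laying minutes
  mixed <- build_position_split(cohort_ids(36), cohort_targets(cohort_ids(36), 1)[1],
                                "mixed1+1", "laying2", offset = 1, seed = 1)
  mins <- unique(mixed$train_selection$minute)
  expect_length(mins, 2L)
  expect_true(any(mins <= 10) && any(mins >= 11)) # 1 laying + 1 sitting minute
  expect_error(build_position_split(cohort_ids(36), "user01", "sitting2",
                                    "sitting2", offset = 5, seed = 1),
               "offset")
})

test_that("spec validation rejects leaky selections", {
  users <- cohort_ids(8)
  decoys <- choose_decoys(users, seed = 2)
  tg <- setdiff(users, decoys)[1]
  train <- data.frame(user_id = c(tg, decoys[1]), minute = c(1L, 2L))
  test <- data.frame(user_id = c(tg, decoys), minute = 14L)
  expect_error(experiment_spec("x", tg, decoys, train, test, 1),
               "decoy users must never")
  train2 <- data.frame(user_id = tg, minute = 14L)
  expect_error(experiment_spec("x", tg, decoys, train2, test, 1),
               "overlap")
})

test_that("run_experiment is reproducible and consistent end to end", {
  co <- build_cohort(6, seed = 4, separation = 1,
                     protocol = protocol_spec(2, 4, 50))
  tg <- cohort_targets(co$users, 4)[1]
  sp <- build_rq1_split(co$users, tg, seed = 4, protocol = co$protocol)
  r1 <- run_experiment(sp, "knn", co, grid = hyperparameter_grid(knn_k = 5L))
  r2 <- run_experiment(sp, "knn", co, grid = hyperparameter_grid(knn_k = 5L))
  expect_identical(r1$predictions, r2$predictions)
  m <- r1$metrics
  expect_identical(m$tp + m$fp + m$tn + m$fn, nrow(r1$predictions))
  expect_identical(r1$predictions$decision,
                   as.integer(r1$predictions$score >= 0.5))
  # test windows cover exactly the target and the decoys
  expect_identical(sort(unique(r1$predictions$user_id)),
                   sort(c(tg, sp$decoy_user_ids)))
})

test_that("the shared-kNN cell evaluator equals per-target runs", {
  co <- build_cohort(7, seed = 9, separation = 1,
                     protocol = protocol_spec(2, 4, 50))
  targets <- cohort_targets(co$users, 9)
  specs <- lapply(targets, function(tg)
    build_rq1_split(co$users, tg, seed = 9, protocol = co$protocol))
  cell <- run_knn_cell(specs, co, k = 5L)
  for (i in seq_along(targets)) {
    ri <- run_experiment(specs[[i]], "knn", co,
                         grid = hyperparameter_grid(knn_k = 5L))
    expect_identical(unclass(ri$metrics), unclass(cell[[targets[i]]]),
                     info = targets[i])
  }
})
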