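test_that("subset_features keeps exactly the requested subjects", {
  sp <- blob_space(n_subjects = 5)
  sub <- subset_features(sp, c(2, 4))
  expect_identical(sort(unique(sub$labels)), c(2L, 4L))
  expect_equal(nrow(sub$matrix), 2 * sp$n_per_subject)
  expect_error(subset_features(sp, integer(0)), "empty")
  expect_error(subset_features(sp, c(2, 9)), "9")
})

test_that("stratified folds give every class at least kfold representatives", {
  sp <- blob_space(n_subjects = 4, n_per_subject = 9)
  ev <- evaluate_step(sp, classifier_spec("knn"), kfold = 3, seed = 1)
  expect_s3_class(ev, "step_evaluation")
  expect_identical(ev$n_classes, 4L)
  expect_length(ev$fold_accuracies, 3L)
  expect_identical(sum(ev$confusion), 36L)
  tiny <- blob_space(n_subjects = 3, n_per_subject = 2)
  expect_error(evaluate_step(tiny, classifier_spec("knn"), kfold = 3),
               "at least kfold")
})

test_that("well-separated blobs are classified perfectly, and determinism holds", {
  sp <- blob_space(n_subjects = 4, n_per_subject = 9, spread = 0.01)
  ev <- evaluate_step(sp, classifier_spec("knn"), kfold = 3, seed = 4)
  expect_identical(ev$accuracy, 1)
  expect_identical(ev$accuracy, mean(ev$fold_accuracies))
  ev2 <- evaluate_step(sp, classifier_spec("knn"), kfold = 3, seed = 4)
  expect_identical(ev2$fold_accuracies, ev$fold_accuracies)
})

test_that("all four classifier kinds run behind the same contract", {
  sp <- blob_space(n_subjects = 3, n_per_subject = 12, spread = 0.3)
  for (kind in c("knn", "naive_bayes", "decision_tree", "lda")) {
    ev <- evaluate_step(sp, classifier_spec(kind), kfold = 3, seed = 2)
    expect_gte(ev$accuracy, 0)
    expect_lte(ev$accuracy, 1)
    expect_gt(ev$accuracy, 0.6)  # blobs are easy for every family
  }
})

test_that("run_openness produces an M x R accuracy matrix and its mean", {
  sp <- blob_space(n_subjects = 8, n_per_subject = 9, spread = 0.05)
  cfg <- openness_config(t1 = 2, tr = 6, steps = 3, n_subjects = 8,
                         step_trials = 100, step_prob = 0.02,
                         sequences = 2, seed = 3)
  sim <- simulate_openness(cfg)
  oa <- run_openness(sp, sim, clf = classifier_spec("knn"), kfold = 3, seed = 5)
  expect_identical(dim(oa$per_sequence), c(2L, 3L))
  expect_equal(oa$mean, colMeans(oa$per_sequence))
  expect_identical(oa$sizes, sim$sizes)
  # clean blobs stay near-perfect at every step
  expect_true(all(oa$per_sequence > 0.9))
  oa2 <- run_openness(sp, sim, clf = classifier_spec("knn"), kfold = 3, seed = 5)
  expect_identical(oa2$per_sequence, oa$per_sequence)
})

test_that("run_openness validates labels and configuration sources", {
  sp <- blob_space(n_subjects = 4)
  cfg <- openness_config(t1 = 2, tr = 5, steps = 2, n_subjects = 8, seed = 1)
  sim <- simulate_openness(cfg)
  expect_error(run_openness(sp, sim, clf = classifier_spec("knn"), kfold = 3),
               "absent from feature space")
  cfg2 <- openness_config(t1 = 2, tr = 3, steps = 2, n_subjects = 4, seed = 1)
  sim2 <- simulate_openness(cfg2)
  expect_error(run_openness(sp, sim2), "classifier and kfold")
})

test_that("openness accuracies round-trip through the tidy CSV", {
  sp <- blob_space(n_subjects = 6, n_per_subject = 9)
  cfg <- openness_config(t1 = 2, tr = 5, steps = 3, n_subjects = 6,
                         step_trials = 100, step_prob = 0.02,
                         sequences = 2, seed = 9)
  oa <- run_openness(sp, simulate_openness(cfg), clf = classifier_spec("knn"),
                     kfold = 3, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_openness_accuracy(oa, path)
  back <- read_openness_accuracy(path)
  expect_equal(back$per_sequence, oa$per_sequence, tolerance = 1e-12)
  expect_identical(back$sizes, oa$sizes)
  expect_identical(back$config_id, oa$config_id)
})
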