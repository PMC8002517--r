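test_that("openness_config enforces its feasibility invariants", {
  cfg <- openness_config(t1 = 5, tr = 97, steps = 24, n_subjects = 108)
  expect_s3_class(cfg, "openness_config")
  expect_error(openness_config(t1 = 5, tr = 108, steps = 24, n_subjects = 108),
               "open")
  expect_error(openness_config(t1 = 10, tr = 5, steps = 2, n_subjects = 20), "tr")
  expect_error(openness_config(t1 = 5, tr = 7, steps = 5, n_subjects = 20),
               "infeasible")
  expect_error(openness_config(t1 = 5, tr = 7, steps = 1, n_subjects = 20),
               "steps")
  expect_error(openness_config(t1 = 5, tr = 7, steps = 2, n_subjects = 20,
                               step_prob = 0), "step_prob")
})

test_that("size sequences increase strictly from t1 to tr", {
  cfg <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12,
                         step_trials = 100, step_prob = 0.02, seed = 5)
  sizes <- simulate_sizes(cfg)
  expect_length(sizes, 4L)
  expect_identical(sizes[1], 3L)
  expect_identical(sizes[4], 9L)
  expect_true(all(diff(sizes) >= 1))
  expect_identical(simulate_sizes(cfg), sizes)  # deterministic
  one <- openness_config(t1 = 4, tr = 4, steps = 1, n_subjects = 12)
  expect_identical(simulate_sizes(one), 4L)
})

test_that("incompatible step laws fail with a clear message", {
  # increments of at least 10 each cannot sum to tr - t1 = 2
  cfg <- openness_config(t1 = 3, tr = 5, steps = 3, n_subjects = 12,
                         step_trials = 10, step_prob = 1)
  expect_error(simulate_sizes(cfg, max_attempts = 50L), "summing to")
})

test_that("label sequences are nested, sized by T, and drawn from 1..E", {
  cfg <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12,
                         step_trials = 100, step_prob = 0.02,
                         sequences = 4, seed = 2)
  sim <- simulate_openness(cfg)
  expect_length(sim$sequences, 4L)
  for (sq in sim$sequences) {
    for (n in seq_along(sq)) {
      expect_length(sq[[n]], sim$sizes[n])
      expect_true(all(sq[[n]] %in% 1:12))
      if (n > 1) expect_true(all(sq[[n - 1]] %in% sq[[n]]))
    }
  }
})

test_that("adding sequences never perturbs earlier sequences", {
  base <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12,
                          step_trials = 100, step_prob = 0.02,
                          sequences = 2, seed = 6)
  more <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12,
                          step_trials = 100, step_prob = 0.02,
                          sequences = 5, seed = 6)
  expect_identical(simulate_labels(base), simulate_labels(more)[1:2])
})

test_that("simulate_labels rejects size sequences that break the config", {
  cfg <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12)
  expect_error(simulate_labels(cfg, sizes = c(3, 5, 9)), "invalid size sequence")
  expect_error(simulate_labels(cfg, sizes = c(3, 5, 5, 9)), "invalid size sequence")
  expect_error(simulate_labels(cfg, sizes = c(4, 5, 7, 9)), "invalid size sequence")
})

test_that("openness simulations round-trip through JSON", {
  cfg <- openness_config(t1 = 3, tr = 9, steps = 4, n_subjects = 12,
                         step_trials = 100, step_prob = 0.02,
                         sequences = 3, seed = 8)
  sim <- simulate_openness(cfg)
  path <- tempfile(fileext = ".json")
  write_openness(sim, path)
  back <- read_openness(path)
  expect_identical(back$sizes, sim$sizes)
  expect_identical(back$sequences, sim$sequences)
  expect_identical(unclass(back$config), unclass(sim$config))
})
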