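test_that("generation is deterministic given the spec seed", {
  a <- small_cohort(seed = 3)
  b <- small_cohort(seed = 3)
  expect_identical(a$recordings[[2]]$samples, b$recordings[[2]]$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- small_cohort(seed = 4)
  expect_false(identical(a$recordings[[2]]$samples, c$recordings[[2]]$samples))
})

test_that("cohort has the requested shape and labels", {
  co <- small_cohort(n_subjects = 5, n_channels = 4, duration = 10)
  expect_length(co$recordings, 5L)
  rec <- co$recordings[[3]]
  expect_s3_class(rec, "eeg_recording")
  expect_identical(dim(rec$samples), c(4L, 1600L))
  expect_identical(rec$subject_label, 3L)
  expect_identical(rec$channel_labels, sprintf("Ch%02d", 1:4))
  expect_identical(nrow(co$ground_truth), 20L)  # E * H rows
})

test_that("ground-truth poles lie inside the identity band", {
  co <- small_cohort(n_subjects = 6, n_channels = 4)
  expect_true(all(co$ground_truth$pole_freq_hz >= 30))
  expect_true(all(co$ground_truth$pole_freq_hz <= 50))
  # plus-sum AR(2) coefficients of a resonance: a2 = -r^2 in (-1, 0)
  expect_true(all(co$ground_truth$a2 > -1 & co$ground_truth$a2 < 0))
})

test_that("separability 0 degenerates to identical subjects", {
  co <- small_cohort(n_subjects = 5, separability = 0)
  gt <- co$ground_truth
  for (ch in unique(gt$channel)) {
    expect_length(unique(gt$a1[gt$channel == ch]), 1L)
    expect_length(unique(gt$a2[gt$channel == ch]), 1L)
  }
})

test_that("separability spreads the subject pole frequencies", {
  hi <- small_cohort(n_subjects = 6, separability = 1, seed = 2)
  lo <- small_cohort(n_subjects = 6, separability = 0.2, seed = 2)
  spread <- function(co) diff(range(tapply(co$ground_truth$pole_freq_hz,
                                           co$ground_truth$subject, mean)))
  expect_gt(spread(hi), spread(lo))
})

test_that("spectral power concentrates in the identity band when planted", {
  co_hi <- small_cohort(n_subjects = 3, n_channels = 3, duration = 20, seed = 9)
  co_0 <- small_cohort(n_subjects = 3, n_channels = 3, duration = 20, seed = 9,
                       separability = 0)
  frac_hi <- spectral_check(co_hi, c(30, 50))
  frac_0 <- spectral_check(co_0, c(30, 50))
  expect_length(frac_hi, 3L)
  expect_true(all(frac_hi > frac_0))
  # a pure white-noise cohort spends roughly the proportional share of its
  # power in any band: (50 - 30) / 80 = 0.25
  set.seed(1)
  wn <- list(eeg_recording(matrix(rnorm(2 * 3200), 2), 160, c("A", "B"), 1L))
  expect_equal(mean(spectral_check(wn, c(30, 50))), 0.25, tolerance = 0.05)
})

test_that("spec validation names the offending field", {
  expect_error(synthetic_cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(synthetic_cohort_spec(4, identity_band = c(30, 90)), "identity_band")
  expect_error(synthetic_cohort_spec(4, identity_band = c(50, 30)), "identity_band")
  expect_error(synthetic_cohort_spec(4, separability = -1), "separability")
  expect_error(synthetic_cohort_spec(4, noise_sd = -1), "noise_sd")
  expect_error(spectral_check(list(), c(4, 8)), "empty")
  expect_error(spectral_check(small_cohort(), c(8, 4)), "band")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(small_cohort(seed = 99))
  expect_identical(.Random.seed, before)
})
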