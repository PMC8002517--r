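# Shared fixtures: small synthetic cohorts and pipeline configurations kept
# tiny so the unit suite stays fast; scale-sensitive properties live in
# test-acceptance.R.

small_cohort <- function(n_subjects = 4, n_channels = 3, duration = 15,
                         seed = 7, ...) {
  generate_cohort(synthetic_cohort_spec(
    n_subjects = n_subjects, n_channels = n_channels, duration = duration,
    identity_band = c(30, 50), seed = seed, ...))
}

small_config <- function(n_channels = 3, duration = 15, ...) {
  pipeline_config(channel_set = sprintf("Ch%02d", seq_len(n_channels)),
                  duration = duration, ar_order = 2, band = c(30, 50),
                  filter_order = 4, ...)
}

# A trivially separable feature space: one Gaussian blob per subject.
blob_space <- function(n_subjects = 4, n_per_subject = 9, d = 4,
                       spread = 0.05, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_subjects * d, sd = 3), n_subjects, d)
  m <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sweep(matrix(rnorm(n_per_subject * d, sd = spread), n_per_subject, d),
          2, centers[s, ], `+`)
  }))
  colnames(m) <- paste0("f", seq_len(d))
  structure(list(matrix = m,
                 labels = rep(seq_len(n_subjects), each = n_per_subject),
                 config_id = "blob", n_per_subject = n_per_subject,
                 config = NULL),
            class = "feature_space")
}
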