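# Shared tiny fixtures, built once per test run.

tinyPhantomConfig <- function(seed = 7L, noise_sd = 0.02)
  phantomConfig(image_size = 32L, n_slices = 4L, noise_sd = noise_sd, seed = seed)

# A small on-disk cohort reused across tests (generated once per session).
tinyCohortDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "tiny_cohort")
      generateCohort(cohortSpec(10, 7, 3, 10, 7, 3), tinyPhantomConfig(), d)
      dir <<- d
    }
    dir
  }
})

# Synthetic, directly-separable feature sequences for classifier tests:
# class "soft" has low-variance maps, "hard" high-variance, mimicking what
# the encoder extracts from the phantom texture classes.
makeSyntheticFeatures <- function(n_patients, seq_length = 6L, side = 4L,
                                  seed = 1L, sd_soft = 0.2, sd_hard = 1.0) {
  withSeed(seed, {
    labels <- rep(c("soft", "hard"), length.out = n_patients)
    feats <- lapply(seq_len(n_patients), function(i) {
      s <- if (labels[i] == "soft") sd_soft else sd_hard
      new("FeatureSequence", patientId = sprintf("S%03d", i),
          features = array(stats::rnorm(seq_length * side * side, sd = s),
                           dim = c(seq_length, side, side)))
    })
    names(feats) <- sprintf("S%03d", seq_len(n_patients))
    list(features = feats,
         labels = stats::setNames(labels, names(feats)))
  })
}

# internal helper used directly in tests
withSeed <- pituitexture:::withSeed
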