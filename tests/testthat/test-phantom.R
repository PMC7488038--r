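test_that("slice generation is deterministic and bounded", {
  cfg <- tinyPhantomConfig()
  a1 <- generateSlice("T1", "soft", 0L, cfg, seed = 1L)
  a2 <- generateSlice("T1", "soft", 0L, cfg, seed = 1L)
  expect_identical(a1, a2)
  expect_true(all(a1 >= -1 & a1 <= 1))
  b <- generateSlice("T1", "soft", 0L, cfg, seed = 2L)
  expect_false(identical(a1, b))
})

test_that("invalid domain, class or slice index are rejected", {
  cfg <- tinyPhantomConfig()
  expect_error(generateSlice("T1C", "soft", 0L, cfg), "domain")
  expect_error(generateSlice("T1", "squishy", 0L, cfg), "texture_class")
  expect_error(generateSlice("T1", "soft", cfg$n_slices, cfg), "slice_index")
})

test_that("domain B equals the invertible transform of domain A when noiseless", {
  cfg <- phantomConfig(image_size = 32L, n_slices = 4L, noise_sd = 0, seed = 3L)
  a <- generateSlice("T1", "hard", 2L, cfg)
  b <- generateSlice("T2", "hard", 2L, cfg)
  expect_equal(domainTransform(a, cfg), b, tolerance = 1e-12)
  # round trip A -> B -> A is exact to numeric tolerance
  expect_equal(domainTransform(domainTransform(a, cfg), cfg, inverse = TRUE), a,
               tolerance = 1e-6)
})

test_that("hard-texture slices have larger within-lesion local variance than soft", {
  cfg <- tinyPhantomConfig()
  stat <- function(class, i) {
    ps <- deriveSeed(100L + i, class)
    s <- generateSlice("T1", class, i %% cfg$n_slices, cfg, seed = ps)
    textureStatistic(s, lesionMask(i %% cfg$n_slices, cfg, ps))
  }
  soft <- vapply(1:50, function(i) stat("soft", i), numeric(1))
  hard <- vapply(1:50, function(i) stat("hard", i), numeric(1))
  expect_gt(mean(hard), mean(soft))
  # a midpoint threshold separates the classes with >= 95% accuracy
  thr <- (mean(soft) + mean(hard)) / 2
  acc <- mean(c(hard > thr, soft <= thr))
  expect_gte(acc, 0.95)
})

test_that("cohort generation matches the requested composition", {
  d <- tinyCohortDir()
  m <- readManifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(m), 10L)
  expect_equal(sum(m$domain_t1 & !m$domain_t2), 7L)  # 7 patients lack domain B
  expect_equal(sum(m$domain_t2 & !m$domain_t1), 3L)
  expect_equal(sum(!is.na(m$label)), 10L)
  expect_true(all(file.exists(file.path(d, sprintf(
    "%s_%s.nii.gz", m$patient_id, ifelse(m$domain_t1, "T1", "T2"))))))
  # hidden truth covers everyone
  truth <- utils::read.csv(file.path(d, ".truth.csv"))
  expect_equal(nrow(truth), 10L)
  expect_true(all(truth$label %in% c("soft", "hard")))
})

test_that("an unbalanced labeled cohort reproduces the expected manifest counts", {
  # composition with 374 patients (280 T1-only / 94 T2-only, 152 labeled of
  # which 112/40) validated at spec level; generation exercised at 1/10 scale
  spec <- cohortSpec(374, 280, 94, 152, 112, 40)
  expect_equal(spec$n_patients, 374L)
  d <- file.path(tempdir(), "scaled_cohort")
  m <- generateCohort(cohortSpec(37, 28, 9, 15, 11, 4), tinyPhantomConfig(9L), d)
  expect_equal(nrow(m), 37L)
  expect_equal(sum(m$domain_t1), 28L)
  expect_equal(sum(!is.na(m$label) & m$domain_t1), 11L)
  expect_equal(sum(!is.na(m$label) & m$domain_t2), 4L)
})

test_that("empty and inconsistent cohort specs behave as documented", {
  d <- file.path(tempdir(), "empty_cohort")
  m <- generateCohort(cohortSpec(0, 0, 0, 0, 0, 0), tinyPhantomConfig(), d)
  expect_equal(nrow(m), 0L)
  expect_equal(length(list.files(d, pattern = "nii")), 0L)
  expect_error(cohortSpec(10, 5, 3, 2, 1, 1), "n_patients")
  expect_error(cohortSpec(10, 7, 3, 5, 1, 1), "n_labeled")
  expect_error(cohortSpec(10, 7, 3, 9, 8, 1), "group sizes")
})

test_that("identical (config, seed) yields byte-identical cohorts on disk", {
  cfg <- tinyPhantomConfig(21L)
  d1 <- file.path(tempdir(), "repro1")
  d2 <- file.path(tempdir(), "repro2")
  generateCohort(cohortSpec(3, 2, 1, 2, 1, 1), cfg, d1)
  generateCohort(cohortSpec(3, 2, 1, 2, 1, 1), cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})
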