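test_that("generator preserves shape, bounds outputs in (-1, 1), and rejects bad sizes", {
  gen <- buildGenerator(generatorSpec(base_channels = 4L), seed = 2)
  x64 <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  y <- applyNetwork(gen, x64)
  expect_equal(dim(y), dim(x64))
  expect_true(all(y > -1 & y < 1))
  x32 <- array(runif(32 * 32, -1, 1), c(32, 32, 1, 2))
  expect_equal(dim(applyNetwork(gen, x32)), dim(x32))
  x60 <- array(0, c(60, 60, 1, 1))
  expect_error(applyNetwork(gen, x60), "divisible")
})

test_that("discriminator produces a finite patch score map that scales with input", {
  dsc <- buildDiscriminator(discriminatorSpec(n_layers = 4L, base_channels = 4L),
                            seed = 3)
  s64 <- applyNetwork(dsc, array(1, c(64, 64, 1, 1)))
  expect_equal(dim(s64)[1:3], c(4L, 4L, 1L))   # four halvings of 64
  s128 <- applyNetwork(dsc, array(-1, c(128, 128, 1, 1)))
  expect_equal(dim(s128)[1:2], 2L * dim(s64)[1:2])
  expect_true(all(is.finite(s64)) && all(is.finite(s128)))
})

test_that("adversarial loss follows the real=1 / fake=0 convention", {
  ones <- array(1, c(2, 2, 1, 1))
  zeros <- array(0, c(2, 2, 1, 1))
  expect_equal(adversarialLoss(ones, 1), 0)
  expect_equal(adversarialLoss(zeros, 1), 1)  # (0 - 1)^2
  expect_equal(adversarialLoss(ones, 0), 1)
  expect_error(adversarialLoss(ones, 0.5), "target")
})

test_that("cycle-consistency loss is the symmetric mean absolute difference", {
  x <- matrix(c(0, 1), 1, 2)
  y <- matrix(c(1, 1), 1, 2)
  expect_equal(cycleConsistencyLoss(x, x), 0)
  expect_equal(cycleConsistencyLoss(x, y), 0.5)
  expect_equal(cycleConsistencyLoss(y, x), 0.5)
  expect_error(cycleConsistencyLoss(x, matrix(0, 2, 2)), "shape")
})

test_that("zero-epoch training returns an initialized bundle with empty history", {
  cfg <- tinyPhantomConfig()
  t1 <- list(phantomSequence("A", "T1", "soft", cfg))
  t2 <- list(phantomSequence("B", "T2", "hard", cfg))
  res <- trainCycleGAN(t1, t2, ganTrainConfig(epochs = 0L),
                       generatorSpec(base_channels = 4L),
                       discriminatorSpec(base_channels = 4L))
  expect_s4_class(res$bundle, "ConverterBundle")
  expect_false(res$bundle@trained)
  expect_equal(nrow(res$history), 0L)
  expect_error(trainCycleGAN(list(), t2, ganTrainConfig(epochs = 0L)), "empty")
})

test_that("short scaled training reduces the cycle loss and logs one row per epoch", {
  cfg <- phantomConfig(image_size = 16L, n_slices = 4L, seed = 19L)
  t1 <- lapply(sprintf("A%d", 1:5), function(p)
    phantomSequence(p, "T1", if (nchar(p) %% 2) "soft" else "hard", cfg))
  t2 <- lapply(sprintf("B%d", 1:3), function(p) phantomSequence(p, "T2", "soft", cfg))
  gcfg <- ganTrainConfig(epochs = 8L, batch_size = 10L, seed = 5L)
  res <- trainCycleGAN(t1, t2, gcfg,
                       generatorSpec(n_down = 2L, n_up = 2L, base_channels = 4L),
                       discriminatorSpec(n_layers = 2L, base_channels = 4L))
  expect_equal(nrow(res$history), 8L)
  expect_lt(mean(tail(res$history$cycle, 3)), mean(head(res$history$cycle, 3)))
  expect_true(res$bundle@trained)

  # determinism: same config and seed reproduces the loss history exactly
  res2 <- trainCycleGAN(t1, t2, gcfg,
                        generatorSpec(n_down = 2L, n_up = 2L, base_channels = 4L),
                        discriminatorSpec(n_layers = 2L, base_channels = 4L))
  expect_equal(res2$history, res$history, tolerance = 1e-12)

  # translation contract on the trained bundle
  tr <- translate(t1[[1]], res$bundle, "T1->T2")
  expect_equal(length(tr), length(t1[[1]]))
  expect_equal(sequenceDomain(tr), "T2")
  expect_equal(sequenceProvenance(tr), "generated")
  expect_error(translate(t1[[1]], res$bundle, "T2->T1"), "inconsistent")
})

test_that("amplification synthesizes exactly the missing domains", {
  d <- tinyCohortDir()
  co <- loadCohort(d)
  bundle <- initConverterBundle(generatorSpec(n_down = 2L, n_up = 2L, base_channels = 4L),
                                discriminatorSpec(n_layers = 2L, base_channels = 4L))
  expect_warning(amp <- amplifyDataset(co, bundle), "untrained")
  m <- amp$manifest
  expect_true(all(m$domain_t1 & m$domain_t2))
  expect_equal(sum(m$generated_t2), 7L)  # the 7 T1-only patients
  expect_equal(sum(m$generated_t1), 3L)
  # a patient that had both domains untouched (none here, so check provenance)
  pid <- m$patient_id[m$generated_t2][1]
  expect_equal(sequenceProvenance(amp$sequences[[pid]][["T2"]]), "generated")
  expect_equal(sequenceProvenance(amp$sequences[[pid]][["T1"]]), "real")
  # every labeled patient now supports a full multi-sequence of length 2N
  ms <- assembleMultiSequence(amp$sequences[[pid]][["T1"]], amp$sequences[[pid]][["T2"]])
  expect_equal(length(ms), 2L * 4L)
})
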