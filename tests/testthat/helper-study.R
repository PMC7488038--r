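# The desk-scale study configuration: a 40-patient two-domain phantom cohort
# at 32x32 run through the full chain (converter -> amplification ->
# autoencoder -> CRNN). Shared by the end-to-end tests; the same conditions
# are used by scripts/acceptance.R.

scaledStudyGenSpec <- function() generatorSpec(n_down = 3L, n_up = 3L, base_channels = 8L)
scaledStudyDiscSpec <- function() discriminatorSpec(n_layers = 3L, base_channels = 8L)

runScaledStudy <- function(seed = 11L, dir = file.path(tempdir(), "scaled_study")) {
  cfg <- phantomConfig(image_size = 32L, seed = deriveSeed(seed, "phantom"))
  if (!file.exists(file.path(dir, "manifest.csv")))
    generateCohort(cohortSpec(40, 28, 12, 40, 28, 12), cfg, dir)
  cohort <- loadCohort(dir)
  m <- cohort$manifest

  # domain converter, trained unpaired on all available sequences
  t1 <- lapply(m$patient_id[m$domain_t1], function(p) cohort$sequences[[p]][["T1"]])
  t2 <- lapply(m$patient_id[m$domain_t2], function(p) cohort$sequences[[p]][["T2"]])
  gan <- trainCycleGAN(t1, t2,
                       ganTrainConfig(epochs = 15L, batch_size = 16L,
                                      learning_rate = 1e-3,
                                      seed = deriveSeed(seed, "gan")),
                       scaledStudyGenSpec(), scaledStudyDiscSpec())

  # cross-domain error against the phantom's hidden ground truth
  maeFor <- function(bundle) {
    ids <- m$patient_id[m$domain_t1][1:6]
    mean(vapply(ids, function(pid) {
      gen <- translate(cohort$sequences[[pid]][["T1"]], bundle, "T1->T2")
      tru <- phantomGroundTruth(pid, "T2", dir, cfg)
      mean(abs(unlist(sequenceSlices(gen)) - unlist(sequenceSlices(tru))))
    }, numeric(1)))
  }
  untrained <- initConverterBundle(scaledStudyGenSpec(), scaledStudyDiscSpec(),
                                   seed = deriveSeed(seed, "gan"))
  mae_untrained <- maeFor(untrained)
  mae_trained <- maeFor(gan$bundle)

  # amplify and assemble multi-sequences for every (labeled) patient
  amp <- amplifyDataset(cohort, gan$bundle)
  seqs <- lapply(amp$manifest$patient_id, function(pid)
    assembleMultiSequence(amp$sequences[[pid]][["T1"]],
                          amp$sequences[[pid]][["T2"]]))
  names(seqs) <- amp$manifest$patient_id

  # unsupervised feature learning on a fixed 8-patient subset
  ae <- trainAutoencoder(seqs[1:8],
                         autoencoderSpec(dense_layers_per_block = 2L,
                                         growth_rate = 4L, steps = 100L,
                                         batch_size = 64L),
                         seed = deriveSeed(seed, "ae"))
  feats <- lapply(seqs, function(s) extractFeatures(s, ae$encoder))
  truth <- utils::read.csv(file.path(dir, ".truth.csv"))
  labels <- stats::setNames(truth$label, truth$patient_id)

  # sequence-level classification, 3 seeds, one 70/15/15 split
  spl <- makeSplits(names(labels),
                    splitSpec(repeats = 1L, seed = deriveSeed(seed, "split")))[[1]]
  accs <- vapply(1:3, function(s) {
    fit <- trainCrnn(feats[spl$train], labels[spl$train],
                     feats[spl$validation], labels[spl$validation],
                     crnnSpec(conv_channels = c(8L, 16L), hidden_size = 32L,
                              batch_size = 7L, learning_rate = 2e-3,
                              max_epochs = 60L),
                     earlyStopSpec(patience = 8L),
                     seed = deriveSeed(seed, paste0("crnn", s)))
    pred <- predictCrnn(fit$model, feats[spl$test])
    mean(pred$label == labels[spl$test])
  }, numeric(1))

  list(dir = dir, cohort = cohort, gan = gan,
       mae_untrained = mae_untrained, mae_trained = mae_trained,
       ae_history = ae$history, crnn_accs = accs,
       labels = labels)
}
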