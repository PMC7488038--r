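# End-to-end orchestration of the three experimental arms (T1-only, T2-only,
# multi-sequence): amplify -> autoencode -> extract -> split -> classify ->
# evaluate, with per-stage artifacts so an interrupted run resumes at the
# first missing stage. A single global seed fans out to per-stage seeds via
# deriveSeed(); the patient splits are derived from the global seed alone
# (not the arm), so all arms are evaluated on identical partitions and the
# paired signed-rank comparison is valid.

#' Pipeline configuration
#'
#' @param arm "t1", "t2" or "multi".
#' @param output_dir artifact directory (created if needed).
#' @param cohort_dir existing cohort directory (with \code{manifest.csv});
#'   if NULL a phantom cohort is generated into
#'   \code{file.path(output_dir, "cohort")}.
#' @param phantom_spec,phantom_config cohort composition and phantom
#'   settings used when generating (defaults mirror the 374-patient /
#'   152-labeled composition of the motivating cohort).
#' @param gan a \code{ganTrainConfig()}.
#' @param gen_spec,disc_spec converter architectures.
#' @param ae an \code{autoencoderSpec()}.
#' @param crnn a \code{crnnSpec()}.
#' @param stop_spec an \code{earlyStopSpec()}.
#' @param split a \code{splitSpec()}.
#' @param seed global seed; stage seeds are derived from it.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(arm = "multi", output_dir,
                           cohort_dir = NULL,
                           phantom_spec = cohortSpec(374, 280, 94, 152, 112, 40),
                           phantom_config = phantomConfig(),
                           gan = ganTrainConfig(),
                           gen_spec = generatorSpec(),
                           disc_spec = discriminatorSpec(),
                           ae = autoencoderSpec(),
                           crnn = crnnSpec(),
                           stop_spec = earlyStopSpec(),
                           split = splitSpec(),
                           seed = 1L) {
  cfg <- list(arm = assertChoice(arm, c("t1", "t2", "multi"), "arm"),
              output_dir = output_dir, cohort_dir = cohort_dir,
              phantom_spec = phantom_spec, phantom_config = phantom_config,
              gan = gan, gen_spec = gen_spec, disc_spec = disc_spec,
              ae = ae, crnn = crnn, stop_spec = stop_spec, split = split,
              seed = assertCount(seed, "seed", 0L))
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort_dir does not exist: ", cohort_dir)
  class(cfg) <- "PipelineConfig"
  cfg
}

pipelineLog <- function(dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE)
  message(line)
}

# Run `build()` unless the artifact already exists; either way return it.
stageArtifact <- function(dir, name, build) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (file.exists(path)) {
    pipelineLog(dir, "stage %-12s reusing %s", name, basename(path))
    return(readRDS(path))
  }
  pipelineLog(dir, "stage %-12s computing ...", name)
  out <- tryCatch(build(), error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  saveRDS(out, path)
  out
}

armSequences <- function(arm, cohort) {
  lapply(cohort$sequences, function(s) {
    switch(arm,
           t1 = s[["T1"]],
           t2 = s[["T2"]],
           multi = assembleMultiSequence(s[["T1"]], s[["T2"]]))
  })
}

#' Run the grading pipeline for one experimental arm
#'
#' Stages execute in order: cohort (generate or load) -> converter training
#' (all patients, both domains, unpaired) -> amplification (every patient
#' gains its missing domain) -> autoencoder training (all slices of the arm,
#' unsupervised) -> feature extraction (labeled patients) -> repeated splits
#' -> CRNN training and evaluation per replicate. Each stage persists an
#' artifact under \code{output_dir}; deleting a stage's artifact and
#' rerunning recomputes that stage and everything downstream, while earlier
#' stages are reused.
#'
#' @param config a \code{pipelineConfig()}.
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  odir <- config$output_dir
  arm <- config$arm

  cohortDir <- config$cohort_dir %||% file.path(odir, "cohort")
  if (is.null(config$cohort_dir) && !file.exists(file.path(cohortDir, "manifest.csv"))) {
    pipelineLog(odir, "stage %-12s generating phantom cohort (%d patients)",
                "cohort", config$phantom_spec$n_patients)
    cfgP <- config$phantom_config
    cfgP$seed <- deriveSeed(config$seed, "phantom")
    generateCohort(config$phantom_spec, cfgP, cohortDir)
  }
  cohort <- loadCohort(cohortDir)

  gan <- stageArtifact(odir, "gan", function() {
    t1 <- lapply(which(cohort$manifest$domain_t1),
                 function(i) cohort$sequences[[cohort$manifest$patient_id[i]]][["T1"]])
    t2 <- lapply(which(cohort$manifest$domain_t2),
                 function(i) cohort$sequences[[cohort$manifest$patient_id[i]]][["T2"]])
    cfg <- config$gan
    cfg$seed <- deriveSeed(config$seed, "gan")
    trainCycleGAN(t1, t2, cfg, config$gen_spec, config$disc_spec)
  })

  amplified <- stageArtifact(odir, "amplified", function()
    amplifyDataset(cohort, gan$bundle))

  ae <- stageArtifact(odir, paste0("ae_", arm), function() {
    seqs <- armSequences(arm, amplified)
    trainAutoencoder(seqs, config$ae, seed = deriveSeed(config$seed, paste0("ae", arm)))
  })

  featStage <- stageArtifact(odir, paste0("features_", arm), function() {
    lab <- amplified$manifest[!is.na(amplified$manifest$label), , drop = FALSE]
    seqs <- armSequences(arm, list(sequences =
      amplified$sequences[lab$patient_id], manifest = lab))
    list(features = lapply(seqs, function(s) extractFeatures(s, ae$encoder)),
         labels = stats::setNames(lab$label, lab$patient_id))
  })

  splits <- makeSplits(names(featStage$labels), {
    sp <- config$split
    sp$seed <- deriveSeed(config$seed, "split")
    sp
  })

  report <- stageArtifact(odir, paste0("report_", arm), function() {
    rows <- list()
    preds <- list()
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      fit <- trainCrnn(featStage$features[sp$train], featStage$labels[sp$train],
                       featStage$features[sp$validation], featStage$labels[sp$validation],
                       config$crnn, config$stop_spec,
                       seed = deriveSeed(config$seed, paste0("crnn", arm, r)))
      for (spl in c("train", "test", "validation")) {
        pred <- predictCrnn(fit$model, featStage$features[sp[[spl]]])
        met <- computeMetrics(pred$label, unname(featStage$labels[sp[[spl]]]))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, split = spl, accuracy = met$accuracy,
          precision = met$precision, recall = met$recall, f1 = met$f1)
        if (spl == "test")
          preds[[r]] <- cbind(replicate = r, pred)
      }
      pipelineLog(odir, "stage %-12s replicate %d/%d done (%d epochs)",
                  paste0("crnn_", arm), r, length(splits), nrow(fit$history))
    }
    list(metrics = do.call(rbind, rows), predictions = do.call(rbind, preds))
  })

  rep <- new("EvaluationReport", perReplicate = report$metrics,
             summary = summarizeReplicates(report$metrics),
             pairedTests = data.frame(), arm = arm)
  utils::write.csv(report$metrics, file.path(odir, paste0("metrics_", arm, ".csv")),
                   row.names = FALSE)
  utils::write.csv(report$predictions,
                   file.path(odir, paste0("predictions_", arm, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(arm = arm, summary = rep@summary, per_replicate = report$metrics),
    file.path(odir, paste0("report_", arm, ".json")),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  rep
}

#' Run several arms on identical splits and compare them
#'
#' Convenience wrapper: runs \code{runPipeline()} for each requested arm
#' (sharing the cohort, converter and splits through the common artifact
#' directory and global seed) and pairs every non-reference arm with the
#' reference using the signed-rank test on per-replicate test accuracies.
#'
#' @param config a \code{pipelineConfig()}; its \code{arm} field is ignored.
#' @param arms character vector of arms to run.
#' @param reference_arm the arm the others are paired against.
#' @return list with \code{reports} (named list of
#'   \code{EvaluationReport}s) and \code{comparison} (the
#'   \code{compareArms()} table, also written to
#'   \code{forest_plot.csv} in the artifact directory).
#' @export
runArmComparison <- function(config, arms = c("t1", "t2", "multi"),
                             reference_arm = "multi") {
  reports <- list()
  for (a in arms) {
    cfg <- config
    cfg$arm <- a
    reports[[a]] <- runPipeline(cfg)
  }
  acc <- lapply(reports, function(r) {
    pr <- r@perReplicate
    pr$accuracy[pr$split == "test"][order(pr$replicate[pr$split == "test"])]
  })
  comparison <- compareArms(acc, reference_arm,
                            csv_path = file.path(config$output_dir, "forest_plot.csv"))
  ref <- reports[[reference_arm]]
  reports[[reference_arm]] <- new("EvaluationReport",
                                  perReplicate = ref@perReplicate,
                                  summary = ref@summary,
                                  pairedTests = comparison,
                                  arm = reference_arm)
  list(reports = reports, comparison = comparison)
}
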