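# Unpaired two-domain translation: two mirrored generator/discriminator
# pairs trained with alternating discriminator and generator updates under a
# least-squares adversarial objective plus a cycle-consistency penalty.

#' Training configuration for the domain converter
#'
#' @param epochs training epochs (120 by default; 0 returns an initialized,
#'   untrained bundle).
#' @param cycle_weight weight of the cycle-consistency term (lambda).
#' @param adversarial_loss_form "least-squares" (default) or "cross-entropy".
#' @param learning_rate Adam learning rate (2e-4, momentum 0.5 — the
#'   community default for this architecture family).
#' @param batch_size slices per update.
#' @param seed RNG seed for initialization, shuffling and batching.
#' @param keep which weights the returned bundle carries: "final" (default)
#'   or "best_disc" (the epoch with the lowest mean discriminator loss).
#' @return a validated list of class \code{"GanTrainConfig"}.
#' @export
ganTrainConfig <- function(epochs = 120L, cycle_weight = 10,
                           adversarial_loss_form = "least-squares",
                           learning_rate = 2e-4, batch_size = 8L, seed = 1L,
                           keep = "final") {
  cfg <- list(epochs = assertCount(epochs, "epochs", 0L),
              cycle_weight = assertNumber(cycle_weight, "cycle_weight", 0),
              adversarial_loss_form = assertChoice(
                adversarial_loss_form, c("least-squares", "cross-entropy"),
                "adversarial_loss_form"),
              learning_rate = assertNumber(learning_rate, "learning_rate", 0),
              batch_size = assertCount(batch_size, "batch_size", 1L),
              seed = assertCount(seed, "seed", 0L),
              keep = assertChoice(keep, c("final", "best_disc"), "keep"))
  class(cfg) <- "GanTrainConfig"
  cfg
}

#' Adversarial loss of a discriminator score map
#'
#' Least-squares form (default): mean over patches of
#' \eqn{(score - target)^2}, with target 1 for real inputs and 0 for
#' generated ones. The cross-entropy form applies a sigmoid to the scores
#' first.
#'
#' @param scores numeric array of patch scores.
#' @param target 0 (fake) or 1 (real).
#' @param form "least-squares" or "cross-entropy".
#' @return a nonnegative scalar.
#' @export
adversarialLoss <- function(scores, target, form = "least-squares") {
  if (!target %in% c(0, 1)) stop("target must be 0 (fake) or 1 (real)")
  assertChoice(form, c("least-squares", "cross-entropy"), "form")
  if (form == "least-squares") {
    mean((scores - target)^2)
  } else {
    p <- pmin(pmax(1 / (1 + exp(-scores)), 1e-7), 1 - 1e-7)
    -mean(target * log(p) + (1 - target) * log(1 - p))
  }
}

#' Cycle-consistency loss
#'
#' Mean absolute pixel difference between an image and its reconstruction
#' after translating to the other domain and back. Zero iff the round trip is
#' exact; symmetric in its arguments.
#'
#' @param original,reconstructed numeric arrays of identical shape.
#' @return a nonnegative scalar.
#' @export
cycleConsistencyLoss <- function(original, reconstructed) {
  if (!identical(dim(original), dim(reconstructed)))
    stop("shape mismatch between original and reconstruction")
  mean(abs(original - reconstructed))
}

#' Initialize an untrained converter bundle
#'
#' @param gen_spec a \code{generatorSpec()} shared by both generators.
#' @param disc_spec a \code{discriminatorSpec()} shared by both
#'   discriminators.
#' @param seed initialization seed.
#' @return a \code{\linkS4class{ConverterBundle}}.
#' @export
initConverterBundle <- function(gen_spec = generatorSpec(),
                                disc_spec = discriminatorSpec(), seed = 1L) {
  new("ConverterBundle",
      genT1ToT2 = buildGenerator(gen_spec, seed = deriveSeed(seed, "g12")),
      genT2ToT1 = buildGenerator(gen_spec, seed = deriveSeed(seed, "g21")),
      discT1 = buildDiscriminator(disc_spec, seed = deriveSeed(seed, "d1")),
      discT2 = buildDiscriminator(disc_spec, seed = deriveSeed(seed, "d2")),
      trained = FALSE, config = list())
}

slicesToBatch <- function(slices) {
  d <- dim(slices[[1]])
  array(unlist(slices, use.names = FALSE), dim = c(d[1], d[2], 1L, length(slices)))
}

# Gather every slice of a list of SpatialSequences (or matrices) into one
# [H, W, 1, n] array; sequences are flattened because the converter trains on
# individual slices.
gatherSlices <- function(seqs) {
  sl <- list()
  for (s in seqs) {
    if (is(s, "SpatialSequence")) sl <- c(sl, sequenceSlices(s))
    else if (is.matrix(s)) sl <- c(sl, list(s))
    else stop("expected SpatialSequence objects or matrices")
  }
  if (!length(sl)) stop("empty training set")
  slicesToBatch(sl)
}

advLossNode <- function(scores, target, form) {
  tgt <- adInput(array(target, dim = dim(adValue(scores))))
  if (form == "least-squares") adMseLoss(scores, tgt)
  else adBceLoss(adSigmoid(scores), tgt)
}

#' Train the two-domain converter
#'
#' Alternates, per batch, (a) a discriminator update with the generator
#' parameters fixed — real slices labeled 1, generated slices labeled 0 —
#' and (b) a generator update (adversarial term plus
#' \code{cycle_weight} times the cycle-consistency term) with the
#' discriminator parameters fixed. Returns the bundle plus per-epoch mean
#' discriminator, adversarial and cycle losses.
#'
#' @param t1_set,t2_set lists of \code{SpatialSequence}s (or slice matrices)
#'   from each domain; the two sets need not be paired or equally sized.
#' @param cfg a \code{ganTrainConfig()}.
#' @param gen_spec,disc_spec architecture specs (ignored when \code{bundle}
#'   is supplied).
#' @param bundle optionally resume from an existing
#'   \code{\linkS4class{ConverterBundle}}.
#' @return list with \code{bundle} (a \code{ConverterBundle}) and
#'   \code{history} (data.frame with one row per epoch: epoch, d_loss,
#'   g_adv, cycle).
#' @export
trainCycleGAN <- function(t1_set, t2_set, cfg = ganTrainConfig(),
                          gen_spec = generatorSpec(),
                          disc_spec = discriminatorSpec(), bundle = NULL) {
  x1 <- gatherSlices(t1_set)
  x2 <- gatherSlices(t2_set)
  if (is.null(bundle)) bundle <- initConverterBundle(gen_spec, disc_spec, cfg$seed)
  g12 <- bundle@genT1ToT2
  g21 <- bundle@genT2ToT1
  d1 <- bundle@discT1
  d2 <- bundle@discT2
  genParams <- c(collectParams(g12$params), collectParams(g21$params))
  discParams <- c(collectParams(d1$params), collectParams(d2$params))
  allParams <- c(genParams, discParams)
  history <- data.frame(epoch = integer(), d_loss = numeric(),
                        g_adv = numeric(), cycle = numeric())
  if (cfg$epochs == 0L) {
    return(list(bundle = bundle, history = history))
  }
  n1 <- dim(x1)[4]
  n2 <- dim(x2)[4]
  bs <- cfg$batch_size
  stepsPerEpoch <- max(1L, ceiling(max(n1, n2) / bs))
  best <- Inf
  bestSnap <- NULL
  tstep <- 0L
  withSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      dls <- gls <- cls <- numeric(stepsPerEpoch)
      for (st in seq_len(stepsPerEpoch)) {
        tstep <- tstep + 1L
        i1 <- sample.int(n1, min(bs, n1))
        i2 <- sample.int(n2, min(bs, n2))
        b1 <- x1[, , , i1, drop = FALSE]
        b2 <- x2[, , , i2, drop = FALSE]

        # generated slices for the discriminator step (no gradient into G)
        f2v <- applyNetwork(g12, b1)
        f1v <- applyNetwork(g21, b2)

        adTapeBegin()
        dl <- adLinComb(list(
          advLossNode(discForward(d1, adInput(b1)), 1, cfg$adversarial_loss_form),
          advLossNode(discForward(d1, adInput(f1v)), 0, cfg$adversarial_loss_form),
          advLossNode(discForward(d2, adInput(b2)), 1, cfg$adversarial_loss_form),
          advLossNode(discForward(d2, adInput(f2v)), 0, cfg$adversarial_loss_form)),
          c(0.5, 0.5, 0.5, 0.5))
        adBackward(dl)
        adamStep(discParams, lr = cfg$learning_rate, beta1 = 0.5, t = tstep)
        adZeroGrads(allParams)
        adTapeEnd()

        adTapeBegin()
        n1b <- adInput(b1)
        n2b <- adInput(b2)
        f2 <- genForward(g12, n1b)
        f1 <- genForward(g21, n2b)
        rec1 <- genForward(g21, f2)
        rec2 <- genForward(g12, f1)
        adv <- adLinComb(list(
          advLossNode(discForward(d2, f2), 1, cfg$adversarial_loss_form),
          advLossNode(discForward(d1, f1), 1, cfg$adversarial_loss_form)),
          c(1, 1))
        cyc <- adLinComb(list(adMaeLoss(rec1, n1b), adMaeLoss(rec2, n2b)), c(1, 1))
        gl <- adLinComb(list(adv, cyc), c(1, cfg$cycle_weight))
        adBackward(gl)
        adamStep(genParams, lr = cfg$learning_rate, beta1 = 0.5, t = tstep)
        adZeroGrads(allParams)
        adTapeEnd()

        dls[st] <- adValue(dl)
        gls[st] <- adValue(adv)
        cls[st] <- adValue(cyc) / 2
      }
      history <- rbind(history, data.frame(
        epoch = ep, d_loss = mean(dls), g_adv = mean(gls), cycle = mean(cls)))
      if (cfg$keep == "best_disc" && mean(dls) < best) {
        best <- mean(dls)
        bestSnap <- paramSnapshot(allParams)
      }
    }
  })
  if (cfg$keep == "best_disc" && !is.null(bestSnap))
    paramRestore(allParams, bestSnap)
  bundle@trained <- TRUE
  bundle@config <- unclass(cfg)
  list(bundle = bundle, history = history)
}

#' Translate a spatial sequence to the other domain
#'
#' @param seq a \code{\linkS4class{SpatialSequence}}.
#' @param bundle a \code{\linkS4class{ConverterBundle}}.
#' @param direction "T1->T2" or "T2->T1"; must match \code{seq}'s domain.
#' @return a \code{SpatialSequence} in the opposite domain with
#'   \code{provenance = "generated"}, same length and slice shape, slice
#'   order preserved.
#' @export
setGeneric("translate", function(seq, bundle, direction) standardGeneric("translate"))

#' @rdname translate
#' @export
setMethod("translate", signature(seq = "SpatialSequence", bundle = "ConverterBundle"),
  function(seq, bundle, direction) {
    assertChoice(direction, c("T1->T2", "T2->T1"), "direction")
    src <- if (direction == "T1->T2") "T1" else "T2"
    if (seq@domain != src)
      stop(sprintf("direction %s inconsistent with sequence domain %s",
                   direction, seq@domain))
    gen <- if (direction == "T1->T2") bundle@genT1ToT2 else bundle@genT2ToT1
    x <- slicesToBatch(seq@slices)
    y <- applyNetwork(gen, x)
    slices <- lapply(seq_len(dim(y)[4]), function(k) y[, , 1, k])
    new("SpatialSequence", patientId = seq@patientId,
        domain = if (src == "T1") "T2" else "T1",
        slices = slices, provenance = "generated")
  })

#' Amplify a cohort: synthesize every patient's missing domain
#'
#' Each patient lacking one domain gains it through the matching generator;
#' patients with both acquired domains are left untouched. The returned
#' manifest gains \code{generated_t1} / \code{generated_t2} flags, and every
#' labeled patient can afterwards be assembled into a full 2N-slice
#' multi-sequence.
#'
#' @param cohort a list with \code{manifest} and \code{sequences}, as from
#'   \code{loadCohort()}.
#' @param bundle a \code{\linkS4class{ConverterBundle}}; an untrained bundle
#'   raises a warning (useful for smoke tests), not an error.
#' @return a cohort list of the same shape with completed sequences and the
#'   flagged manifest.
#' @export
amplifyDataset <- function(cohort, bundle) {
  stopifnot(is(bundle, "ConverterBundle"))
  m <- cohort$manifest
  if (nrow(m) && any(!m$domain_t1 & !m$domain_t2))
    stop("every patient must have at least one acquired domain")
  if (!bundle@trained)
    warning("amplifying with an untrained converter bundle")
  m$generated_t1 <- FALSE
  m$generated_t2 <- FALSE
  for (i in seq_len(nrow(m))) {
    pid <- m$patient_id[i]
    if (!m$domain_t1[i]) {
      cohort$sequences[[pid]][["T1"]] <-
        translate(cohort$sequences[[pid]][["T2"]], bundle, "T2->T1")
      m$domain_t1[i] <- TRUE
      m$generated_t1[i] <- TRUE
    } else if (!m$domain_t2[i]) {
      cohort$sequences[[pid]][["T2"]] <-
        translate(cohort$sequences[[pid]][["T1"]], bundle, "T1->T2")
      m$domain_t2[i] <- TRUE
      m$generated_t2[i] <- TRUE
    }
  }
  cohort$manifest <- m
  cohort
}
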