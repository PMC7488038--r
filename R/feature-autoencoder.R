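# Unsupervised sequence feature extraction: the dense-block encoder /
# residual-block decoder pair is trained to reconstruct every available slice
# (labeled and unlabeled, acquired and generated alike), then the encoder
# alone maps each slice to a compact feature map.

#' Pixel reconstruction loss
#'
#' Mean squared pixel difference (default) or mean absolute difference
#' between an input slice and its reconstruction.
#'
#' @param input,output numeric arrays of identical shape.
#' @param loss "mse" or "mae".
#' @return a nonnegative scalar.
#' @export
reconstructionLoss <- function(input, output, loss = "mse") {
  if (!identical(dim(input), dim(output)))
    stop("shape mismatch between input and reconstruction")
  assertChoice(loss, c("mse", "mae"), "loss")
  if (loss == "mse") mean((input - output)^2) else mean(abs(input - output))
}

#' Train the autoencoder on all available slices
#'
#' Unsupervised: minimizes the pixel reconstruction loss over every slice of
#' every supplied sequence; labels play no role at this stage. One training
#' step is one epoch over the slice set (minibatched). The best-loss
#' parameters are kept.
#'
#' @param sequences list of \code{SpatialSequence} / \code{MultiSequence}
#'   objects or slice matrices (real and generated alike).
#' @param spec an \code{autoencoderSpec()}.
#' @param seed RNG seed for initialization, shuffling and batching.
#' @param encoder,decoder optionally resume from existing networks.
#' @return list with \code{encoder}, \code{decoder} and \code{history}
#'   (data.frame: step, loss — one row per step).
#' @export
trainAutoencoder <- function(sequences, spec = autoencoderSpec(), seed = 1L,
                             encoder = NULL, decoder = NULL) {
  sl <- list()
  for (s in sequences) {
    if (is(s, "SpatialSequence") || is(s, "MultiSequence"))
      sl <- c(sl, sequenceSlices(s))
    else if (is.matrix(s)) sl <- c(sl, list(s))
    else stop("expected sequence objects or matrices")
  }
  if (!length(sl)) stop("empty training set")
  x <- slicesToBatch(sl)
  if (is.null(encoder)) encoder <- buildEncoder(spec, seed = deriveSeed(seed, "enc"))
  if (is.null(decoder)) decoder <- buildDecoder(spec, seed = deriveSeed(seed, "dec"))
  params <- c(collectParams(encoder$params), collectParams(decoder$params))
  history <- data.frame(step = integer(), loss = numeric())
  if (spec$steps == 0L)
    return(list(encoder = encoder, decoder = decoder, history = history))
  n <- dim(x)[4]
  bs <- min(spec$batch_size, n)
  best <- Inf
  bestSnap <- NULL
  tstep <- 0L
  withSeed(seed, {
    for (stp in seq_len(spec$steps)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        tstep <- tstep + 1L
        adTapeBegin()
        xin <- adInput(xb)
        rec <- decForward(decoder, encForward(encoder, xin))
        lo <- if (spec$loss == "mse") adMseLoss(rec, xin) else adMaeLoss(rec, xin)
        adBackward(lo)
        adamStep(params, lr = spec$learning_rate, t = tstep)
        adZeroGrads(params)
        adTapeEnd()
        losses <- c(losses, adValue(lo))
      }
      history <- rbind(history, data.frame(step = stp, loss = mean(losses)))
      if (mean(losses) < best) {
        best <- mean(losses)
        bestSnap <- paramSnapshot(params)
      }
    }
  })
  if (!is.null(bestSnap)) paramRestore(params, bestSnap)
  list(encoder = encoder, decoder = decoder, history = history)
}

#' Extract the feature sequence of one patient
#'
#' Applies the encoder to every slice of the sequence in flattened order
#' (t1_1, t2_1, ... for a multi-sequence) and stacks the per-slice feature
#' maps into a 3-D array: sequence position x height' x width'.
#'
#' @param seq a \code{\linkS4class{SpatialSequence}} or
#'   \code{\linkS4class{MultiSequence}}.
#' @param encoder a trained (or initialized) encoder network.
#' @return a \code{\linkS4class{FeatureSequence}} whose first-axis length is
#'   the number of input slices (N or 2N).
#' @export
setGeneric("extractFeatures", function(seq, encoder) standardGeneric("extractFeatures"))

extractFeaturesImpl <- function(seq, encoder) {
  sl <- sequenceSlices(seq)
  x <- slicesToBatch(sl)
  y <- applyNetwork(encoder, x)  # [h', w', 1, n]
  feats <- aperm(array(y, dim = dim(y)[c(1, 2, 4)]), c(3, 1, 2))
  new("FeatureSequence", patientId = patientId(seq), features = feats)
}

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "SpatialSequence", extractFeaturesImpl)

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "MultiSequence", extractFeaturesImpl)
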