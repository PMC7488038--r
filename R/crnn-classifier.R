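# Sequence-level binary texture grading. One label per patient: the CRNN
# consumes a whole FeatureSequence and emits a single probability; no
# per-slice labels exist anywhere in the training interface.

#' Early-stopping rule
#'
#' Training stops once the monitored metric has failed to improve on its best
#' value for \code{patience} consecutive epochs; the best epoch's parameters
#' are restored when \code{restore_best} is on.
#'
#' @param monitor monitored quantity (only "val_loss" is computed).
#' @param patience epochs without improvement tolerated before stopping.
#' @param restore_best restore the best-epoch weights after stopping.
#' @return a validated list of class \code{"EarlyStopSpec"}.
#' @export
earlyStopSpec <- function(monitor = "val_loss", patience = 2L,
                          restore_best = TRUE) {
  sp <- list(monitor = assertChoice(monitor, "val_loss", "monitor"),
             patience = assertCount(patience, "patience", 0L),
             restore_best = assertFlag(restore_best, "restore_best"))
  class(sp) <- "EarlyStopSpec"
  sp
}

#' Trace the early-stopping rule over a loss sequence
#'
#' Pure bookkeeping, exposed for testability: given per-epoch monitor values,
#' returns the epoch training would stop after and the best epoch. A trace of
#' c(0.50, 0.40, 0.41, 0.42) with patience 2 stops after epoch 4 and restores
#' epoch 2.
#'
#' @param trace numeric vector of monitor values, one per epoch.
#' @param patience see \code{earlyStopSpec()}.
#' @return list with \code{stop_epoch} (NA if never triggered) and
#'   \code{best_epoch}.
#' @export
earlyStopTrace <- function(trace, patience = 2L) {
  best <- Inf
  bestEpoch <- NA_integer_
  wait <- 0L
  for (ep in seq_along(trace)) {
    if (trace[ep] < best) {
      best <- trace[ep]
      bestEpoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(stop_epoch = ep, best_epoch = bestEpoch))
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = bestEpoch)
}

featureBatch <- function(featureSeqs) {
  d <- dim(featureSeqs[[1]]@features)
  for (f in featureSeqs)
    if (!identical(dim(f@features), d))
      stop("all feature sequences must share dimensions")
  arr <- array(0, dim = c(length(featureSeqs), d))
  for (i in seq_along(featureSeqs)) arr[i, , , ] <- featureSeqs[[i]]@features
  arr
}

encodeLabels <- function(labels) {
  assertChoice(unique(labels)[1], c("soft", "hard"), "labels")
  if (!all(labels %in% c("soft", "hard"))) stop("labels must be 'soft' or 'hard'")
  as.numeric(labels == "soft")  # positive class = soft
}

#' Train the CRNN on labeled feature sequences
#'
#' Binary cross-entropy objective, Adam updates, dropout before the output
#' unit, and early stopping on the validation loss (the best-epoch weights
#' are restored). Exactly one label per patient is consumed.
#'
#' @param train_feats,val_feats lists of
#'   \code{\linkS4class{FeatureSequence}}s.
#' @param train_labels,val_labels character vectors of "soft"/"hard", one
#'   per patient; both classes must be present in the training set.
#' @param spec a \code{crnnSpec()}.
#' @param stop_spec an \code{earlyStopSpec()}.
#' @param seed RNG seed (initialization, shuffling, dropout masks).
#' @return list with \code{model} and \code{history} (data.frame: epoch,
#'   train_loss, val_loss).
#' @export
trainCrnn <- function(train_feats, train_labels, val_feats, val_labels,
                      spec = crnnSpec(), stop_spec = earlyStopSpec(), seed = 1L) {
  if (!length(train_feats) || !length(val_feats))
    stop("training and validation sets must be nonempty")
  y <- encodeLabels(train_labels)
  yv <- encodeLabels(val_labels)
  if (length(unique(y)) < 2L)
    stop("both texture classes must be present in the training set")
  xtr <- featureBatch(train_feats)
  xv <- featureBatch(val_feats)
  # standardize features with training-set statistics (stored in the model so
  # prediction applies the identical affine map)
  mu <- mean(xtr)
  sdv <- stats::sd(xtr)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xtr <- (xtr - mu) / sdv
  xv <- (xv - mu) / sdv
  d <- dim(xtr)
  model <- buildCrnn(spec, input_shape = d[2:4], seed = deriveSeed(seed, "crnn"))
  model$norm <- c(mu = mu, sd = sdv)
  params <- collectParams(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  n <- d[1]
  bs <- min(spec$batch_size, n)
  best <- Inf
  bestSnap <- NULL
  wait <- 0L
  tstep <- 0L
  withSeed(seed, {
    for (ep in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        tstep <- tstep + 1L
        adTapeBegin()
        p <- crnnForward(model, xtr[idx, , , , drop = FALSE], training = TRUE)
        lo <- adBceLoss(p, adInput(matrix(y[idx], ncol = 1)))
        adBackward(lo)
        adamStep(params, lr = spec$learning_rate, t = tstep)
        adZeroGrads(params)
        adTapeEnd()
        losses <- c(losses, adValue(lo))
      }
      pv <- crnnForward(model, xv, training = FALSE)
      vl <- adValue(adBceLoss(pv, adInput(matrix(yv, ncol = 1))))
      history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                           val_loss = vl))
      if (vl < best) {
        best <- vl
        bestSnap <- paramSnapshot(params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= stop_spec$patience) break
      }
    }
  })
  if (stop_spec$restore_best && !is.null(bestSnap)) paramRestore(params, bestSnap)
  list(model = model, history = history)
}

#' Predict the texture grade of feature sequences
#'
#' Dropout is disabled at inference, so repeated calls are identical.
#' Probabilities at or above the decision threshold are labeled "soft" (the
#' positive class; ties resolve to "soft").
#'
#' @param model a trained CRNN from \code{trainCrnn()}.
#' @param features a \code{\linkS4class{FeatureSequence}} or a list of them.
#' @return data.frame with columns \code{patient_id}, \code{probability},
#'   \code{label}.
#' @export
predictCrnn <- function(model, features) {
  if (is(features, "FeatureSequence")) features <- list(features)
  x <- featureBatch(features)
  if (!is.null(model$norm)) x <- (x - model$norm[["mu"]]) / model$norm[["sd"]]
  p <- adValue(crnnForward(model, x, training = FALSE))
  thr <- model$spec$decision_threshold
  data.frame(
    patient_id = vapply(features, patientId, character(1)),
    probability = as.numeric(p),
    label = ifelse(as.numeric(p) >= thr, "soft", "hard"),
    stringsAsFactors = FALSE)
}
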