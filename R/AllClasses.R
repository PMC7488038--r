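#' @import methods
NULL

#' SpatialSequence: one patient's ordered slice stack in one MRI domain
#'
#' Holds the ordered 2-D slices (coronal stack) of one patient in a single
#' intensity domain ("T1" or "T2"). Slice values are expected on the
#' \eqn{[-1, 1]} scale used throughout the package.
#'
#' @slot patientId character scalar identifier.
#' @slot domain "T1" or "T2".
#' @slot slices list of numeric matrices, all of identical dimensions.
#' @slot provenance "real" for acquired data, "generated" for slices produced
#'   by the domain converter.
#' @export
setClass("SpatialSequence",
  representation(patientId = "character", domain = "character",
                 slices = "list", provenance = "character"),
  prototype(provenance = "real"))

setValidity("SpatialSequence", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be a single string")
  if (!object@domain %in% c("T1", "T2")) msg <- c(msg, "domain must be 'T1' or 'T2'")
  if (!object@provenance %in% c("real", "generated"))
    msg <- c(msg, "provenance must be 'real' or 'generated'")
  if (length(object@slices) < 1L) msg <- c(msg, "at least one slice required")
  dims <- lapply(object@slices, dim)
  if (!all(vapply(object@slices, is.matrix, logical(1))))
    msg <- c(msg, "slices must be numeric matrices")
  else if (length(unique(dims)) > 1L)
    msg <- c(msg, "all slices must share the same dimensions")
  if (length(msg)) msg else TRUE
})

#' MultiSequence: interleaved, index-aligned T1/T2 slice pairs for one patient
#'
#' The per-patient pairing of T1 and T2 spatial sequences: pair \eqn{n} holds
#' slice \eqn{n} from each domain, and the flattened sequence
#' (t1_1, t2_1, t1_2, t2_2, ...) has length \eqn{2N}.
#'
#' @slot patientId character scalar.
#' @slot t1,t2 lists of aligned slice matrices of equal length and shape.
#' @export
setClass("MultiSequence",
  representation(patientId = "character", t1 = "list", t2 = "list"))

setValidity("MultiSequence", function(object) {
  msg <- character()
  if (length(object@t1) != length(object@t2))
    msg <- c(msg, "t1 and t2 must have the same number of slices")
  else if (length(object@t1) >= 1L &&
           !identical(dim(object@t1[[1]]), dim(object@t2[[1]])))
    msg <- c(msg, "t1 and t2 slices must share dimensions")
  if (length(msg)) msg else TRUE
})

#' FeatureSequence: stacked per-slice encoder feature maps for one patient
#'
#' A 3-D array (sequence position x height' x width') of per-slice feature
#' maps, in the flattened slice order of the originating sequence. This is the
#' input representation consumed by the CRNN classifier.
#'
#' @slot patientId character scalar.
#' @slot features 3-D numeric array, first axis = sequence position.
#' @export
setClass("FeatureSequence",
  representation(patientId = "character", features = "array"))

setValidity("FeatureSequence", function(object) {
  msg <- character()
  if (length(dim(object@features)) != 3L)
    msg <- c(msg, "features must be a 3-D array (position x h' x w')")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' ConverterBundle: the four trainable components of the domain converter
#'
#' Two mirrored generators (T1->T2 and T2->T1) and the two domain
#' discriminators, together with the training configuration used to fit them.
#'
#' @slot genT1ToT2,genT2ToT1 generator networks.
#' @slot discT1,discT2 patch discriminator networks.
#' @slot trained logical; FALSE for a freshly initialized bundle.
#' @slot config the \code{ganTrainConfig()} used (empty list if untrained).
#' @export
setClass("ConverterBundle",
  representation(genT1ToT2 = "list", genT2ToT1 = "list",
                 discT1 = "list", discT2 = "list",
                 trained = "logical", config = "list"),
  prototype(trained = FALSE, config = list()))

#' EvaluationReport: repeated-split metrics plus paired-test summaries
#'
#' @slot perReplicate data.frame with one row per (replicate, split) holding
#'   accuracy, precision, recall and F1.
#' @slot summary data.frame of mean, sd and variance per split and metric.
#' @slot pairedTests data.frame of paired signed-rank comparisons (may be
#'   empty when only one arm was evaluated).
#' @slot arm character scalar ("t1", "t2" or "multi").
#' @export
setClass("EvaluationReport",
  representation(perReplicate = "data.frame", summary = "data.frame",
                 pairedTests = "data.frame", arm = "character"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "SpatialSequence", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("SpatialSequence %s | domain %s (%s) | %d slices of %dx%d\n",
              object@patientId, object@domain, object@provenance,
              length(object@slices), d[1], d[2]))
})

setMethod("show", "MultiSequence", function(object) {
  d <- dim(object@t1[[1]])
  cat(sprintf("MultiSequence %s | %d aligned T1/T2 pairs (%d slices flattened) of %dx%d\n",
              object@patientId, length(object@t1), 2L * length(object@t1), d[1], d[2]))
})

setMethod("show", "FeatureSequence", function(object) {
  d <- dim(object@features)
  cat(sprintf("FeatureSequence %s | %d positions x %dx%d feature maps\n",
              object@patientId, d[1], d[2], d[3]))
})

setMethod("show", "ConverterBundle", function(object) {
  cat(sprintf("ConverterBundle | %s | generators T1<->T2 + per-domain patch discriminators\n",
              if (object@trained) "trained" else "initialized"))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport | arm %s | %d replicates\n", object@arm,
              length(unique(object@perReplicate$replicate))))
  print(object@summary)
  if (nrow(object@pairedTests)) {
    cat("Paired signed-rank comparisons:\n")
    print(object@pairedTests)
  }
})

## ---- basic accessors ------------------------------------------------------

#' Number of slices in a sequence object
#'
#' For a \code{SpatialSequence} the slice count N; for a \code{MultiSequence}
#' the flattened length 2N.
#' @param x a SpatialSequence or MultiSequence
#' @export
setMethod("length", "SpatialSequence", function(x) length(x@slices))

#' @rdname length-SpatialSequence-method
#' @export
setMethod("length", "MultiSequence", function(x) 2L * length(x@t1))

#' Accessors for sequence objects
#'
#' \code{patientId()} returns the patient identifier; \code{sequenceDomain()}
#' the intensity domain; \code{sequenceSlices()} the list of slice matrices
#' (flattened, interleaved order for a \code{MultiSequence});
#' \code{sequenceProvenance()} whether the slices are acquired or generated.
#'
#' @param x a sequence object
#' @return see details per accessor.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname patientId
#' @export
setGeneric("sequenceDomain", function(x) standardGeneric("sequenceDomain"))

#' @rdname patientId
#' @export
setGeneric("sequenceSlices", function(x) standardGeneric("sequenceSlices"))

#' @rdname patientId
#' @export
setGeneric("sequenceProvenance", function(x) standardGeneric("sequenceProvenance"))

setMethod("patientId", "SpatialSequence", function(x) x@patientId)
setMethod("patientId", "MultiSequence", function(x) x@patientId)
setMethod("patientId", "FeatureSequence", function(x) x@patientId)
setMethod("sequenceDomain", "SpatialSequence", function(x) x@domain)
setMethod("sequenceProvenance", "SpatialSequence", function(x) x@provenance)
setMethod("sequenceSlices", "SpatialSequence", function(x) x@slices)

# Flattened (t1_1, t2_1, t1_2, t2_2, ...) order per the multi-sequence
# definition: pair n contributes its T1 member before its T2 member.
setMethod("sequenceSlices", "MultiSequence", function(x) {
  n <- length(x@t1)
  out <- vector("list", 2L * n)
  out[seq(1, 2 * n, by = 2)] <- x@t1
  out[seq(2, 2 * n, by = 2)] <- x@t2
  out
})

#' Feature array of a FeatureSequence
#' @param x a FeatureSequence
#' @return the 3-D feature array (position x h' x w')
#' @export
featureArray <- function(x) {
  stopifnot(is(x, "FeatureSequence"))
  x@features
}
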