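# Cohort I/O: NIfTI / PNG stacks, intensity normalization, manifest handling,
# and assembly of interleaved multi-sequences.

#' Min-max normalization to [-1, 1]
#'
#' Per-volume min-max rescaling, the normalization applied on load so slice
#' intensities match the tanh output range of the generator networks. A
#' constant volume (min = max) maps to all zeros. The map is idempotent:
#' normalizing twice equals normalizing once.
#'
#' @param x numeric array.
#' @return array of the same shape with values in \eqn{[-1, 1]}.
#' @export
normalizeIntensity <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(x * 0)
  2 * (x - lo) / (hi - lo) - 1
}

#' Load one patient's spatial sequence
#'
#' Reads either a NIfTI volume (slice axis = third axis) or a directory of
#' index-ordered PNG slices, normalizes intensities to \eqn{[-1, 1]} by
#' per-volume min-max, and returns a \code{\linkS4class{SpatialSequence}}.
#'
#' @param path NIfTI file (.nii / .nii.gz) or a directory of PNGs.
#' @param domain "T1" or "T2".
#' @param patient_id identifier to attach (default: basename of \code{path}).
#' @param n_slices if given, error unless the stack has exactly this many
#'   slices.
#' @param provenance "real" or "generated".
#' @return a \code{\linkS4class{SpatialSequence}}.
#' @export
loadSequence <- function(path, domain, patient_id = NULL, n_slices = NULL,
                         provenance = "real") {
  assertChoice(domain, c("T1", "T2"), "domain")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    vol <- simplify2array(lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3L) im <- im[, , 1]
      im
    }))
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
  }
  if (!is.null(n_slices) && dim(vol)[3] != n_slices)
    stop(sprintf("sequence length mismatch: stack has %d slices, expected %d",
                 dim(vol)[3], n_slices))
  vol <- normalizeIntensity(vol)
  slices <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
  new("SpatialSequence",
      patientId = patient_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)),
      domain = domain, slices = slices, provenance = provenance)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with header
#' \code{patient_id,domain_t1,domain_t2,label}; \code{label} is "soft",
#' "hard" or empty for unlabeled patients. Every row must have at least one
#' available domain and patient ids must be unique.
#'
#' @param path CSV file path.
#' @return a data.frame with columns \code{patient_id} (character),
#'   \code{domain_t1}, \code{domain_t2} (logical) and \code{label}
#'   (character or NA).
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "domain_t1", "domain_t2", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m$domain_t1 <- as.logical(m$domain_t1)
  m$domain_t2 <- as.logical(m$domain_t2)
  m$label[m$label %in% c("", "none")] <- NA_character_
  validateManifest(m)
  m
}

#' @rdname readManifest
#' @param manifest a manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validateManifest <- function(m) {
  if (nrow(m)) {
    if (anyDuplicated(m$patient_id)) stop("manifest patient ids must be unique")
    if (any(!m$domain_t1 & !m$domain_t2))
      stop("every manifest row must have at least one available domain")
    bad <- !is.na(m$label) & !m$label %in% c("soft", "hard")
    if (any(bad)) stop("labels must be 'soft', 'hard' or missing")
  }
  invisible(m)
}

#' Assemble the interleaved multi-sequence of one patient
#'
#' Pairs slice \eqn{n} of the T1 sequence with slice \eqn{n} of the T2
#' sequence; the flattened order is t1_1, t2_1, t1_2, t2_2, ... and the
#' flattened length is \eqn{2N} (24 for the default 12-slice stacks).
#'
#' @param t1,t2 \code{SpatialSequence}s of the same patient, equal length and
#'   slice shape, with domains "T1" and "T2" respectively.
#' @return a \code{\linkS4class{MultiSequence}}.
#' @export
assembleMultiSequence <- function(t1, t2) {
  stopifnot(is(t1, "SpatialSequence"), is(t2, "SpatialSequence"))
  if (t1@domain != "T1" || t2@domain != "T2")
    stop("arguments must be a T1 and a T2 sequence, in that order")
  if (t1@patientId != t2@patientId)
    stop("patient mismatch: ", t1@patientId, " vs ", t2@patientId)
  if (length(t1@slices) != length(t2@slices))
    stop(sprintf("pairing error: %d T1 slices vs %d T2 slices",
                 length(t1@slices), length(t2@slices)))
  if (!identical(dim(t1@slices[[1]]), dim(t2@slices[[1]])))
    stop("pairing error: slice shapes differ between domains")
  new("MultiSequence", patientId = t1@patientId, t1 = t1@slices, t2 = t2@slices)
}

#' Split a multi-sequence back into its two spatial sequences
#'
#' Exact inverse of \code{assembleMultiSequence()} up to provenance (which is
#' not recorded in a \code{MultiSequence}).
#'
#' @param ms a \code{\linkS4class{MultiSequence}}.
#' @return list with elements \code{t1} and \code{t2}.
#' @export
splitMultiSequence <- function(ms) {
  stopifnot(is(ms, "MultiSequence"))
  list(t1 = new("SpatialSequence", patientId = ms@patientId, domain = "T1",
                slices = ms@t1, provenance = "real"),
       t2 = new("SpatialSequence", patientId = ms@patientId, domain = "T2",
                slices = ms@t2, provenance = "real"))
}

# Conventional on-disk path of a patient's volume within a cohort directory.
cohortVolumePath <- function(dir, patient_id, domain) {
  file.path(dir, sprintf("%s_%s.nii.gz", patient_id, domain))
}

#' Load all available sequences of a cohort
#'
#' @param dir cohort directory containing \code{manifest.csv} and the NIfTI
#'   volumes written by \code{generateCohort()} (or arranged by the same
#'   convention, \code{<patient>_<domain>.nii.gz}).
#' @param n_slices optional expected slice count per sequence.
#' @return list with \code{manifest} and \code{sequences}, the latter a named
#'   list \code{sequences[[patient_id]][[domain]]}.
#' @export
loadCohort <- function(dir, n_slices = NULL) {
  manifest <- readManifest(file.path(dir, "manifest.csv"))
  seqs <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    seqs[[pid]] <- list()
    if (manifest$domain_t1[i])
      seqs[[pid]][["T1"]] <- loadSequence(cohortVolumePath(dir, pid, "T1"),
                                          "T1", pid, n_slices)
    if (manifest$domain_t2[i])
      seqs[[pid]][["T2"]] <- loadSequence(cohortVolumePath(dir, pid, "T2"),
                                          "T2", pid, n_slices)
  }
  list(manifest = manifest, sequences = seqs)
}
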