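# Synthetic two-domain, two-class slice-sequence phantom.
#
# Each phantom patient is a smooth elliptical "lesion" embedded in a
# low-frequency background, imaged as an ordered stack of N slices. The two
# texture classes ("soft" vs "hard") differ only in the correlation length of
# band-limited Gaussian noise inside the lesion, so they are separable by a
# local-variance statistic but not by shape. Domain "T2" is a fixed invertible
# intensity transform of the matched "T1" slice plus independent noise,
# emulating T1/T2 contrast reversal and giving the domain converter a known
# recoverable mapping.

#' Configuration for the synthetic phantom generator
#'
#' @param image_size pixels per side (>= 16); 64 is convenient for tests,
#'   256 for demos.
#' @param n_slices slices per spatial sequence (default 12).
#' @param class_texture_scale granularity margin between the two texture
#'   classes: the "soft" smoothing length is \code{(1 + class_texture_scale)}
#'   times the "hard" one. Larger values make the classes easier to separate.
#' @param domain_transform name of the invertible intensity map relating the
#'   two domains; \code{"invert_gamma"} (contrast inversion followed by a mild
#'   gamma curve) or \code{"identity"}.
#' @param gamma exponent of the gamma curve used by \code{"invert_gamma"}.
#' @param noise_sd standard deviation of the independent additive noise on
#'   domain-B slices (0 disables it).
#' @param seed integer seed; identical (config, seed) pairs yield
#'   bit-identical cohorts.
#' @return a validated list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(image_size = 64L, n_slices = 12L,
                          class_texture_scale = 4, domain_transform = "invert_gamma",
                          gamma = 0.8, noise_sd = 0.02, seed = 1L) {
  cfg <- list(
    image_size = assertCount(image_size, "image_size", min = 16L),
    n_slices = assertCount(n_slices, "n_slices", min = 1L),
    class_texture_scale = assertNumber(class_texture_scale, "class_texture_scale", min = 0),
    domain_transform = assertChoice(domain_transform, c("invert_gamma", "identity"),
                                    "domain_transform"),
    gamma = assertNumber(gamma, "gamma", min = 0.1, max = 10),
    noise_sd = assertNumber(noise_sd, "noise_sd", min = 0),
    seed = assertCount(seed, "seed", min = 0L))
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Cohort composition for phantom generation
#'
#' Describes an unbalanced two-domain cohort: every patient has exactly one
#' acquired domain, and only a subset carries a texture label.
#'
#' @param n_patients total patients.
#' @param n_t1_only patients with only a T1 sequence.
#' @param n_t2_only patients with only a T2 sequence
#'   (\code{n_t1_only + n_t2_only} must equal \code{n_patients}).
#' @param n_labeled number of labeled patients (<= \code{n_patients}).
#' @param labeled_t1_only labeled patients drawn from the T1-only group.
#' @param labeled_t2_only labeled patients drawn from the T2-only group.
#' @param class_balance fraction of patients in the "soft" class.
#' @return a validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_patients, n_t1_only, n_t2_only, n_labeled,
                       labeled_t1_only, labeled_t2_only, class_balance = 0.5) {
  spec <- list(
    n_patients = assertCount(n_patients, "n_patients"),
    n_t1_only = assertCount(n_t1_only, "n_t1_only"),
    n_t2_only = assertCount(n_t2_only, "n_t2_only"),
    n_labeled = assertCount(n_labeled, "n_labeled"),
    labeled_t1_only = assertCount(labeled_t1_only, "labeled_t1_only"),
    labeled_t2_only = assertCount(labeled_t2_only, "labeled_t2_only"),
    class_balance = assertNumber(class_balance, "class_balance", 0, 1))
  if (spec$n_t1_only + spec$n_t2_only != spec$n_patients)
    stop("n_t1_only + n_t2_only must equal n_patients")
  if (spec$labeled_t1_only + spec$labeled_t2_only != spec$n_labeled)
    stop("labeled_t1_only + labeled_t2_only must equal n_labeled")
  if (spec$n_labeled > spec$n_patients) stop("n_labeled must not exceed n_patients")
  if (spec$labeled_t1_only > spec$n_t1_only || spec$labeled_t2_only > spec$n_t2_only)
    stop("labeled counts cannot exceed the corresponding domain group sizes")
  class(spec) <- "CohortSpec"
  spec
}

#' The invertible intensity transform relating the two phantom domains
#'
#' \code{"invert_gamma"} maps intensity \eqn{x \in [-1,1]} to
#' \eqn{2(1-u)^\gamma - 1} with \eqn{u = (x+1)/2}: contrast inversion (bright
#' tissue in one domain is dark in the other) followed by a mild gamma curve.
#' The map is strictly monotone and exactly invertible.
#'
#' @param x numeric array of intensities in \eqn{[-1, 1]}.
#' @param config a \code{phantomConfig()}.
#' @param inverse apply the inverse map (domain B back to domain A).
#' @return transformed array of the same shape.
#' @export
domainTransform <- function(x, config, inverse = FALSE) {
  if (config$domain_transform == "identity") return(x)
  g <- config$gamma
  if (!inverse) {
    u <- (x + 1) / 2
    2 * (1 - u)^g - 1
  } else {
    v <- (x + 1) / 2
    2 * (1 - v^(1 / g)) - 1
  }
}

# Separable Gaussian smoothing via the package's conv kernel; 'same' output.
gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-k, k), sd = sigma)
  g <- g / sum(g)
  w <- outer(g, g)
  x <- array(m, dim = c(nrow(m), ncol(m), 1L, 1L))
  wv <- array(w, dim = c(length(g), length(g), 1L, 1L))
  y <- conv2d_fwd(x, wv, 0, 1L, k)
  matrix(y, nrow(m), ncol(m))
}

# Per-patient lesion geometry, deterministic in (config, seed).
lesionGeometry <- function(config, seed) {
  withSeed(deriveSeed(seed, "geom"), {
    s <- config$image_size
    list(cx = stats::runif(1, 0.46, 0.54) * s,
         cy = stats::runif(1, 0.46, 0.54) * s,
         rx = stats::runif(1, 0.24, 0.30) * s,
         ry = stats::runif(1, 0.24, 0.30) * s,
         bg_phase = stats::runif(2, 0, 2 * pi))
  })
}

# Through-slice scaling of the ellipse axes (a 3-D lesion cut by the stack).
sliceAxisScale <- function(slice_index, n_slices) {
  z <- (slice_index - (n_slices - 1) / 2) / max(1, n_slices / 2)
  sqrt(pmax(0.45, 1 - (0.75 * z)^2))
}

#' Binary lesion mask of one phantom slice
#'
#' Recomputes the deterministic lesion geometry so tests and oracles can
#' measure within-lesion statistics without segmentation.
#'
#' @param slice_index 0-based slice index in \code{[0, n_slices)}.
#' @param config a \code{phantomConfig()}.
#' @param seed the per-patient seed the slice was generated with.
#' @return logical matrix, TRUE inside the lesion.
#' @export
lesionMask <- function(slice_index, config, seed) {
  geo <- lesionGeometry(config, seed)
  sc <- sliceAxisScale(slice_index, config$n_slices)
  s <- config$image_size
  xx <- matrix(seq_len(s), s, s)
  yy <- t(xx)
  ((xx - geo$cx) / (geo$rx * sc))^2 + ((yy - geo$cy) / (geo$ry * sc))^2 <= 1
}

#' Generate one phantom slice
#'
#' Domain "T1" slices are composed from a low-frequency background, an
#' elliptical lesion, and within-lesion band-limited Gaussian texture whose
#' correlation length depends on the texture class. Domain "T2" slices are the
#' configured invertible intensity transform of the matched T1 slice plus
#' independent Gaussian noise of sd \code{noise_sd}.
#'
#' @param domain "T1" or "T2".
#' @param texture_class "soft" or "hard".
#' @param slice_index 0-based index in \code{[0, n_slices)}.
#' @param config a \code{phantomConfig()}.
#' @param seed per-patient seed (defaults to \code{config$seed}).
#' @return a numeric matrix with values in \eqn{[-1, 1]}.
#' @export
generateSlice <- function(domain, texture_class, slice_index, config,
                          seed = config$seed) {
  assertChoice(domain, c("T1", "T2"), "domain")
  assertChoice(texture_class, c("soft", "hard"), "texture_class")
  assertCount(slice_index, "slice_index")
  if (slice_index >= config$n_slices)
    stop("slice_index must be in [0, n_slices)")
  s <- config$image_size
  geo <- lesionGeometry(config, seed)
  mask <- lesionMask(slice_index, config, seed)

  # low-frequency background (deterministic per patient)
  xx <- matrix(seq_len(s) / s, s, s)
  yy <- t(xx)
  bg <- 0.25 + 0.08 * sin(2 * pi * xx + geo$bg_phase[1]) *
    cos(2 * pi * yy + geo$bg_phase[2])

  # within-lesion texture: band-limited Gaussian noise, renormalized to a
  # fixed marginal sd so the classes differ only in correlation length —
  # "hard" is fine-grained (high local variance), "soft" is coarse-grained
  # (its clumps survive spatial averaging)
  sigma_hard <- 0.6
  sigma <- if (texture_class == "hard") sigma_hard
           else sigma_hard * (1 + config$class_texture_scale)
  tex <- withSeed(deriveSeed(seed, paste0("tex", slice_index)), {
    t0 <- gaussSmooth(matrix(stats::rnorm(s * s), s, s), sigma)
    t0 * (0.28 / stats::sd(t0))
  })

  img <- bg
  img[mask] <- 0.52 + tex[mask]
  img <- pmin(pmax(img, 0), 1)
  a <- 2 * img - 1
  if (domain == "T1") return(a)
  b <- domainTransform(a, config)
  if (config$noise_sd > 0) {
    b <- b + withSeed(deriveSeed(seed, paste0("bnoise", slice_index)),
                      matrix(stats::rnorm(s * s, sd = config$noise_sd), s, s))
    b <- pmin(pmax(b, -1), 1)
  }
  b
}

#' Generate a full phantom spatial sequence for one patient
#'
#' @param patient_id character identifier; the per-patient seed is derived
#'   from \code{config$seed} and this id.
#' @param domain "T1" or "T2".
#' @param texture_class "soft" or "hard".
#' @param config a \code{phantomConfig()}.
#' @return a \code{\linkS4class{SpatialSequence}}.
#' @export
phantomSequence <- function(patient_id, domain, texture_class, config) {
  pseed <- deriveSeed(config$seed, patient_id)
  slices <- lapply(seq_len(config$n_slices) - 1L, function(i)
    generateSlice(domain, texture_class, i, config, seed = pseed))
  new("SpatialSequence", patientId = patient_id, domain = domain,
      slices = slices, provenance = "real")
}

#' Within-lesion local-variance texture statistic
#'
#' Mean of the 3x3 local variance over the masked region — the simple
#' hand-computable statistic that separates the phantom's two texture classes
#' and serves as the classifier sanity oracle.
#'
#' @param slice numeric matrix.
#' @param mask logical matrix of the same shape (default: whole slice).
#' @return a nonnegative scalar.
#' @export
textureStatistic <- function(slice, mask = NULL) {
  x <- array(slice, dim = c(nrow(slice), ncol(slice), 1L, 1L))
  box <- array(1 / 9, dim = c(3L, 3L, 1L, 1L))
  m1 <- matrix(conv2d_fwd(x, box, 0, 1L, 1L), nrow(slice), ncol(slice))
  m2 <- matrix(conv2d_fwd(x^2, box, 0, 1L, 1L), nrow(slice), ncol(slice))
  lv <- pmax(m2 - m1^2, 0)
  if (is.null(mask)) mean(lv) else mean(lv[mask])
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI volume per patient per available domain (slice axis =
#' third axis), a manifest CSV with header
#' \code{patient_id,domain_t1,domain_t2,label}, and a hidden
#' \code{.truth.csv} holding the ground-truth class of every patient
#' (labeled or not) for oracle testing. Optionally also writes zero-padded
#' PNG series \code{<patient>/<domain>/slice_000.png ...}.
#'
#' @param spec a \code{cohortSpec()}.
#' @param config a \code{phantomConfig()}.
#' @param dir output directory (created if missing).
#' @param write_png also export PNG stacks.
#' @return the manifest as a data.frame (invisibly also written to
#'   \code{file.path(dir, "manifest.csv")}).
#' @export
generateCohort <- function(spec, config, dir, write_png = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"), inherits(config, "PhantomConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  n <- spec$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  if (n == 0L) {
    manifest <- data.frame(patient_id = character(), domain_t1 = logical(),
                           domain_t2 = logical(), label = character(),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    return(manifest)
  }
  has_t1 <- c(rep(TRUE, spec$n_t1_only), rep(FALSE, spec$n_t2_only))
  has_t2 <- !has_t1
  classes <- withSeed(deriveSeed(config$seed, "classes"), {
    ifelse(stats::runif(n) < spec$class_balance, "soft", "hard")
  })
  labeled <- rep(FALSE, n)
  withSeed(deriveSeed(config$seed, "labelpick"), {
    t1_idx <- which(has_t1)
    t2_idx <- which(has_t2)
    if (spec$labeled_t1_only > 0)
      labeled[sample(t1_idx, spec$labeled_t1_only)] <- TRUE
    if (spec$labeled_t2_only > 0)
      labeled[sample(t2_idx, spec$labeled_t2_only)] <- TRUE
  })
  for (i in seq_len(n)) {
    dom <- if (has_t1[i]) "T1" else "T2"
    seq_i <- phantomSequence(ids[i], dom, classes[i], config)
    vol <- simplify2array(sequenceSlices(seq_i))
    RNifti::writeNifti(vol, file.path(dir, sprintf("%s_%s.nii.gz", ids[i], dom)))
    if (write_png) {
      pdir <- file.path(dir, ids[i], dom)
      dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
      for (k in seq_len(config$n_slices)) {
        png::writePNG((sequenceSlices(seq_i)[[k]] + 1) / 2,
                      file.path(pdir, sprintf("slice_%03d.png", k - 1L)))
      }
    }
  }
  manifest <- data.frame(
    patient_id = ids, domain_t1 = has_t1, domain_t2 = has_t2,
    label = ifelse(labeled, classes, NA_character_),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- data.frame(patient_id = ids, label = classes, stringsAsFactors = FALSE)
  utils::write.csv(truth, file.path(dir, ".truth.csv"), row.names = FALSE)
  manifest
}

#' Ground-truth sequence for any phantom patient and domain
#'
#' Regenerates (deterministically) the noiseless-or-noisy slices of either
#' domain for a phantom patient, including the domain the cohort never wrote
#' to disk — the oracle for measuring the domain converter's cross-domain
#' error.
#'
#' @param patient_id patient identifier used at generation time.
#' @param domain "T1" or "T2".
#' @param dir the cohort directory (to read the hidden truth labels).
#' @param config the \code{phantomConfig()} used at generation time.
#' @return a \code{\linkS4class{SpatialSequence}}.
#' @export
phantomGroundTruth <- function(patient_id, domain, dir, config) {
  truth <- utils::read.csv(file.path(dir, ".truth.csv"), stringsAsFactors = FALSE)
  cls <- truth$label[truth$patient_id == patient_id]
  if (length(cls) != 1L) stop("unknown patient id: ", patient_id)
  phantomSequence(patient_id, domain, cls, config)
}
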