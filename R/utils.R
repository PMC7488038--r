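# Shared helpers: seed derivation, argument checks.

#' Derive a stage seed from a global seed
#'
#' Stages of the pipeline (phantom generation, GAN training, autoencoder,
#' per-replicate splits, CRNN) each get their own reproducible RNG seed,
#' derived deterministically from the single global seed and a stage tag, so
#' that any stage can be re-run in isolation. The derived value stays below
#' 2^31 - 1.
#'
#' @param seed integer global seed
#' @param tag character stage tag (e.g. "gan", "split3")
#' @return an integer seed
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assertNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a number in [%s, %s]", name, min, max), call. = FALSE)
  invisible(as.numeric(x))
}

assertChoice <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices)
    stop(sprintf("'%s' must be one of: %s", name, paste(choices, collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# RNG afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
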