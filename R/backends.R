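## Pluggable nuclei-segmentation backends. The built-in quantise-watershed
## method is always available; a star-convex polygon segmenter (or any
## external tool, e.g. a deep-learning model run outside R) can be attached
## by registering a function that maps a DAPI matrix to a label map.

.backends <- new.env(parent = emptyenv())

#' Register a nuclei-segmentation backend
#'
#' @param name Backend name, selectable via
#'   `segmentationParams(backend = name)`.
#' @param segmenter `function(dapi, params)` returning an integer label
#'   matrix (0 = background) or a [NucleusLabelMap-class] of the same
#'   dimensions as `dapi`. Minimum-area filtering and contiguous relabelling
#'   are applied afterwards by [segmentNuclei()].
#' @param overwrite Allow replacing an existing registration.
#' @return Invisibly, the backend name.
#' @export
registerBackend <- function(name, segmenter, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(segmenter))
  if (!overwrite && exists(name, envir = .backends, inherits = FALSE))
    stop(sprintf("backend '%s' is already registered", name))
  assign(name, segmenter, envir = .backends)
  invisible(name)
}

#' List registered segmentation backends
#'
#' @return Character vector of backend names.
#' @export
segmentationBackends <- function() {
  sort(ls(envir = .backends))
}

getBackend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE))
    stop(sprintf("unknown segmentation backend '%s' (registered: %s)",
                 name, paste(segmentationBackends(), collapse = ", ")))
  get(name, envir = .backends, inherits = FALSE)
}

.onLoad <- function(libname, pkgname) {
  if (!exists("quantise-watershed", envir = .backends, inherits = FALSE))
    registerBackend("quantise-watershed", quantiseWatershed)
  ## interface slot for an external star-convex polygon segmenter; no
  ## model is bundled, so invoking it without registration is an error
  if (!exists("star-convex", envir = .backends, inherits = FALSE))
    registerBackend("star-convex", function(dapi, params) {
      stop("no star-convex segmenter attached; use registerBackend(",
           "\"star-convex\", <segmenter>, overwrite = TRUE) to supply one")
    })
}
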