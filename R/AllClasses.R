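## Central S4 containers. Images are plain numeric matrices in R orientation:
## rows are y (top to bottom), columns are x; all pixel coordinates are
## 1-based with x = column index, y = row index.

#' Parameters of the difference-of-Gaussians band-pass filter
#'
#' The raw image is blurred with a small Gaussian (standard deviation
#' `sigmaSmall`, in pixels) to enhance the diffraction-limited signal; the
#' background is estimated with a larger Gaussian (`sigmaLarge`) and
#' subtracted. Defaults are 0.5 and 3 pixels, the standard setting for
#' single-molecule dot enhancement at high magnification.
#'
#' @slot sigmaSmall numeric(1), signal-enhancement scale in pixels.
#' @slot sigmaLarge numeric(1), background-estimation scale in pixels.
#' @exportClass DoGParams
setClass("DoGParams",
  representation(sigmaSmall = "numeric", sigmaLarge = "numeric"),
  prototype(sigmaSmall = 0.5, sigmaLarge = 3)
)

setValidity("DoGParams", function(object) {
  if (length(object@sigmaSmall) != 1 || length(object@sigmaLarge) != 1)
    return("sigmaSmall and sigmaLarge must be scalars")
  if (!(object@sigmaSmall > 0))
    return("sigmaSmall must be > 0")
  if (!(object@sigmaLarge > object@sigmaSmall))
    return("sigmaLarge must be greater than sigmaSmall")
  TRUE
})

#' @param sigmaSmall,sigmaLarge Gaussian standard deviations in pixels,
#'   `0 < sigmaSmall < sigmaLarge`.
#' @return A [DoGParams-class] object.
#' @rdname DoGParams-class
#' @export
dogParams <- function(sigmaSmall = 0.5, sigmaLarge = 3) {
  new("DoGParams", sigmaSmall = sigmaSmall, sigmaLarge = sigmaLarge)
}

#' Parameters of the DAPI nuclei segmentation
#'
#' @slot dapiSigma numeric(1), Gaussian smoothing scale (pixels) applied to
#'   the DAPI channel to even out intensity inhomogeneities; default 7.
#' @slot nLevels integer(1), number of foreground intensity tiers detected by
#'   the multi-level Otsu quantisation; fixed at 3 (nuclei differ in
#'   brightness with their position along the optical axis).
#' @slot minArea numeric(1), minimum retained nucleus area in pixels^2.
#' @slot backend character(1), name of a registered segmentation backend;
#'   `"quantise-watershed"` is the built-in default, `"star-convex"` is an
#'   interface for externally supplied star-convex polygon segmenters.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(dapiSigma = "numeric", nLevels = "integer",
                 minArea = "numeric", backend = "character"),
  prototype(dapiSigma = 7, nLevels = 3L, minArea = 150,
            backend = "quantise-watershed")
)

setValidity("SegmentationParams", function(object) {
  if (!(length(object@dapiSigma) == 1 && object@dapiSigma > 0))
    return("dapiSigma must be a positive scalar")
  if (object@nLevels != 3L)
    return("nLevels is fixed at 3")
  if (!(length(object@minArea) == 1 && object@minArea >= 0))
    return("minArea must be a non-negative scalar")
  if (length(object@backend) != 1)
    return("backend must be a single name")
  TRUE
})

#' @param dapiSigma Smoothing scale in pixels (default 7).
#' @param minArea Minimum nucleus area in pixels^2 (default 150).
#' @param backend Registered backend name.
#' @return A [SegmentationParams-class] object.
#' @rdname SegmentationParams-class
#' @export
segmentationParams <- function(dapiSigma = 7, minArea = 150,
                               backend = "quantise-watershed") {
  new("SegmentationParams", dapiSigma = dapiSigma, minArea = minArea,
      backend = backend)
}

#' A four-channel multiplex FISH field
#'
#' One imaged field: a height x width x 4 intensity array plus acquisition
#' metadata. Channels 1, 2 and 4 carry probe signal; channel 3 is the DAPI
#' nuclear counterstain.
#'
#' @slot data numeric array, `dim = c(height, width, 4)`.
#' @slot animalId character(1).
#' @slot fieldIndex integer(1), position of the field along the imaging axis
#'   (1-8 in a standard series).
#' @slot assay character(1), marker panel identifier.
#' @exportClass MultiplexField
setClass("MultiplexField",
  representation(data = "array", animalId = "character",
                 fieldIndex = "integer", assay = "character"),
  prototype(animalId = NA_character_, fieldIndex = NA_integer_,
            assay = NA_character_)
)

setValidity("MultiplexField", function(object) {
  d <- dim(object@data)
  if (length(d) != 3 || d[3] != 4)
    return("data must be a height x width x 4 array")
  if (any(object@data < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' Detected single-molecule puncta
#'
#' @slot spots data.frame with columns `x`, `y` (integer pixel coordinates,
#'   1-based), `channel` (1, 2 or 4) and `intensity` (DoG-filtered value at
#'   the maximum).
#' @slot thresholds named numeric, the per-channel detection thresholds used
#'   (names `"ch1"`, `"ch2"`, `"ch4"`).
#' @slot minSeparation numeric(1), minimum centre-to-centre distance (pixels)
#'   enforced between retained spots of one channel.
#' @slot imageDim integer(2), `c(height, width)` of the source image.
#' @exportClass SpotSet
setClass("SpotSet",
  representation(spots = "data.frame", thresholds = "numeric",
                 minSeparation = "numeric", imageDim = "integer")
)

setValidity("SpotSet", function(object) {
  need <- c("x", "y", "channel", "intensity")
  if (!all(need %in% names(object@spots)))
    return("spots must have columns x, y, channel, intensity")
  if (nrow(object@spots) > 0) {
    if (!all(object@spots$channel %in% c(1L, 2L, 4L)))
      return("spot channels must be 1, 2 or 4")
    th <- object@thresholds[paste0("ch", object@spots$channel)]
    if (any(!is.na(th) & object@spots$intensity <= th))
      return("every spot intensity must exceed its channel threshold")
  }
  TRUE
})

#' Integer-labelled nucleus segmentation of one field
#'
#' @slot labels integer matrix; 0 is background, nuclei are labelled 1..n
#'   contiguously.
#' @slot nucleusTable data.frame with one row per nucleus: `nucleus` (label),
#'   `x`, `y` (centroid, pixels) and `area` (pixels^2).
#' @exportClass NucleusLabelMap
setClass("NucleusLabelMap",
  representation(labels = "matrix", nucleusTable = "data.frame")
)

setValidity("NucleusLabelMap", function(object) {
  lab <- object@labels
  n <- if (length(lab)) max(lab) else 0L
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (length(ids) && !identical(as.integer(ids), seq_len(n)))
    return("labels must be contiguous 1..n")
  if (nrow(object@nucleusTable) != n)
    return("nucleusTable must have one row per label")
  TRUE
})

#' Exact ground truth of a synthetic field
#'
#' @slot labelMap integer matrix of true nucleus masks (0 = background).
#' @slot trueCounts integer matrix, one row per nucleus, columns `ch1`,
#'   `ch2`, `ch4`: the number of molecules owned by that nucleus.
#' @slot dots data.frame of every rendered molecule: `x`, `y`, `channel`,
#'   `nucleus` (owner label, 0 for molecules planted away from all nuclei).
#' @exportClass FieldGroundTruth
setClass("FieldGroundTruth",
  representation(labelMap = "matrix", trueCounts = "matrix",
                 dots = "data.frame")
)

setValidity("FieldGroundTruth", function(object) {
  n <- if (length(object@labelMap)) max(object@labelMap) else 0L
  if (nrow(object@trueCounts) != n)
    return("trueCounts must have one row per true nucleus")
  owned <- object@dots[object@dots$nucleus > 0, , drop = FALSE]
  if (nrow(owned) &&
      !identical(sum(object@trueCounts), as.integer(nrow(owned))))
    return("trueCounts must total the number of owned dots")
  TRUE
})

#' Specification of a synthetic multiplex field
#'
#' Describes the simulated imaging conditions: elliptical nuclei in three
#' brightness tiers (nuclei sit at different depths, so not all are equally
#' bright), an adjustable fraction of touching nucleus pairs, per-cell
#' Poisson molecule counts rendered as 2-D Gaussian puncta, a fraction of
#' stray molecules placed away from every nucleus, and additive Gaussian
#' background noise.
#'
#' @slot width,height integers, field size in pixels.
#' @slot nNuclei integer, number of nuclei to place.
#' @slot nucleusRadiusRange numeric(2), semi-major axis range in pixels.
#' @slot nucleusAxisRatioRange numeric(2), major/minor axis ratio range
#'   (1 = circle).
#' @slot brightnessTiers numeric(3), strictly increasing relative DAPI
#'   intensities of the dim, mid and bright tier.
#' @slot touchingFraction numeric(1), fraction of nuclei placed as touching
#'   pairs.
#' @slot perChannelLambda named numeric(3), mean true molecules per cell for
#'   channels 1, 2, 4.
#' @slot dotSigma numeric(1), point-spread width of a rendered punctum
#'   (pixels).
#' @slot dotAmplitude numeric(1), peak intensity of a rendered punctum.
#' @slot farDotFraction numeric(1), fraction of rendered molecules placed
#'   more than the assignment radius away from every nucleus.
#' @slot minDotSeparation numeric(1), minimum distance between same-channel
#'   molecules (pixels).
#' @slot backgroundSigma numeric(1), s.d. of additive Gaussian noise.
#' @slot seed integer(1); the same spec and seed reproduce the field
#'   bit-exactly.
#' @exportClass FieldSpec
setClass("FieldSpec",
  representation(width = "integer", height = "integer", nNuclei = "integer",
                 nucleusRadiusRange = "numeric",
                 nucleusAxisRatioRange = "numeric",
                 brightnessTiers = "numeric", touchingFraction = "numeric",
                 perChannelLambda = "numeric", dotSigma = "numeric",
                 dotAmplitude = "numeric", farDotFraction = "numeric",
                 minDotSeparation = "numeric", backgroundSigma = "numeric",
                 seed = "integer")
)

setValidity("FieldSpec", function(object) {
  if (object@width < 1 || object@height < 1)
    return("field dimensions must be positive")
  if (object@nNuclei < 0)
    return("nNuclei must be >= 0")
  if (any(object@nucleusRadiusRange <= 0) ||
      diff(object@nucleusRadiusRange) < 0)
    return("nucleusRadiusRange must be positive and ordered")
  if (any(object@nucleusAxisRatioRange < 1) ||
      diff(object@nucleusAxisRatioRange) < 0)
    return("nucleusAxisRatioRange must be >= 1 and ordered")
  if (length(object@brightnessTiers) != 3 ||
      any(diff(object@brightnessTiers) <= 0))
    return("brightnessTiers must be 3 strictly increasing levels")
  if (object@touchingFraction < 0 || object@touchingFraction > 1)
    return("touchingFraction must be in [0, 1]")
  if (length(object@perChannelLambda) != 3 || any(object@perChannelLambda < 0))
    return("perChannelLambda must be 3 non-negative means")
  if (object@dotSigma <= 0 || object@dotAmplitude < 0)
    return("dotSigma must be > 0 and dotAmplitude >= 0")
  if (object@farDotFraction < 0 || object@farDotFraction >= 1)
    return("farDotFraction must be in [0, 1)")
  if (object@backgroundSigma < 0)
    return("backgroundSigma must be >= 0")
  TRUE
})

#' Specification of a synthetic drinking cohort
#'
#' Emulates a schedule-induced polydipsia experiment: after a short baseline,
#' animals drink a stable regulatory volume each daily session except for a
#' planted fraction of escalators whose expected intake increases linearly
#' from an onset session onward, the pattern by which high drinkers diverge
#' from the rest of the population.
#'
#' @slot nAnimals integer(1).
#' @slot nSessions integer(1), number of daily training sessions (default 21).
#' @slot baselineSessions integer(1), habituation sessions preceding training
#'   during which regulatory intake is measured (default 2).
#' @slot hdFraction numeric(1), fraction of animals planted as escalators.
#' @slot escalationOnset integer(1), training session after which escalators'
#'   expected intake starts to rise (default 8).
#' @slot escalationRate numeric(1), mean intake increase in mL/session.
#' @slot baselineIntake numeric(1), regulatory intake in mL.
#' @slot noiseSd numeric(1), session-to-session Gaussian noise in mL.
#' @slot seed integer(1).
#' @exportClass BehaviorSpec
setClass("BehaviorSpec",
  representation(nAnimals = "integer", nSessions = "integer",
                 baselineSessions = "integer", hdFraction = "numeric",
                 escalationOnset = "integer", escalationRate = "numeric",
                 baselineIntake = "numeric", noiseSd = "numeric",
                 seed = "integer")
)

setValidity("BehaviorSpec", function(object) {
  if (object@nAnimals < 1) return("nAnimals must be >= 1")
  if (object@hdFraction < 0 || object@hdFraction > 1)
    return("hdFraction must be in [0, 1]")
  if (object@nSessions < object@baselineSessions)
    return("nSessions must be >= baselineSessions")
  if (object@escalationOnset < 1 || object@escalationOnset > object@nSessions)
    return("escalationOnset must lie within the session range")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' A simulated behavioural cohort with its planted ground truth
#'
#' @slot intake data.frame with columns `animal_id`, `session`, `phase`
#'   (`"baseline"` or `"training"`), `intake_ml`.
#' @slot escalators character, animal ids planted as escalating drinkers.
#' @slot spec the generating [BehaviorSpec-class].
#' @exportClass BehaviorCohort
setClass("BehaviorCohort",
  representation(intake = "data.frame", escalators = "character",
                 spec = "BehaviorSpec")
)

#' Per-cell counts of one field
#'
#' @slot counts data.frame, one row per nucleus: `field_id`, `nucleus`,
#'   `x`, `y`, `area`, `ch1`, `ch2`, `ch4`.
#' @slot unassigned named numeric(3), per-channel count of detected spots
#'   farther than the assignment radius from every nucleus.
#' @slot fieldId character(1).
#' @slot maxDist numeric(1), the assignment radius used (pixels).
#' @exportClass CellCountTable
setClass("CellCountTable",
  representation(counts = "data.frame", unassigned = "numeric",
                 fieldId = "character", maxDist = "numeric")
)

setValidity("CellCountTable", function(object) {
  chn <- c("ch1", "ch2", "ch4")
  if (!all(chn %in% names(object@counts)))
    return("counts must have columns ch1, ch2, ch4")
  cc <- as.matrix(object@counts[, chn, drop = FALSE])
  if (length(cc) && (any(cc < 0) || any(cc != round(cc))))
    return("counts must be non-negative integers")
  if (!all(chn %in% names(object@unassigned)))
    return("unassigned must be named ch1, ch2, ch4")
  TRUE
})

#' Session-by-metric Spearman correlation matrices
#'
#' Each cell holds the Spearman correlation between per-animal water intake
#' in one session and one animal-level metric, its two-sided p-value, and
#' the Benjamini-Hochberg adjusted q-value computed over all cells of the
#' matrix as one family.
#'
#' @slot r,p,q numeric matrices (sessions x metrics).
#' @slot sig logical matrix, `q <= alpha` (NA where undefined).
#' @slot alpha numeric(1), significance level.
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(r = "matrix", p = "matrix", q = "matrix", sig = "matrix",
                 alpha = "numeric"),
  prototype(alpha = 0.05)
)

setValidity("CorrelationMatrix", function(object) {
  if (!identical(dim(object@r), dim(object@p)) ||
      !identical(dim(object@r), dim(object@q)))
    return("r, p and q must share dimensions")
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE))
    return("correlations must lie in [-1, 1]")
  if (any(object@q < object@p - 1e-12, na.rm = TRUE))
    return("q-values cannot fall below raw p-values")
  TRUE
})

#' Frozen parameter set of a batch run
#'
#' One threshold set is fixed on a sample image and then kept unchanged for
#' the entire assay batch; the configuration is serialised verbatim into the
#' output directory so the run log proves a single parameter tuple.
#'
#' @slot dog a [DoGParams-class].
#' @slot thresholds named numeric(3), detection thresholds `th1`, `th2`,
#'   `th4` applied to the DoG-filtered channels.
#' @slot segmentation a [SegmentationParams-class].
#' @slot maxDist numeric(1), dot-to-nucleus assignment radius in pixels
#'   (default 10).
#' @slot minSeparation numeric(1), spot non-maximum-suppression radius.
#' @slot positivityThresholds named numeric, minimum copies for a cell to
#'   count as marker-positive.
#' @slot markerMaps named list, per-assay channel-to-marker maps.
#' @slot seed integer(1).
#' @exportClass RunConfig
setClass("RunConfig",
  representation(dog = "DoGParams", thresholds = "numeric",
                 segmentation = "SegmentationParams", maxDist = "numeric",
                 minSeparation = "numeric", positivityThresholds = "numeric",
                 markerMaps = "list", seed = "integer")
)

setValidity("RunConfig", function(object) {
  if (!identical(sort(names(object@thresholds)),
                 c("th1", "th2", "th4")))
    return("thresholds must be named th1, th2, th4")
  if (any(object@thresholds <= 0))
    return("thresholds must be positive")
  if (!(length(object@maxDist) == 1 && object@maxDist >= 0))
    return("maxDist must be a non-negative scalar")
  if (any(object@positivityThresholds < 1))
    return("positivity thresholds must be >= 1 copy")
  TRUE
})
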