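## Accessors and show methods.

#' Extract one channel of a field as a plain intensity matrix
#'
#' @param x A [MultiplexField-class].
#' @param channel Channel index 1-4 (3 is the DAPI counterstain).
#' @return A numeric matrix (rows = y, columns = x).
#' @export
setMethod("channelImage", "MultiplexField", function(x, channel) {
  channel <- as.integer(channel)
  stopifnot(length(channel) == 1, channel %in% 1:4)
  x@data[, , channel]
})

#' Nucleus label image accessor
#'
#' @param x A [NucleusLabelMap-class] or [FieldGroundTruth-class].
#' @return An integer matrix; 0 is background.
#' @name labelMap
NULL

#' @rdname labelMap
#' @export
setMethod("labelMap", "NucleusLabelMap", function(x) x@labels)

#' @rdname labelMap
#' @export
setMethod("labelMap", "FieldGroundTruth", function(x) x@labelMap)

#' Detected spot table accessor
#'
#' @param x A [SpotSet-class].
#' @return A data.frame with columns `x`, `y`, `channel`, `intensity`.
#' @name spots
NULL

#' @rdname spots
#' @export
setMethod("spots", "SpotSet", function(x) x@spots)

#' Per-nucleus summary table accessor
#'
#' @param x A [NucleusLabelMap-class].
#' @return A data.frame with columns `nucleus`, `x`, `y`, `area`.
#' @name nucleusTable
NULL

#' @rdname nucleusTable
#' @export
setMethod("nucleusTable", "NucleusLabelMap", function(x) x@nucleusTable)

#' True per-cell molecule counts of a synthetic field
#'
#' @param x A [FieldGroundTruth-class].
#' @return Integer matrix, one row per nucleus, columns `ch1`, `ch2`, `ch4`.
#' @name trueCounts
NULL

#' @rdname trueCounts
#' @export
setMethod("trueCounts", "FieldGroundTruth", function(x) x@trueCounts)

#' Per-cell count table accessor
#'
#' @param x A [CellCountTable-class].
#' @return A data.frame, one row per nucleus.
#' @name cellCounts
NULL

#' @rdname cellCounts
#' @export
setMethod("cellCounts", "CellCountTable", function(x) x@counts)

#' Per-channel counts of spots not attributed to any nucleus
#'
#' @param x A [CellCountTable-class].
#' @return Named numeric(3) (`ch1`, `ch2`, `ch4`).
#' @name unassignedCounts
NULL

#' @rdname unassignedCounts
#' @export
setMethod("unassignedCounts", "CellCountTable", function(x) x@unassigned)

#' Intake table of a simulated cohort
#'
#' @param x A [BehaviorCohort-class].
#' @return A data.frame with columns `animal_id`, `session`, `phase`,
#'   `intake_ml`.
#' @name intakeTable
NULL

#' @rdname intakeTable
#' @export
setMethod("intakeTable", "BehaviorCohort", function(x) x@intake)

#' Planted escalating animals of a simulated cohort
#'
#' @param x A [BehaviorCohort-class].
#' @return Character vector of animal ids.
#' @name escalators
NULL

#' @rdname escalators
#' @export
setMethod("escalators", "BehaviorCohort", function(x) x@escalators)

setMethod("show", "MultiplexField", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiplexField %d x %d px, 4 channels (3 = DAPI)\n",
              d[2], d[1]))
  cat(sprintf("  animal: %s  field: %s  assay: %s\n",
              object@animalId, object@fieldIndex, object@assay))
})

setMethod("show", "SpotSet", function(object) {
  tab <- table(factor(object@spots$channel, levels = c(1, 2, 4)))
  cat(sprintf("SpotSet: %d puncta (ch1: %d, ch2: %d, ch4: %d)\n",
              nrow(object@spots), tab[[1]], tab[[2]], tab[[3]]))
  cat("  thresholds:",
      paste(names(object@thresholds), signif(object@thresholds, 3),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "NucleusLabelMap", function(object) {
  cat(sprintf("NucleusLabelMap: %d nuclei over %d x %d px\n",
              nrow(object@nucleusTable), ncol(object@labels),
              nrow(object@labels)))
})

setMethod("show", "FieldGroundTruth", function(object) {
  cat(sprintf(
    "FieldGroundTruth: %d nuclei, %d molecules (%d stray)\n",
    nrow(object@trueCounts), nrow(object@dots),
    sum(object@dots$nucleus == 0)))
})

setMethod("show", "CellCountTable", function(object) {
  cat(sprintf("CellCountTable [%s]: %d cells\n", object@fieldId,
              nrow(object@counts)))
  tot <- colSums(object@counts[, c("ch1", "ch2", "ch4"), drop = FALSE])
  cat("  assigned copies:",
      paste(names(tot), tot, sep = "=", collapse = ", "), "\n")
  cat("  unassigned:",
      paste(names(object@unassigned), object@unassigned, sep = "=",
            collapse = ", "), "\n")
})

setMethod("show", "BehaviorCohort", function(object) {
  cat(sprintf(
    "BehaviorCohort: %d animals x %d sessions (%d baseline), %d escalators\n",
    object@spec@nAnimals, object@spec@nSessions + object@spec@baselineSessions,
    object@spec@baselineSessions, length(object@escalators)))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf(
    "CorrelationMatrix: %d sessions x %d metrics, %d significant at q <= %g\n",
    nrow(object@r), ncol(object@r), sum(object@sig, na.rm = TRUE),
    object@alpha))
})
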