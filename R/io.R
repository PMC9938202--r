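## File formats: fields as multi-page 32-bit TIFF (one page per channel)
## with a JSON sidecar recording the intensity scale (TIFF float storage is
## clipped to [0,1]); label maps as 16-bit single-channel TIFF; tables as
## CSV.

sidecarPath <- function(path) paste0(path, ".scale.json")

#' Write a multiplex field as a multi-page TIFF
#'
#' Channels are stored as four 32-bit float pages normalised to [0, 1];
#' the normalisation factor and the field metadata are recorded in a JSON
#' sidecar (`<path>.scale.json`) so that [readField()] restores the
#' original intensities.
#'
#' @param field A [MultiplexField-class].
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "MultiplexField"))
  mx <- max(field@data, 1e-12)
  pages <- lapply(1:4, function(ch) field@data[, , ch] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = mx, animal_id = field@animalId,
         field_index = field@fieldIndex, assay = field@assay),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multiplex field from a multi-page or multi-channel TIFF
#'
#' Accepts four-page greyscale TIFFs (as written by [writeField()], whose
#' sidecar restores intensities and metadata) or a single page with four
#' samples per pixel.
#'
#' @param path TIFF path.
#' @param animalId,fieldIndex,assay Metadata overrides; defaults come from
#'   the sidecar when present.
#' @return A [MultiplexField-class].
#' @export
readField <- function(path, animalId = NULL, fieldIndex = NULL,
                      assay = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3 &&
      dim(pages[[1]])[3] == 4)
    pages <- lapply(1:4, function(ch) pages[[1]][, , ch])
  if (length(pages) != 4)
    stop(sprintf("'%s': expected 4 channels, found %d", path, length(pages)))
  meta <- list(scale = 1, animal_id = NA_character_,
               field_index = NA_integer_, assay = NA_character_)
  sc <- sidecarPath(path)
  if (file.exists(sc)) meta <- modifyList(meta, jsonlite::read_json(sc))
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], 4))
  for (ch in 1:4) arr[, , ch] <- pages[[ch]] * meta$scale
  new("MultiplexField", data = arr,
      animalId = as.character(animalId %||% meta$animal_id),
      fieldIndex = as.integer(fieldIndex %||% meta$field_index),
      assay = as.character(assay %||% meta$assay))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a nucleus label map as 16-bit TIFF
#'
#' @param labels A [NucleusLabelMap-class] (or integer matrix) to write.
#' @param path TIFF path.
#' @return `writeLabelMap` returns `path` invisibly; `readLabelMap` a
#'   [NucleusLabelMap-class].
#' @export
writeLabelMap <- function(labels, path) {
  if (is(labels, "NucleusLabelMap")) labels <- labelMap(labels)
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @param minArea Minimum-area filter applied on read.
#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path, minArea = 0) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  asNucleusLabelMap(round(m * 65535), minArea)
}

#' Write detected spots as CSV
#'
#' Columns: `field_id`, `channel`, `x`, `y`, `intensity`.
#'
#' @param spotSet A [SpotSet-class].
#' @param path CSV path.
#' @param fieldId Field identifier column value.
#' @return Invisibly, `path`.
#' @export
writeSpotsCsv <- function(spotSet, path, fieldId = "field") {
  sp <- spots(spotSet)
  out <- data.frame(field_id = rep(fieldId, nrow(sp)),
                    channel = sp$channel, x = sp$x, y = sp$y,
                    intensity = sp$intensity)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-cell count table as CSV
#'
#' The header comment records the assignment radius; the final rows carry
#' the per-channel unassigned counts under nucleus id 0.
#'
#' @param cct A [CellCountTable-class].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeCellCountsCsv <- function(cct, path) {
  stopifnot(is(cct, "CellCountTable"))
  df <- cellCounts(cct)
  un <- unassignedCounts(cct)
  extra <- data.frame(field_id = cct@fieldId, nucleus = 0L,
                      x = NA_real_, y = NA_real_, area = NA_real_,
                      ch1 = un[["ch1"]], ch2 = un[["ch2"]],
                      ch4 = un[["ch4"]])
  write.csv(rbind(df, extra), path, row.names = FALSE)
  invisible(path)
}

#' Write synthetic ground truth to disk
#'
#' Dots as CSV, label map as 16-bit TIFF.
#'
#' @param truth A [FieldGroundTruth-class].
#' @param dotsPath,labelsPath Output paths.
#' @return Invisibly, `NULL`.
#' @export
writeGroundTruth <- function(truth, dotsPath, labelsPath) {
  write.csv(truth@dots, dotsPath, row.names = FALSE)
  writeLabelMap(truth@labelMap, labelsPath)
  invisible(NULL)
}

#' Write a behaviour table as CSV
#'
#' @param cohort A [BehaviorCohort-class] or intake data.frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeBehaviorCsv <- function(cohort, path) {
  if (is(cohort, "BehaviorCohort")) cohort <- intakeTable(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a behaviour table from CSV
#'
#' @param path CSV with columns `animal_id`, `session`, `intake_ml` and
#'   optionally `phase` (assumed all-training when absent).
#' @return data.frame in the package's intake-table layout.
#' @export
readBehaviorCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "session", "intake_ml")
  if (!all(need %in% names(df)))
    stop("behaviour table needs columns animal_id, session, intake_ml")
  if (is.null(df$phase)) df$phase <- "training"
  df[, c("animal_id", "session", "phase", "intake_ml")]
}
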