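## Dot-to-nucleus assignment and per-cell / per-animal summaries.
##
## A molecule closer than the assignment radius (default 10 px, inclusive)
## to a nucleus is attributed to that nucleus; distance is the Euclidean
## distance from the spot pixel to the nearest pixel of the nucleus mask
## (0 inside). A spot within reach of several nuclei goes to the nearest
## one; exact ties go to the lower label.

## Nearest labelled pixel within maxDist of (x, y); returns 0L if none.
nearestLabel <- function(labels, x, y, maxDist) {
  r <- ceiling(maxDist)
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- max(1L, y - r):min(nr, y + r)
  cols <- max(1L, x - r):min(nc, x + r)
  win <- labels[rows, cols, drop = FALSE]
  nz <- which(win > 0)
  if (!length(nz)) return(0L)
  wy <- rows[(nz - 1L) %% length(rows) + 1L]
  wx <- cols[(nz - 1L) %/% length(rows) + 1L]
  d2 <- (wx - x)^2 + (wy - y)^2
  ok <- d2 <= maxDist^2 + 1e-9
  if (!any(ok)) return(0L)
  lab <- win[nz][ok]; d2 <- d2[ok]
  cand <- lab[d2 == min(d2)]
  as.integer(min(cand))
}

#' Assign detected puncta to nuclei
#'
#' @param spotSet A [SpotSet-class] detected on the same field.
#' @param labels A [NucleusLabelMap-class] of the same dimensions.
#' @param maxDist Assignment radius in pixels (default 10, inclusive).
#' @param fieldId Identifier recorded in the output table.
#' @return A [CellCountTable-class] with one row per nucleus (nuclei with
#'   zero molecules included) and per-channel unassigned counts; assigned
#'   plus unassigned always equals the number of detected spots per channel.
#' @export
assignSpots <- function(spotSet, labels, maxDist = 10, fieldId = "field") {
  stopifnot(is(spotSet, "SpotSet"), is(labels, "NucleusLabelMap"))
  lab <- labelMap(labels)
  if (!identical(as.integer(spotSet@imageDim), as.integer(dim(lab))))
    stop("spot set and label map come from different image dimensions")
  sp <- spots(spotSet)
  ntab <- nucleusTable(labels)
  n <- nrow(ntab)
  chn <- c(1L, 2L, 4L)
  counts <- matrix(0L, nrow = n, ncol = 3,
                   dimnames = list(NULL, c("ch1", "ch2", "ch4")))
  unassigned <- setNames(numeric(3), c("ch1", "ch2", "ch4"))
  if (nrow(sp)) {
    owner <- vapply(seq_len(nrow(sp)), function(i)
      nearestLabel(lab, sp$x[i], sp$y[i], maxDist), integer(1))
    for (k in seq_along(chn)) {
      sel <- sp$channel == chn[k]
      unassigned[k] <- sum(sel & owner == 0L)
      tab <- tabulate(owner[sel], nbins = n)
      if (n) counts[, k] <- tab
    }
  }
  out <- cbind(data.frame(field_id = rep(fieldId, n),
                          nucleus = ntab$nucleus,
                          x = ntab$x, y = ntab$y, area = ntab$area),
               as.data.frame(counts))
  new("CellCountTable", counts = out, unassigned = unassigned,
      fieldId = fieldId, maxDist = maxDist)
}

#' Marker positivity flags per cell
#'
#' A cell is positive for a marker iff its copy number in the marker's
#' channel reaches that marker's threshold (minimum copies, default 1 for
#' all markers).
#'
#' @param counts A [CellCountTable-class] or its `counts` data.frame.
#' @param markerMap Named character mapping channels to markers, e.g.
#'   `c(ch1 = "TH", ch2 = "zif268", ch4 = "Arc")`.
#' @param thresholds Named numeric of minimum copies per marker (>= 1);
#'   markers absent from `thresholds` default to 1.
#' @return Logical matrix, one row per cell, one column per marker.
#' @export
positivity <- function(counts, markerMap = defaultMarkerMap("A"),
                       thresholds = NULL) {
  if (is(counts, "CellCountTable")) counts <- cellCounts(counts)
  stopifnot(all(names(markerMap) %in% c("ch1", "ch2", "ch4")))
  markers <- unname(markerMap)
  if (is.null(thresholds)) thresholds <- setNames(rep(1, 3), markers)
  if (!all(names(thresholds) %in% markers))
    stop(sprintf("unknown marker in thresholds: %s",
                 paste(setdiff(names(thresholds), markers), collapse = ", ")))
  if (any(thresholds < 1)) stop("positivity thresholds must be >= 1 copy")
  th <- setNames(rep(1, length(markers)), markers)
  th[names(thresholds)] <- thresholds
  flags <- vapply(seq_along(markerMap), function(i)
    counts[[names(markerMap)[i]]] >= th[[markers[i]]],
    logical(nrow(counts)))
  flags <- matrix(flags, nrow = nrow(counts),
                  dimnames = list(NULL, markers))
  flags
}

## Exhaustive marker-combination labels, e.g. "TH+/zif268-/Arc+".
comboLabels <- function(markers) {
  grid <- expand.grid(rep(list(c("+", "-")), length(markers)),
                      stringsAsFactors = FALSE)[, length(markers):1,
                                                drop = FALSE]
  apply(grid, 1, function(s) paste0(markers, s, collapse = "/"))
}

#' Ensemble percentages over the marker-combination partition
#'
#' Every cell falls in exactly one of the `2^m` positivity combinations of
#' the assay's markers, so the percentages sum to 100.
#'
#' @param flags Logical matrix from [positivity()].
#' @return Named numeric of percentages, one per combination.
#' @export
ensemblePercentages <- function(flags) {
  markers <- colnames(flags)
  labels <- comboLabels(markers)
  if (nrow(flags) == 0)
    return(setNames(rep(NA_real_, length(labels)), labels))
  cell <- apply(flags, 1, function(f)
    paste0(markers, ifelse(f, "+", "-"), collapse = "/"))
  cnt <- table(factor(cell, levels = labels))
  setNames(100 * as.numeric(cnt) / nrow(flags), labels)
}

#' Default channel-to-marker maps of the two assay panels
#'
#' @param assay `"A"` (TH / zif268 / Arc neuronal panel) or `"B"`
#'   (GFAP / zif268 / Arc astrocyte panel).
#' @return Named character: channels `ch1`, `ch2`, `ch4` to marker names.
#' @export
defaultMarkerMap <- function(assay = c("A", "B")) {
  assay <- match.arg(assay)
  if (assay == "A") c(ch1 = "TH", ch2 = "zif268", ch4 = "Arc")
  else              c(ch1 = "GFAP", ch2 = "zif268", ch4 = "Arc")
}

#' Aggregate one animal's fields into an animal-level summary
#'
#' Copy numbers are summed over the animal's fields (typically 8 fields
#' spanning the imaged region); ensemble percentages are computed over all
#' of the animal's cells. The animal, not the cell, is the statistical unit
#' for downstream group comparisons.
#'
#' @param tables List of [CellCountTable-class] for one animal.
#' @param animalId Animal identifier.
#' @param markerMap,thresholds Passed to [positivity()].
#' @return One-row data.frame: `animal_id`, `n_fields`, `n_cells`, totals
#'   `total_ch1/2/4`, and `pct_<combination>` columns. With zero cells the
#'   percentages are `NA` and a warning is raised.
#' @export
aggregateAnimal <- function(tables, animalId,
                            markerMap = defaultMarkerMap("A"),
                            thresholds = NULL) {
  stopifnot(length(tables) > 0)
  all <- do.call(rbind, lapply(tables, cellCounts))
  tot <- colSums(all[, c("ch1", "ch2", "ch4"), drop = FALSE])
  if (nrow(all) == 0) {
    warning(sprintf("animal %s has zero cells: percentages undefined",
                    animalId))
    pct <- ensemblePercentages(
      matrix(logical(0), 0, 3, dimnames = list(NULL, unname(markerMap))))
  } else {
    pct <- ensemblePercentages(positivity(all, markerMap, thresholds))
  }
  names(pct) <- paste0("pct_", gsub("/", ".", names(pct)))
  cbind(data.frame(animal_id = animalId, n_fields = length(tables),
                   n_cells = nrow(all),
                   total_ch1 = tot[["ch1"]], total_ch2 = tot[["ch2"]],
                   total_ch4 = tot[["ch4"]]),
        as.data.frame(as.list(pct), check.names = FALSE))
}

#' Group means of animal-level summaries
#'
#' Averages animal-level values within groups (animals are the unit of
#' analysis; fields were already summed per animal).
#'
#' @param summaries data.frame of [aggregateAnimal()] rows.
#' @param group Vector of group labels, one per row.
#' @return data.frame of per-group means of all numeric columns.
#' @export
groupMean <- function(summaries, group) {
  stopifnot(nrow(summaries) == length(group))
  num <- summaries[, vapply(summaries, is.numeric, logical(1)), drop = FALSE]
  out <- aggregate(num, by = list(group = group), FUN = mean)
  out[order(out$group), , drop = FALSE]
}
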