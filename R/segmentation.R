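## DAPI nuclei segmentation: Gaussian smoothing, three-level multi-Otsu
## quantisation (nuclei sit at different depths and are not equally bright),
## distance-transform watershed to split touching nuclei, minimum-area
## filtering.

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximisation of the between-class variance over a binned
#' histogram, the k-threshold generalisation of Otsu's method. With
#' `nThresholds = 3` the image is quantised into background plus three
#' foreground intensity tiers.
#'
#' @param img Numeric matrix.
#' @param nThresholds Number of thresholds (default 3).
#' @param nBins Histogram resolution (default 96).
#' @return Increasing numeric vector of `nThresholds` intensity cut points.
#' @export
multiOtsu <- function(img, nThresholds = 3, nBins = 96) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant image: no thresholds exist")
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nBins),
                nbins = nBins)
  w <- h / sum(h)
  W <- cumsum(w)                      # cumulative mass
  M <- cumsum(w * seq_len(nBins))     # cumulative first moment (bin index)
  W0 <- c(0, W); M0 <- c(0, M)
  csum <- function(a, b) {            # class mass / mean-square contribution
    om <- W0[b + 1L] - W0[a + 1L]
    mu <- M0[b + 1L] - M0[a + 1L]
    ifelse(om > 0, mu^2 / om, 0)
  }
  stopifnot(nThresholds == 3)         # fixed three-tier quantisation
  B <- nBins
  best <- -Inf; bestT <- c(1L, 2L, 3L)
  t3 <- seq_len(B - 1L)
  for (t1 in 1L:(B - 3L)) {
    s1 <- csum(0L, t1)
    for (t2 in (t1 + 1L):(B - 2L)) {
      s2 <- s1 + csum(t1, t2)
      tt <- t3[t3 > t2]
      s <- s2 + csum(t2, tt) + csum(tt, B)
      i <- which.max(s)
      if (s[i] > best) { best <- s[i]; bestT <- c(t1, t2, tt[i]) }
    }
  }
  edges[bestT + 1L]                   # upper edge of each lower class
}

## 3x3 maximum filter with reflective borders.
maxFilter3 <- function(img) {
  p <- padReflect(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (dy in 0:2) for (dx in 0:2) {
    if (dy == 1 && dx == 1) next
    out <- pmax(out, p[dy + seq_len(nr), dx + seq_len(nc), drop = FALSE])
  }
  out
}

## Split the tier-union nucleus mask into nuclei. Intensity maxima alone
## cannot seed a dim nucleus that touches a brighter one (the dim cell sits
## entirely on the bright cell's smoothed slope and has no regional maximum
## in any tier), so the split is shape-based: a tolerance watershed on the
## lightly smoothed distance transform of the mask. The tolerance (in
## distance-transform pixels) merges the shallow spurious maxima that the
## medial ridge of an elongated nucleus produces while keeping the deeper
## dip at the neck between touching nuclei. The brightness adaptation
## lives in the three-tier quantisation that builds the mask, which is
## what brings dim nuclei into it at all.
splitMask <- function(mask, smooth = 2, tolerance = 1.5) {
  dt <- matrix(as.numeric(EBImage::distmap(mask * 1)), nrow(mask))
  dts <- gaussianBlur(dt, smooth)
  dts[!mask] <- 0
  ws <- EBImage::watershed(dts, tolerance = tolerance, ext = 1)
  matrix(as.integer(ws), nrow(mask))
}

#' Construct a NucleusLabelMap from a raw label matrix
#'
#' Drops labels below the minimum area, relabels contiguously from 1 in
#' ascending original-label order, and computes per-nucleus centroids and
#' areas.
#'
#' @param labels Integer matrix, 0 = background.
#' @param minArea Minimum retained area in pixels^2.
#' @return A [NucleusLabelMap-class].
#' @export
asNucleusLabelMap <- function(labels, minArea = 0) {
  labels <- matrix(as.integer(labels), nrow(labels))
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  if (length(ids)) {
    areas <- tabulate(labels, nbins = max(ids))[ids]
    keep <- ids[areas >= minArea]
    remap <- integer(max(ids) + 1L)
    remap[keep + 1L] <- seq_along(keep)
    labels <- matrix(remap[labels + 1L], nrow(labels))
    ids <- seq_along(keep)
  }
  if (length(ids)) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[idx]
    tab <- data.frame(
      nucleus = ids,
      x = as.vector(tapply(idx[, 2], lab, mean)),
      y = as.vector(tapply(idx[, 1], lab, mean)),
      area = as.vector(tabulate(lab, nbins = length(ids))))
  } else {
    tab <- data.frame(nucleus = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0))
  }
  new("NucleusLabelMap", labels = labels, nucleusTable = tab)
}

## Brightness-adaptive halo correction. Thresholding a Gaussian-smoothed
## image dilates every nucleus: the t-level set of a step edge blurred with
## sigma lies -sigma*qnorm(t/peak) outside the true edge, and the dimmer
## the nucleus the smaller that halo. Each label is eroded by its own
## predicted halo width (from its peak smoothed intensity), which restores
## near-true boundaries for all three brightness tiers. Only the
## mask/background boundary is eroded; watershed split lines between
## touching nuclei are deep inside the mask and untouched.
haloCorrect <- function(labels, sm, t1, sigma) {
  if (max(labels) == 0) return(labels)
  dt <- matrix(as.numeric(EBImage::distmap((labels > 0) * 1)), nrow(labels))
  out <- labels
  for (i in seq_len(max(labels))) {
    sel <- labels == i
    ratio <- min(t1 / max(sm[sel]), 0.49)
    delta <- -sigma * stats::qnorm(ratio)
    if (delta > 0) out[sel & dt <= delta] <- 0L
  }
  out
}

## The built-in quantise-watershed backend.
quantiseWatershed <- function(dapi, params) {
  sm <- gaussianBlur(dapi, params@dapiSigma)
  if (diff(range(sm)) == 0)           # blank channel: zero nuclei
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  th <- multiOtsu(sm, 3)
  tier <- matrix(0L, nrow(sm), ncol(sm))
  tier <- tier + (sm > th[1]) + (sm > th[2]) + (sm > th[3])
  mask <- tier > 0
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  haloCorrect(splitMask(mask), sm, th[1], params@dapiSigma)
}

#' Segment DAPI nuclei into a label map
#'
#' The default `"quantise-watershed"` backend smooths the DAPI channel with
#' a Gaussian (sigma = `dapiSigma`, default 7 px), quantises the smoothed
#' image into three foreground intensity tiers by multi-level Otsu (the
#' union of the tiers is the nucleus mask, so dim nuclei are detected
#' alongside bright ones), splits touching nuclei with a tolerance
#' watershed on the smoothed distance transform of that mask, and discards
#' components smaller than `minArea`.
#' Alternative backends (e.g. a star-convex polygon segmenter) can be
#' plugged in via [registerBackend()].
#'
#' Regardless of backend, the returned map satisfies the minimum-area and
#' contiguous-labelling invariants: they are enforced on the backend output.
#'
#' @param dapi Numeric matrix, the DAPI (third) channel.
#' @param params A [SegmentationParams-class].
#' @return A [NucleusLabelMap-class]; a blank channel yields an empty map.
#' @export
segmentNuclei <- function(dapi, params = segmentationParams()) {
  stopifnot(is.matrix(dapi))
  validObject(params)
  backend <- getBackend(params@backend)
  raw <- backend(dapi, params)
  if (is(raw, "NucleusLabelMap")) raw <- labelMap(raw)
  if (!identical(dim(raw), dim(dapi)))
    stop("backend returned a label map of mismatched dimensions")
  asNucleusLabelMap(raw, params@minArea)
}
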