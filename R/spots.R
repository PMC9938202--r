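## Single-molecule punctum detection on DoG-filtered channels.

## Candidate maxima: pixels >= all 8 neighbours. The 1-px image border is
## excluded (its neighbourhood is incomplete).
localMaxima <- function(img, threshold) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(cbind(x = integer(0), y = integer(0)))
  ctr <- img[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  best <- ctr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- img[2:(nr - 1) + dy, 2:(nc - 1) + dx, drop = FALSE]
    best <- pmax(best, nb)
  }
  keep <- which(ctr >= best & ctr > threshold, arr.ind = TRUE)
  cbind(x = keep[, 2] + 1L, y = keep[, 1] + 1L)
}

## Greedy non-maximum suppression: highest intensity wins; ties broken by
## (y, x) scan order for determinism.
suppressClose <- function(x, y, val, minSep) {
  n <- length(x)
  if (n <= 1) return(seq_len(n))
  ord <- order(-val, y, x)
  keep <- logical(n)
  sep2 <- minSep^2
  kx <- numeric(0); ky <- numeric(0)
  for (i in ord) {
    if (length(kx) == 0 ||
        all((kx - x[i])^2 + (ky - y[i])^2 >= sep2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  which(keep)
}

#' Detect puncta in one DoG-filtered channel
#'
#' Spots are local maxima (8-neighbourhood) of the filtered image whose
#' value exceeds the channel threshold, greedily pruned so that no two
#' retained spots lie within `minSeparation` pixels of each other (the
#' brighter spot wins). Maxima on the 1-px image border are discarded.
#'
#' @param filtered Numeric matrix, a [dogFilter()] output.
#' @param channel Probe channel id (1, 2 or 4).
#' @param threshold Positive detection threshold on the filtered intensity.
#' @param minSeparation Minimum centre-to-centre distance in pixels
#'   (default 2).
#' @return A [SpotSet-class]; empty if nothing exceeds the threshold.
#' @export
detectSpots <- function(filtered, channel, threshold, minSeparation = 2) {
  stopifnot(is.matrix(filtered), channel %in% c(1, 2, 4), threshold > 0)
  cand <- localMaxima(filtered, threshold)
  x <- as.integer(cand[, "x"]); y <- as.integer(cand[, "y"])
  val <- filtered[cbind(y, x)]
  if (length(x) > 1) {
    keep <- suppressClose(x, y, val, minSeparation)
    x <- x[keep]; y <- y[keep]; val <- val[keep]
  }
  ord <- order(y, x)
  df <- data.frame(x = x[ord], y = y[ord],
                   channel = rep(as.integer(channel), length(x)),
                   intensity = val[ord])
  new("SpotSet", spots = df,
      thresholds = setNames(threshold, paste0("ch", as.integer(channel))),
      minSeparation = minSeparation,
      imageDim = c(nrow(filtered), ncol(filtered)))
}

#' Detect puncta in all probe channels of a field
#'
#' Applies the DoG filter and [detectSpots()] to channels 1, 2 and 4 with
#' their independent thresholds (th1, th2, th4), which are fixed once per
#' assay batch.
#'
#' @param field A [MultiplexField-class].
#' @param thresholds Named numeric(3): `th1`, `th2`, `th4`.
#' @param dog A [DoGParams-class].
#' @param minSeparation Non-maximum-suppression radius in pixels.
#' @return A [SpotSet-class] holding all three channels.
#' @export
detectFieldSpots <- function(field, thresholds,
                             dog = dogParams(), minSeparation = 2) {
  stopifnot(is(field, "MultiplexField"))
  thresholds <- thresholds[c("th1", "th2", "th4")]
  if (any(is.na(thresholds)))
    stop("thresholds must be named th1, th2, th4")
  parts <- lapply(c(1L, 2L, 4L), function(ch) {
    f <- dogFilter(channelImage(field, ch), dog)
    spots(detectSpots(f, ch, thresholds[[paste0("th", ch)]], minSeparation))
  })
  new("SpotSet", spots = do.call(rbind, parts),
      thresholds = setNames(as.numeric(thresholds), c("ch1", "ch2", "ch4")),
      minSeparation = minSeparation,
      imageDim = dim(field@data)[1:2])
}
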