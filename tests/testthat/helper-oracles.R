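## Independent oracles and small fixtures shared across the suite.

## Dense 2-D convolution with an explicitly sampled, normalised Gaussian
## kernel and mirrored (symmetric) borders — the reference for dogFilter.
denseGaussianKernel2 <- function(sigma, radius = ceiling(4 * sigma)) {
  off <- seq(-radius, radius)
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  k / sum(k)
}

reflectIndex <- function(i, n) {
  # symmetric reflection including the edge sample
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

denseConv2 <- function(img, kernel) {
  r <- (nrow(kernel) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      yy <- reflectIndex(y + dy, nr)
      xx <- reflectIndex(x + dx, nc)
      acc <- acc + kernel[dy + r + 1, dx + r + 1] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

## Exhaustive all-pairs dot-to-nucleus assignment: distance from each spot
## to every labelled pixel, nearest nucleus within maxDist wins, ties to
## the lower label.
bruteForceAssign <- function(sp, labels, maxDist = 10) {
  px <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[px]
  vapply(seq_len(nrow(sp)), function(i) {
    if (nrow(px) == 0) return(0L)
    d2 <- (px[, 2] - sp$x[i])^2 + (px[, 1] - sp$y[i])^2
    best <- tapply(d2, lab, min)
    best <- best[best <= maxDist^2 + 1e-9]
    if (!length(best)) return(0L)
    cand <- as.integer(names(best)[best == min(best)])
    min(cand)
  }, integer(1))
}

## Closed-form Benjamini-Hochberg step-up q-values.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  qs <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q[o] <- pmin(qs, 1)
  q
}

## Textbook Kruskal-Wallis rank-sum statistic (no tie correction; valid
## only for tie-free data).
kwRankSum <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  R <- tapply(rk, idx, sum)
  12 / (n * (n + 1)) * sum(R^2 / sizes) - 3 * (n + 1)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

## Majority-vote mapping from segmentation labels to ground-truth labels.
majorityMatch <- function(segLabels, trueLabels) {
  n <- max(segLabels)
  vapply(seq_len(n), function(i) {
    tt <- trueLabels[segLabels == i]
    tt <- tt[tt > 0]
    if (!length(tt)) 0L
    else as.integer(names(sort(table(tt), decreasing = TRUE))[1])
  }, integer(1))
}

## TRUE iff the pipeline recovered every nucleus and every per-cell count
## of a synthetic field exactly, with unassigned counts matching the
## planted stray dots.
exactRecovery <- function(fg, config = punctaConfig()) {
  ss <- detectFieldSpots(fg$field, config@thresholds, config@dog,
                         config@minSeparation)
  seg <- segmentNuclei(channelImage(fg$field, 3), config@segmentation)
  cct <- assignSpots(ss, seg, config@maxDist, "f")
  tl <- labelMap(fg$truth)
  sl <- labelMap(seg)
  nt <- nrow(trueCounts(fg$truth))
  ns <- nrow(nucleusTable(seg))
  if (ns != nt) return(FALSE)
  mt <- majorityMatch(sl, tl)
  if (anyDuplicated(mt) || any(mt == 0)) return(FALSE)
  cc <- as.matrix(cellCounts(cct)[, c("ch1", "ch2", "ch4")])
  if (!all(cc == trueCounts(fg$truth)[mt, , drop = FALSE])) return(FALSE)
  far <- table(factor(fg$truth@dots$channel[fg$truth@dots$nucleus == 0],
                      levels = c(1, 2, 4)))
  all(unassignedCounts(cct) == as.integer(far))
}

## A small two-nucleus touching-pair field (one planted pair).
pairFieldSpec <- function(seed)
  fieldSpec(width = 320, height = 320, nNuclei = 2, touchingFraction = 1,
            seed = seed)
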