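## Synthetic multiplex field generator with exact ground truth.
##
## Emulates what the pipeline must handle in real assays: elliptical nuclei
## of three brightness tiers (cells sit at different depths along the
## optical axis), a configurable fraction of touching nucleus pairs,
## per-cell Poisson molecule counts rendered as 2-D Gaussian puncta, a
## small fraction of stray molecules far from every nucleus, and additive
## Gaussian background noise. Molecule ownership at generation time uses
## the same inclusive 10-pixel rule as the assignment stage, so the ground
## truth is a valid oracle for the whole pipeline.

ASSIGN_RADIUS <- 10  # pixels; must match the assignment default

## Evaluate RNG-dependent code under a fixed seed without disturbing the
## caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Specification of a synthetic multiplex field
#'
#' See [FieldSpec-class] for the meaning of each parameter. Defaults
#' describe a standard high-magnification field: 512 x 512 px, 20 nuclei of
#' 28-40 px semi-major axis in three brightness tiers, 20% of nuclei in
#' touching pairs, 5 expected molecules per cell and channel rendered as
#' 1-px Gaussian puncta of unit amplitude, 5% stray molecules, and
#' background noise of s.d. 0.05 (peak signal-to-noise 20).
#'
#' @param width,height Field size in pixels.
#' @param nNuclei Number of nuclei.
#' @param nucleusRadiusRange Semi-major axis range (pixels).
#' @param nucleusAxisRatioRange Major/minor axis ratio range.
#' @param brightnessTiers Three strictly increasing relative intensities.
#' @param touchingFraction Fraction of nuclei placed as touching pairs.
#' @param perChannelLambda Mean molecules per cell for channels 1, 2, 4.
#' @param dotSigma,dotAmplitude Punctum PSF width (pixels) and peak
#'   intensity.
#' @param farDotFraction Fraction of molecules placed out of reach of every
#'   nucleus.
#' @param minDotSeparation Minimum same-channel molecule spacing (pixels).
#' @param backgroundSigma Additive Gaussian noise s.d.
#' @param seed Integer; fixes the output bit-exactly.
#' @return A [FieldSpec-class].
#' @export
fieldSpec <- function(width = 512, height = 512, nNuclei = 20,
                      nucleusRadiusRange = c(28, 40),
                      nucleusAxisRatioRange = c(1, 1.4),
                      brightnessTiers = c(0.35, 0.65, 1),
                      touchingFraction = 0.2,
                      perChannelLambda = c(ch1 = 5, ch2 = 5, ch4 = 5),
                      dotSigma = 1, dotAmplitude = 1,
                      farDotFraction = 0.05, minDotSeparation = 4,
                      backgroundSigma = 0.05, seed = 1) {
  new("FieldSpec", width = as.integer(width), height = as.integer(height),
      nNuclei = as.integer(nNuclei),
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      nucleusAxisRatioRange = as.numeric(nucleusAxisRatioRange),
      brightnessTiers = as.numeric(brightnessTiers),
      touchingFraction = touchingFraction,
      perChannelLambda = setNames(as.numeric(perChannelLambda),
                                  c("ch1", "ch2", "ch4")),
      dotSigma = dotSigma, dotAmplitude = dotAmplitude,
      farDotFraction = farDotFraction,
      minDotSeparation = minDotSeparation,
      backgroundSigma = backgroundSigma, seed = as.integer(seed))
}

## Radius of a rotated ellipse along a direction phi (from its centre).
ellipseRadius <- function(a, b, theta, phi) {
  psi <- phi - theta
  1 / sqrt((cos(psi) / a)^2 + (sin(psi) / b)^2)
}

## Sample nucleus geometries and centres. Touching pairs are placed with a
## centre distance of 1.02 of the sum of the two directional radii so the
## rendered masks abut (their blurred images fuse into one blob that the
## watershed must split); all other nuclei keep a clear gap.
placeNuclei <- function(spec) {
  n <- spec@nNuclei
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), tier = integer(0),
                      pair = integer(0)))
  a <- runif(n, spec@nucleusRadiusRange[1], spec@nucleusRadiusRange[2])
  ratio <- runif(n, spec@nucleusAxisRatioRange[1],
                 spec@nucleusAxisRatioRange[2])
  b <- a / ratio
  theta <- runif(n, 0, pi)
  tier <- sample.int(3, n, replace = TRUE)
  nPairs <- floor(spec@touchingFraction * n / 2)
  pair <- integer(n)                     # 0 = single, else pair id
  if (nPairs > 0) {
    pid <- rep(seq_len(nPairs), each = 2)
    pair[seq_len(2 * nPairs)] <- pid
  }
  margin <- max(a) + ASSIGN_RADIUS + 4
  if (2 * margin >= min(spec@width, spec@height))
    stop("field too small for the requested nuclei")
  x <- numeric(n); y <- numeric(n)
  placed <- logical(n)
  gap <- 8                               # clear gap between non-pair nuclei
  tries <- 0L; maxTries <- 400L * n
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("placement failure: too many nuclei for the field area")
    if (pair[i] > 0 && i > 1 && pair[i - 1] == pair[i]) {
      ## second member of a touching pair: offset from the first
      phi <- runif(1, 0, 2 * pi)
      d <- 1.02 * (ellipseRadius(a[i - 1], b[i - 1], theta[i - 1], phi) +
                   ellipseRadius(a[i], b[i], theta[i], phi + pi))
      cx <- x[i - 1] + d * cos(phi)
      cy <- y[i - 1] + d * sin(phi)
    } else {
      cx <- runif(1, margin, spec@width - margin)
      cy <- runif(1, margin, spec@height - margin)
    }
    if (cx < margin || cx > spec@width - margin ||
        cy < margin || cy > spec@height - margin) next
    ok <- TRUE
    for (j in seq_len(i - 1L)) {
      if (pair[i] > 0 && pair[j] == pair[i]) next
      phij <- atan2(y[j] - cy, x[j] - cx)
      dmin <- ellipseRadius(a[i], b[i], theta[i], phij) +
        ellipseRadius(a[j], b[j], theta[j], phij + pi) + gap
      if ((x[j] - cx)^2 + (y[j] - cy)^2 < dmin^2) { ok <- FALSE; break }
    }
    if (!ok) {
      ## a failed second pair member restarts the whole pair
      if (pair[i] > 0 && i > 1 && pair[i - 1] == pair[i]) i <- i - 1L
      next
    }
    x[i] <- cx; y[i] <- cy; placed[i] <- TRUE
    i <- i + 1L
  }
  data.frame(x = x, y = y, a = a, b = b, theta = theta, tier = tier,
             pair = pair)
}

## Rasterise nuclei: returns the integer label map and, per pixel, the
## normalised ellipse coordinate q (<= 1 inside). Overlapping pixels go to
## the nucleus with the smaller q (the one whose centre is closer in units
## of its own radius).
rasteriseNuclei <- function(nuc, width, height) {
  labels <- matrix(0L, height, width)
  qbest <- matrix(Inf, height, width)
  for (i in seq_len(nrow(nuc))) {
    r <- ceiling(nuc$a[i]) + 1L
    xs <- max(1L, floor(nuc$x[i] - r)):min(width, ceiling(nuc$x[i] + r))
    ys <- max(1L, floor(nuc$y[i] - r)):min(height, ceiling(nuc$y[i] + r))
    dx <- outer(rep(1, length(ys)), xs - nuc$x[i])
    dy <- outer(ys - nuc$y[i], rep(1, length(xs)))
    ct <- cos(nuc$theta[i]); st <- sin(nuc$theta[i])
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    q <- (u / nuc$a[i])^2 + (v / nuc$b[i])^2
    inside <- q <= 1
    sub <- cbind(rep(ys, times = length(xs))[inside],
                 rep(xs, each = length(ys))[inside])
    qi <- q[inside]
    better <- qi < qbest[sub]
    labels[sub[better, , drop = FALSE]] <- i
    qbest[sub[better, , drop = FALSE]] <- qi[better]
  }
  list(labels = labels, q = qbest)
}

## Pick dot positions on a nucleus' interior pixels (q <= 0.55, i.e. away
## from the mask boundary) honouring the global same-channel spacing.
sampleDotPixels <- function(pool, nDots, placedX, placedY, minSep) {
  xs <- integer(0); ys <- integer(0)
  if (nrow(pool) == 0) return(cbind(x = xs, y = ys))
  sep2 <- minSep^2
  for (k in seq_len(nDots)) {
    for (try in seq_len(60L)) {
      j <- sample.int(nrow(pool), 1L)
      px <- pool[j, 1]; py <- pool[j, 2]
      ax <- c(placedX, xs); ay <- c(placedY, ys)
      if (!length(ax) || all((ax - px)^2 + (ay - py)^2 >= sep2)) {
        xs <- c(xs, px); ys <- c(ys, py)
        break
      }
    }
  }
  cbind(x = xs, y = ys)
}

## Additive rendering of one Gaussian punctum.
renderDot <- function(img, x, y, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  xs <- max(1L, x - r):min(ncol(img), x + r)
  ys <- max(1L, y - r):min(nrow(img), y + r)
  g <- amplitude * exp(-(outer((ys - y)^2, (xs - x)^2, "+")) /
                         (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + g
  img
}

#' Generate a synthetic multiplex field with exact ground truth
#'
#' Renders nuclei into the DAPI (third) channel, Poisson numbers of Gaussian
#' puncta per cell into the probe channels (1, 2, 4), a configurable
#' fraction of stray puncta out of reach of every nucleus, and additive
#' Gaussian background noise. Deterministic given `spec@seed`: the same
#' spec reproduces the field byte-for-byte.
#'
#' @param spec A [FieldSpec-class].
#' @param animalId,fieldIndex,assay Metadata stamped on the field.
#' @return A list with elements `field` ([MultiplexField-class]) and
#'   `truth` ([FieldGroundTruth-class]).
#' @examples
#' fg <- generateField(fieldSpec(nNuclei = 5, seed = 3))
#' fg$truth
#' @export
generateField <- function(spec, animalId = "sim", fieldIndex = 1L,
                          assay = "A") {
  validObject(spec)
  withSeed(spec@seed, {
    w <- spec@width; h <- spec@height
    nuc <- placeNuclei(spec)
    ras <- rasteriseNuclei(nuc, w, h)
    labels <- ras$labels
    img <- array(0, dim = c(h, w, 4))

    ## DAPI: tier brightness on each mask, softened edges
    if (nrow(nuc)) {
      dapi <- matrix(0, h, w)
      bright <- spec@brightnessTiers[nuc$tier]
      on <- labels > 0
      dapi[on] <- bright[labels[on]]
      img[, , 3] <- gaussianBlur(dapi, 1.5)
    }

    ## interior pixel pools per nucleus
    pools <- lapply(seq_len(nrow(nuc)), function(i) {
      sel <- which(labels == i & ras$q <= 0.55, arr.ind = TRUE)
      if (nrow(sel) == 0) sel <- which(labels == i, arr.ind = TRUE)
      cbind(x = sel[, 2], y = sel[, 1])
    })

    ## far-dot candidate pixels: beyond assignment reach of every nucleus,
    ## clear of the image border
    bg <- matrix(1, h, w); bg[labels > 0] <- 0
    dist2nuc <- if (any(labels > 0))
      matrix(as.numeric(EBImage::distmap(bg)), h, w) else
      matrix(Inf, h, w)
    ## stray dots stay out of reach even of the smoothed-halo mask the
    ## segmentation stage sees (the DAPI blur widens masks by ~ dapiSigma*1.5)
    farIdx <- which(dist2nuc > ASSIGN_RADIUS + 14, arr.ind = TRUE)
    farIdx <- farIdx[farIdx[, 1] > 3 & farIdx[, 1] < h - 2 &
                     farIdx[, 2] > 3 & farIdx[, 2] < w - 2, , drop = FALSE]
    farPool <- cbind(x = farIdx[, 2], y = farIdx[, 1])

    channels <- c(1L, 2L, 4L)
    trueCounts <- matrix(0L, nrow(nuc), 3,
                         dimnames = list(NULL, c("ch1", "ch2", "ch4")))
    dots <- list()
    for (k in seq_along(channels)) {
      ch <- channels[k]
      px <- integer(0); py <- integer(0); owner <- integer(0)
      if (nrow(nuc)) {
        nPer <- rpois(nrow(nuc), spec@perChannelLambda[k])
        for (i in seq_len(nrow(nuc))) {
          got <- sampleDotPixels(pools[[i]], nPer[i], px, py,
                                 spec@minDotSeparation)
          px <- c(px, got[, "x"]); py <- c(py, got[, "y"])
          owner <- c(owner, rep(i, nrow(got)))
          trueCounts[i, k] <- nrow(got)
        }
      }
      nOwned <- length(px)
      nFar <- round(nOwned * spec@farDotFraction / (1 - spec@farDotFraction))
      if (nFar > 0 && nrow(farPool) > 0) {
        got <- sampleDotPixels(farPool, nFar, px, py, spec@minDotSeparation)
        px <- c(px, got[, "x"]); py <- c(py, got[, "y"])
        owner <- c(owner, rep(0L, nrow(got)))
      }
      ch_img <- matrix(0, h, w)
      for (d in seq_along(px))
        ch_img <- renderDot(ch_img, px[d], py[d], spec@dotSigma,
                            spec@dotAmplitude)
      img[, , ch] <- ch_img
      dots[[k]] <- data.frame(x = px, y = py,
                              channel = rep(ch, length(px)),
                              nucleus = owner)
    }
    dots <- do.call(rbind, dots)

    if (spec@backgroundSigma > 0)
      img <- pmax(img + array(rnorm(length(img), 0, spec@backgroundSigma),
                              dim = dim(img)), 0)

    field <- new("MultiplexField", data = img,
                 animalId = animalId, fieldIndex = as.integer(fieldIndex),
                 assay = assay)
    truth <- new("FieldGroundTruth", labelMap = labels,
                 trueCounts = trueCounts, dots = dots)
    list(field = field, truth = truth)
  })
}
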