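## Gaussian smoothing and difference-of-Gaussians band-pass filtering.
## Kernels are explicitly sampled at integer offsets, normalised to sum 1,
## and truncated at 4 sigma; borders use symmetric (reflective) padding, so
## a constant image is mapped to itself by the blur and to zero by the DoG.

#' Sampled, normalised 1-D Gaussian kernel
#'
#' @param sigma Standard deviation in pixels.
#' @param radius Truncation radius in pixels; default `ceiling(4 * sigma)`.
#' @return Numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gaussianKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0, radius >= 0)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

## Symmetric (edge-including) reflection pad of a matrix by r rows/cols.
padReflect <- function(m, r) {
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc)
    stop("image smaller than the filter support")
  ri <- c(rev(seq_len(r)), seq_len(nr), nr + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(nc), nc + 1 - seq_len(r))
  m[ri, ci, drop = FALSE]
}

## 1-D convolution along rows then columns of a padded matrix, by shifted
## accumulation (fast enough in base R for 512 x 512 fields).
convSeparable <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  p <- padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  ## along columns (vertical pass)
  v <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(kernel))
    v <- v + kernel[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  ## along rows (horizontal pass)
  out <- matrix(0, nr, nc)
  for (i in seq_along(kernel))
    out <- out + kernel[i] * v[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

#' Gaussian blur of an intensity image
#'
#' Separable convolution with a sampled, normalised Gaussian kernel and
#' reflective border padding.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Numeric matrix of the same dimensions.
#' @export
gaussianBlur <- function(img, sigma) {
  stopifnot(is.matrix(img), length(img) > 0)
  convSeparable(img, gaussianKernel(sigma))
}

#' Difference-of-Gaussians band-pass filter
#'
#' Enhances diffraction-limited puncta and removes background: the image is
#' blurred with a small Gaussian (`sigmaSmall`, default 0.5 px) to enhance
#' signal and the background estimated by a larger blur (`sigmaLarge`,
#' default 3 px) is subtracted. The result may be negative; constant images
#' map exactly to zero.
#'
#' @param img Numeric matrix (one probe channel).
#' @param params A [DoGParams-class]; defaults to `dogParams()`.
#' @return Numeric matrix of the filtered image, same dimensions.
#' @examples
#' img <- matrix(0, 31, 31); img[16, 16] <- 1
#' f <- dogFilter(img)
#' which(f == max(f), arr.ind = TRUE)  # response peaks at the impulse
#' @export
dogFilter <- function(img, params = dogParams()) {
  stopifnot(is.matrix(img))
  if (length(img) == 0) stop("empty image")
  validObject(params)
  gaussianBlur(img, params@sigmaSmall) - gaussianBlur(img, params@sigmaLarge)
}
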