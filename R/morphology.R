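#' @useDynLib mammodensity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Grayscale morphology and smoothing primitives
#'
#' Flat-disk grayscale erosion/dilation, separable Gaussian smoothing,
#' median filtering and Sobel gradient magnitude on plain numeric matrices.
#' These operate on (and return) numeric matrices; [gray_image] inputs are
#' unwrapped automatically.
#'
#' @param x numeric matrix or [gray_image].
#' @param radius structuring-element / window radius in pixels (>= 1).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return numeric matrix of the filtered image.
#' @name morphology
NULL

as_pixel_matrix <- function(x) {
  if (is_gray_image(x)) x$pixels * 1.0 else x * 1.0
}

#' @rdname morphology
#' @export
erode_gray <- function(x, radius) {
  stopifnot(radius >= 1)
  cpp_morph_disk(as_pixel_matrix(x), as.integer(radius), FALSE)
}

#' @rdname morphology
#' @export
dilate_gray <- function(x, radius) {
  stopifnot(radius >= 1)
  cpp_morph_disk(as_pixel_matrix(x), as.integer(radius), TRUE)
}

#' @rdname morphology
#' @export
gaussian_blur <- function(x, sigma) {
  cpp_convolve_sep(as_pixel_matrix(x), gaussian_kernel(sigma))
}

#' @rdname morphology
#' @export
median_filter <- function(x, radius = 1L) {
  stopifnot(radius >= 1)
  cpp_median_filter(as_pixel_matrix(x), as.integer(radius))
}

#' Smooth / de-noise an image
#'
#' Standard de-noising pass applied before thresholding of the
#' background-subtracted image. `size` is the full window width for the
#' median filter (odd, default 3) and the standard deviation in pixels for
#' the Gaussian.
#'
#' @param image a [gray_image].
#' @param method `"median"` (default) or `"gaussian"`.
#' @param size window width (median) or sigma (Gaussian).
#' @return a [gray_image] with the same bit depth.
#' @export
denoise <- function(image, method = c("median", "gaussian"), size = 3) {
  stopifnot(is_gray_image(image), size >= 1)
  method <- match.arg(method)
  px <- as_pixel_matrix(image)
  out <- switch(method,
    median = cpp_median_filter(px, as.integer((size - 1) / 2)),
    gaussian = gaussian_blur(px, size))
  mx <- 2^image$bit_depth - 1
  gray_image(matrix(as.integer(pmin(pmax(round(out), 0), mx)),
                    nrow(out), ncol(out)), image$bit_depth)
}

#' Sobel edge magnitude ("find edges")
#'
#' 3x3 Sobel gradient magnitude, clamped to the image bit depth. Constant
#' regions map to zero; the response is invariant to adding a constant
#' offset to the image.
#'
#' @param image a [gray_image].
#' @return a [gray_image] of the edge magnitude.
#' @export
find_edges <- function(image) {
  stopifnot(is_gray_image(image))
  g <- cpp_sobel(as_pixel_matrix(image))
  mx <- 2^image$bit_depth - 1
  gray_image(matrix(as.integer(pmin(round(g), mx)), nrow(g), ncol(g)),
             image$bit_depth)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with
#' a ball-shaped structuring element of the given radius and subtracts it,
#' flooring at zero. For radii above 16 px the opening is computed on a
#' min-pooled image (shrink factor `floor(radius/16)`) and interpolated
#' back, the classic speed-up for large balls. The output never exceeds the
#' input anywhere.
#'
#' @param image a [gray_image].
#' @param radius ball radius in pixels (>= 1); default 50.
#' @return a [gray_image] with background removed.
#' @export
rolling_ball_subtract <- function(image, radius = 50) {
  stopifnot(is_gray_image(image), radius >= 1)
  px <- as_pixel_matrix(image)
  shrink <- max(1L, as.integer(radius %/% 16))
  if (shrink > 1L) {
    small <- cpp_min_pool(px, shrink)
    op <- cpp_morph_ball(cpp_morph_ball(small, radius / shrink, FALSE),
                         radius / shrink, TRUE)
    bg <- cpp_bilinear_resize(op, nrow(px), ncol(px))
  } else {
    bg <- cpp_morph_ball(cpp_morph_ball(px, radius, FALSE), radius, TRUE)
  }
  bg <- pmin(bg, px)  # opening may overshoot after interpolation
  out <- pmax(px - bg, 0)
  gray_image(matrix(as.integer(round(out)), nrow(px), ncol(px)),
             image$bit_depth)
}

#' Connected-component labelling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels (0 = background) with attribute
#'   `n_labels`; labels are assigned in row-major scan order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Watershed splitting of a binary mask
#'
#' Splits touching objects along ridge lines of the Euclidean distance
#' transform: connected plateaus of distance maxima seed a priority flood
#' over descending distance. Labels partition the mask exactly, and the
#' label count is at least the connected-component count.
#'
#' @param mask logical matrix (dense-tissue mask).
#' @return integer label matrix with attribute `n_labels`; empty masks give
#'   zero labels.
#' @export
watershed_split <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  cpp_watershed_binary(mask)
}

#' Binary thinning (skeletonization)
#'
#' Zhang-Suen iterative thinning to a one-pixel-wide, topology-preserving
#' centerline skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the skeleton.
#' @export
thin <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(mask)
  out <- cpp_thin(mask)
  dimnames(out) <- NULL
  out
}
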