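#' Remove a patient-identification tag
#'
#' Digitized film mammograms often carry a bright identification tag in a
#' corner of the film. In `auto` mode the tag is detected as a bright
#' 8-connected component that touches the two borders adjacent to an image
#' corner, occupies less than `max_frac` of the image, and whose mean
#' intensity lies above the global minimum-error threshold. Detected tag
#' pixels (their bounding box) are replaced by the image minimum (film
#' background), so they cannot enter any downstream mask. An explicit
#' rectangle may be given instead.
#'
#' @param image a [gray_image].
#' @param rect optional integer vector `c(row0, row1, col0, col1)` (1-based,
#'   inclusive) to blank explicitly; overrides auto detection.
#' @param max_frac maximum tag area as a fraction of the image (default 0.05).
#' @return a [gray_image] with the tag blanked; attribute `tag_mask` is a
#'   logical matrix of the removed region (all-`FALSE` when nothing found).
#' @export
crop_tag <- function(image, rect = NULL, max_frac = 0.05) {
  stopifnot(is_gray_image(image))
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  tag <- matrix(FALSE, nr, nc)
  if (!is.null(rect)) {
    stopifnot(length(rect) == 4)
    if (rect[1] < 1 || rect[2] > nr || rect[3] < 1 || rect[4] > nc ||
        rect[1] > rect[2] || rect[3] > rect[4])
      stop("explicit crop rectangle outside the image")
    if ((rect[2] - rect[1] + 1) * (rect[4] - rect[3] + 1) > 0.5 * nr * nc)
      stop("crop rectangle would remove more than 50% of the image")
    tag[rect[1]:rect[2], rect[3]:rect[4]] <- TRUE
  } else {
    hist <- build_histogram(image)
    t_lvl <- tryCatch(min_error_threshold(hist), error = function(e) NULL)
    if (!is.null(t_lvl)) {
      cut <- level_to_intensity(t_lvl, image$bit_depth, hist$n_levels)
      fg <- px > cut
      lab <- label_components(fg, 8L)
      n <- attr(lab, "n_labels")
      if (n > 0) {
        areas <- tabulate(lab[lab > 0L], nbins = n)
        # border occupancy per label
        top <- unique(lab[1, ]); bottom <- unique(lab[nr, ])
        left <- unique(lab[, 1]); right <- unique(lab[, nc])
        cornerish <- function(l) {
          (l %in% top | l %in% bottom) & (l %in% left | l %in% right)
        }
        gmean <- vapply(seq_len(n), function(l) mean(px[lab == l]), 0)
        for (l in seq_len(n)) {
          if (areas[l] < max_frac * nr * nc && cornerish(l) &&
              gmean[l] > cut) {
            rr <- range(which(rowSums(lab == l) > 0))
            cc <- range(which(colSums(lab == l) > 0))
            tag[rr[1]:rr[2], cc[1]:cc[2]] <- TRUE
          }
        }
      }
    }
  }
  if (any(tag)) px[tag] <- min(image$pixels)
  out <- gray_image(px, image$bit_depth)
  attr(out, "tag_mask") <- tag
  out
}

#' Extract the breast region
#'
#' Builds the breast/background separation used throughout the pipeline:
#' grayscale erosion (suppressing thin bright artifacts) followed by
#' Gaussian smoothing gives a working image whose 256-level histogram is
#' split by the Kittler-Illingworth minimum-error threshold; the largest
#' 8-connected foreground component is retained as the breast. Defaults
#' (`erosion_radius = 5`, `blur_sigma = 4` at 1000 px image height) scale
#' linearly with image height.
#'
#' @param image a [gray_image] (tag already removed).
#' @param erosion_radius structuring-disk radius in px, or `NULL` to scale
#'   with height.
#' @param blur_sigma Gaussian sigma in px, or `NULL` to scale with height.
#' @return a [breast_mask].
#' @export
background_mask <- function(image, erosion_radius = NULL, blur_sigma = NULL) {
  stopifnot(is_gray_image(image))
  h <- nrow(image$pixels)
  if (is.null(erosion_radius)) erosion_radius <- max(1L, round(5 * h / 1000))
  if (is.null(blur_sigma)) blur_sigma <- max(0.5, 4 * h / 1000)
  stopifnot(erosion_radius >= 1, blur_sigma > 0)
  work <- gaussian_blur(erode_gray(image, erosion_radius), blur_sigma)
  mx <- 2^image$bit_depth - 1
  wimg <- gray_image(matrix(as.integer(pmin(pmax(round(work), 0), mx)),
                            nrow(work), ncol(work)), image$bit_depth)
  hist <- build_histogram(wimg)
  if (sum(hist$counts > 0) < 2L || stats::sd(wimg$pixels) < 1e-8)
    stop("degenerate input: image is (near-)constant, no breast/background split")
  t_lvl <- min_error_threshold(hist)
  cut <- level_to_intensity(t_lvl, image$bit_depth, hist$n_levels)
  fg <- wimg$pixels > cut
  if (!any(fg)) stop("degenerate input: empty foreground after thresholding")
  lab <- label_components(fg, 8L)
  n <- attr(lab, "n_labels")
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(areas)  # largest component; ties -> first in scan order
  breast_mask(lab == keep)
}
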