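#' @import data.table
NULL

# grouped sample moments; returns skewness and excess kurtosis (NA when the
# group is constant)
moment_stats <- function(n, s1, s2, s3, s4) {
  m <- s1 / n
  m2 <- s2 / n - m^2
  m3 <- s3 / n - 3 * m * s2 / n + 2 * m^3
  m4 <- s4 / n - 4 * m * s3 / n + 6 * m^2 * s2 / n - 3 * m^4
  sd2 <- pmax(m2, 0)
  skew <- ifelse(sd2 > 1e-12, m3 / sd2^1.5, NA_real_)
  kurt <- ifelse(sd2 > 1e-12, m4 / sd2^2 - 3, NA_real_)
  list(mean = m, var = sd2, skew = skew, kurt = kurt)
}

mode_lowest <- function(v) {
  r <- rle(sort(v))
  r$values[which.max(r$lengths)]
}

# shoelace area of the convex hull of a point set (pixel corners)
hull_area <- function(x, y) {
  if (length(x) < 3) return(NA_real_)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(hx)
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
}

#' Per-object particle measurements
#'
#' Computes the full shape/intensity measurement set for every labelled
#' object: area, traced-boundary perimeter (8-connected chain, diagonal
#' steps weighted sqrt(2)), circularity `4*pi*area/perimeter^2`, solidity
#' (area / convex-hull area, hull taken over pixel corners), mean, modal
#' (ties to the lowest level) and median gray, integrated density (sum of
#' member intensities = area x mean gray), skewness and excess kurtosis of
#' member intensities, and the best-fit ellipse from second-order spatial
#' moments (full major/minor axes normalized to the object area, angle in
#' degrees counter-clockwise from the x axis in `[0, 180)`).
#'
#' Shape statistics of single-pixel objects are undefined (`NaN`).
#'
#' @param labels integer label matrix (0 = background), e.g. from
#'   [label_components()] or [watershed_split()].
#' @param image the [gray_image] the labels refer to.
#' @param clamp_circularity clamp circularity at 1.0? Digitization can push
#'   slightly above 1 for small objects; default `FALSE` keeps raw values.
#' @return a `data.frame` with one row per label.
#' @export
measure_objects <- function(labels, image, clamp_circularity = FALSE) {
  stopifnot(is.matrix(labels), is_gray_image(image),
            all(dim(labels) == dim(image$pixels)))
  n_lab <- max(0L, as.integer(attr(labels, "n_labels") %||% max(labels)))
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      solidity = numeric(0), mean_gray = numeric(0),
                      modal_gray = numeric(0), median_gray = numeric(0),
                      integrated_density = numeric(0), skewness = numeric(0),
                      kurtosis = numeric(0), major = numeric(0),
                      minor = numeric(0), angle = numeric(0))
  if (n_lab == 0L) return(empty)
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  v <- as.numeric(image$pixels[idx])
  x <- (idx - 1L) %/% nr   # column, 0-based
  y <- (idx - 1L) %% nr    # row, 0-based
  dt <- data.table(lab = lab, v = v, x = x, y = y)
  agg <- dt[, .(n = .N, s1 = sum(v), s2 = sum(v^2), s3 = sum(v^3),
                s4 = sum(v^4), med = as.numeric(stats::median(v)),
                mode = as.numeric(mode_lowest(v)),
                sx = sum(as.numeric(x)), sy = sum(as.numeric(y)),
                sxx = sum(as.numeric(x)^2), syy = sum(as.numeric(y)^2),
                sxy = sum(as.numeric(x) * y)), keyby = lab]
  ms <- moment_stats(agg$n, agg$s1, agg$s2, agg$s3, agg$s4)

  # best-fit ellipse from central second moments (+ 1/12 per-pixel term)
  mxx <- agg$sxx / agg$n - (agg$sx / agg$n)^2 + 1 / 12
  myy <- agg$syy / agg$n - (agg$sy / agg$n)^2 + 1 / 12
  mxy <- agg$sxy / agg$n - agg$sx * agg$sy / agg$n^2
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- pmax((mxx + myy - common) / 2, 1e-12)
  a <- 2 * sqrt(l1)  # semi-axes of the moment ellipse
  b <- 2 * sqrt(l2)
  scl <- sqrt(agg$n / (pi * a * b))  # normalize ellipse area to object area
  major <- 2 * a * scl
  minor <- 2 * b * scl
  ang <- 0.5 * atan2(-2 * mxy, mxx - myy) * 180 / pi  # y-up convention
  ang <- ang %% 180

  per <- cpp_perimeters(labels, n_lab)[agg$lab]
  circ <- ifelse(per > 0, 4 * pi * agg$n / per^2, NA_real_)
  if (clamp_circularity) circ <- pmin(circ, 1)

  # solidity: convex hull over corner points of boundary pixels
  bnd <- boundary_pixels(labels)
  bdt <- data.table(lab = labels[bnd], x = (bnd - 1L) %/% nr,
                    y = (bnd - 1L) %% nr)
  hulls <- bdt[, .(hull = hull_area(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
                                    c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))),
               keyby = lab]
  solidity <- pmin(agg$n / hulls$hull[match(agg$lab, hulls$lab)], 1)

  out <- data.frame(label = agg$lab, area = as.numeric(agg$n),
                    perimeter = per, circularity = circ, solidity = solidity,
                    mean_gray = ms$mean, modal_gray = agg$mode,
                    median_gray = agg$med,
                    integrated_density = agg$s1,
                    skewness = ms$skew, kurtosis = ms$kurt,
                    major = major, minor = minor, angle = ang)
  single <- out$area <= 1
  out[single, c("circularity", "solidity", "skewness", "kurtosis")] <- NaN
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear indices of pixels with a 4-neighbour of a different label
boundary_pixels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- function(shift_r, shift_c) {
    m <- matrix(-1L, nr, nc)
    rs <- max(1, 1 + shift_r):min(nr, nr + shift_r)
    cs <- max(1, 1 + shift_c):min(nc, nc + shift_c)
    m[rs, cs] <- labels[rs - shift_r, cs - shift_c]
    m
  }
  b <- labels > 0L &
    (labels != pad(1, 0) | labels != pad(-1, 0) |
     labels != pad(0, 1) | labels != pad(0, -1))
  which(b)
}

#' Size-class summaries of an object table
#'
#' Objects are binned by area into half-open classes `[breaks[i],
#' breaks[i+1])`. Each class reports Count, TotalArea, AverageSize
#' (TotalArea / Count) and AreaFraction (percent of the breast area), the
#' summed integrated density, and the unweighted mean over member objects of
#' every per-object intensity/shape statistic. Classes with no members keep
#' the definitional zeros (count, total area, area fraction) and `NaN` for
#' everything that averages over members — the "NaN" semantics that the
#' missingness filter later consumes.
#'
#' @param objects output of [measure_objects()].
#' @param breaks strictly increasing area edges, e.g. `c(1, 101, 1001, Inf)`
#'   for the 1-100 / 101-1000 / 1001+ pixel classes, or `c(5, Inf)` for a
#'   single 5+ class.
#' @param breast_area denominator for AreaFraction (total breast pixels).
#' @param class_names optional names, default derived from breaks.
#' @return a `data.frame`, one row per size class, 16 statistics each.
#' @export
summarize_sizeclass <- function(objects, breaks, breast_area,
                                class_names = NULL) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("bin edges must be strictly increasing")
  nb <- length(breaks) - 1L
  stopifnot(nb >= 1L, breast_area > 0)
  if (is.null(class_names)) {
    class_names <- vapply(seq_len(nb), function(i) {
      if (is.infinite(breaks[i + 1])) paste0(breaks[i], "+")
      else paste0(breaks[i], "-", breaks[i + 1] - 1)
    }, "")
  }
  aggs <- c("mean_gray", "modal_gray", "median_gray", "skewness", "kurtosis",
            "circularity", "solidity", "perimeter", "major", "minor", "angle")
  res <- lapply(seq_len(nb), function(i) {
    sel <- objects$area >= breaks[i] & objects$area < breaks[i + 1]
    o <- objects[sel, , drop = FALSE]
    n <- nrow(o)
    base <- data.frame(class = class_names[i], count = n,
                       total_area = sum(o$area),
                       average_size = if (n > 0) sum(o$area) / n else NaN,
                       area_fraction = 100 * sum(o$area) / breast_area,
                       integrated_density = if (n > 0) sum(o$integrated_density) else NaN)
    for (s in aggs)
      base[[s]] <- if (n > 0) mean(o[[s]], na.rm = TRUE) else NaN
    base
  })
  out <- do.call(rbind, res)
  out[is.na(out)] <- NaN  # empty na.rm means collapse to NaN, keep as NaN
  out
}

# ---- the fixed feature layout ----------------------------------------------

sizeclass_stats <- function() {
  c("count", "total_area", "average_size", "area_fraction",
    "integrated_density", "mean_gray", "modal_gray", "median_gray",
    "skewness", "kurtosis", "circularity", "solidity", "perimeter",
    "major", "minor", "angle")
}

# 32-bit FNV-1a over a string; arithmetic kept exact by 16-bit splitting
hash32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- ((h %% 65536) * prime + ((h %/% 65536 * prime) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' The fixed per-image feature layout
#'
#' Declares the ordered, named slot list produced by [extract_features()]:
#' whole-breast intensity statistics, edge-pass (Sobel) statistics, and for
#' each registered thresholding method the size-class summaries of two
#' segmentation variants — variant A (the preprocessed image, single 5+
#' pixel class) and variant B (rolling-ball background subtraction +
#' de-noising + watershed splitting, classes 1-100 / 101-1000 / 1001+) —
#' plus a binary-thinning pass (skeleton pixel count and skeleton/area
#' ratio). With the default 15-method roster the layout has 1008 slots.
#' The layout carries a content hash; feature files are validated against
#' it, not against the slot count.
#'
#' @param methods thresholding-method roster (default [threshold_methods()]).
#' @return object of class `md_layout`: `slots`, `methods`, `version`,
#'   `hash`.
#' @export
feature_layout <- function(methods = threshold_methods()) {
  st <- sizeclass_stats()
  wb <- paste0("wb_", c("area", "mean", "sd", "median", "mode", "skew",
                        "kurt", "min", "max", "iqr"))
  edge <- paste0("edge_", c("mean", "sd", "median", "mode", "skew", "kurt",
                            "max", "integrated"))
  per_method <- function(m) {
    c(paste0(m, "_A_ge5_", st),
      paste0(m, "_B_1_100_", st),
      paste0(m, "_B_101_1000_", st),
      paste0(m, "_B_1001p_", st),
      paste0(m, "_thin_pixels"), paste0(m, "_thin_fraction"))
  }
  slots <- c(wb, edge, unlist(lapply(methods, per_method)))
  structure(list(slots = slots, methods = methods, version = "1",
                 hash = hash32(paste(c("v1", slots), collapse = "\x1f"))),
            class = "md_layout")
}

#' @export
print.md_layout <- function(x, ...) {
  cat(sprintf("<md_layout v%s: %d slots, %d methods, hash %s>\n",
              x$version, length(x$slots), length(x$methods), x$hash))
  invisible(x)
}

region_stats <- function(values, prefix) {
  v <- as.numeric(values)
  n <- length(v)
  m <- mean(v)
  ms <- moment_stats(n, sum(v), sum(v^2), sum(v^3), sum(v^4))
  if (prefix == "wb") {
    out <- c(n, m, stats::sd(v), stats::median(v), mode_lowest(v),
             ms$skew, ms$kurt, min(v), max(v),
             stats::IQR(v))
    names(out) <- paste0("wb_", c("area", "mean", "sd", "median", "mode",
                                  "skew", "kurt", "min", "max", "iqr"))
  } else {
    out <- c(m, stats::sd(v), stats::median(v), mode_lowest(v),
             ms$skew, ms$kurt, max(v), sum(v))
    names(out) <- paste0("edge_", c("mean", "sd", "median", "mode", "skew",
                                    "kurt", "max", "integrated"))
  }
  out
}

#' Extract the fixed-layout feature vector of one image
#'
#' Runs the full per-image measurement battery (see [feature_layout()]) and
#' returns a named numeric vector in layout order. A failing pass (e.g. a
#' histogram a mode-seeking method cannot split, or a size class with no
#' objects) records `NaN` in its slots and never aborts the vector. The
#' vector is bit-exactly reproducible for the same image and parameters.
#'
#' @param image a [gray_image] (tag-cropped).
#' @param mask a [breast_mask] from [background_mask()].
#' @param layout an `md_layout`.
#' @param rolling_ball_radius background-subtraction ball radius (px).
#' @param denoise_size median-filter window for variant B.
#' @return named numeric vector of `length(layout$slots)`.
#' @export
extract_features <- function(image, mask, layout = feature_layout(),
                             rolling_ball_radius = 50, denoise_size = 3) {
  stopifnot(is_gray_image(image), inherits(mask, "breast_mask"),
            inherits(layout, "md_layout"))
  out <- stats::setNames(rep(NaN, length(layout$slots)), layout$slots)
  m <- mask$mask
  barea <- mask$breast_area
  inb <- image$pixels[m]
  out[names(region_stats(inb, "wb"))] <- region_stats(inb, "wb")
  edge_img <- find_edges(image)
  es <- region_stats(edge_img$pixels[m], "edge")
  out[names(es)] <- es

  bimg <- denoise(rolling_ball_subtract(image, rolling_ball_radius),
                  "median", denoise_size)
  hist_a <- build_histogram(image, mask)
  hist_b <- tryCatch(build_histogram(bimg, mask), error = function(e) NULL)
  st <- sizeclass_stats()

  fill_class <- function(summary_row, prefix) {
    vals <- as.numeric(summary_row[1, st])
    out[paste0(prefix, "_", st)] <<- vals
  }

  for (meth in layout$methods) {
    # variant A: threshold the preprocessed image, 5+ px objects
    t_a <- tryCatch(auto_threshold(hist_a, meth), error = function(e) NULL)
    if (!is.null(t_a)) {
      cut_a <- level_to_intensity(t_a, image$bit_depth, hist_a$n_levels)
      dense_a <- apply_threshold(image, mask, cut_a)
      labs_a <- label_components(dense_a$mask, 8L)
      obj_a <- measure_objects(labs_a, image)
      sm_a <- summarize_sizeclass(obj_a, c(5, Inf), barea, "ge5")
      fill_class(sm_a, paste0(meth, "_A_ge5"))
      sk <- thin(dense_a$mask)
      out[paste0(meth, "_thin_pixels")] <- sum(sk)
      out[paste0(meth, "_thin_fraction")] <-
        if (dense_a$area > 0) sum(sk) / dense_a$area else NaN
    }
    # variant B: rolling-ball + de-noise + watershed, three size classes
    if (!is.null(hist_b)) {
      t_b <- tryCatch(auto_threshold(hist_b, meth), error = function(e) NULL)
      if (!is.null(t_b)) {
        cut_b <- level_to_intensity(t_b, bimg$bit_depth, hist_b$n_levels)
        dense_b <- apply_threshold(bimg, mask, cut_b)
        labs_b <- watershed_split(dense_b$mask)
        obj_b <- measure_objects(labs_b, bimg)
        sm_b <- summarize_sizeclass(obj_b, c(1, 101, 1001, Inf), barea,
                                    c("1_100", "101_1000", "1001p"))
        fill_class(sm_b[1, , drop = FALSE], paste0(meth, "_B_1_100"))
        fill_class(sm_b[2, , drop = FALSE], paste0(meth, "_B_101_1000"))
        fill_class(sm_b[3, , drop = FALSE], paste0(meth, "_B_1001p"))
      }
    }
  }
  out
}

#' Append feature vectors to a CSV feature table
#'
#' First column `id`, remaining columns the layout slot names; undefined
#' values serialized as `NaN`.
#'
#' @param features named list of feature vectors (names = image ids), or a
#'   single named vector with `id` given.
#' @param path CSV destination.
#' @param layout the `md_layout` the vectors follow.
#' @param id id for a single vector.
#' @return the path, invisibly.
#' @export
write_feature_csv <- function(features, path, layout = feature_layout(),
                              id = NULL) {
  if (is.numeric(features)) features <- stats::setNames(list(features), id)
  mat <- do.call(rbind, features)
  mat[is.na(mat)] <- NaN  # undefined-marker serialized uniformly as NaN
  stopifnot(identical(colnames(mat), layout$slots))
  df <- data.frame(id = names(features), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV into a feature matrix
#'
#' @param path CSV written by [write_feature_csv()] (or any table with an
#'   `id` first column).
#' @return numeric matrix, rownames = image ids.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
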