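#' Intensity histogram over a masked region
#'
#' All automatic thresholding operates on fixed-width histograms (256 levels
#' by default, the footing on which the classic global-threshold algorithms
#' were formulated). Images deeper than `log2(n_levels)` bits are linearly
#' rescaled into the bins, so total mass is conserved.
#'
#' @param image a [gray_image].
#' @param mask optional [breast_mask] (or logical matrix) restricting the
#'   histogram to the breast region; `NULL` uses the whole image.
#' @param n_levels number of histogram levels (must divide `2^bit_depth`).
#' @return an object of class `md_histogram`: `counts` (length `n_levels`,
#'   level `l` in `counts[l + 1]`), `n_levels`, `total`, and `bin_width`
#'   (intensity units per level).
#' @export
build_histogram <- function(image, mask = NULL, n_levels = 256L) {
  stopifnot(is_gray_image(image))
  px <- image$pixels
  if (!is.null(mask)) {
    m <- if (inherits(mask, "breast_mask")) mask$mask else mask
    stopifnot(is.logical(m), all(dim(m) == dim(px)))
    if (!any(m)) stop("empty mask: histogram undefined")
    px <- px[m]
  }
  n_levels <- as.integer(n_levels)
  binw <- 2^image$bit_depth / n_levels
  if (binw < 1 || binw != as.integer(binw))
    stop("n_levels must divide 2^bit_depth")
  lev <- as.integer(px %/% binw)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  md_histogram(counts, bin_width = as.integer(binw))
}

#' @param counts non-negative integer vector of per-level counts.
#' @param bin_width intensity units covered by one level (default 1).
#' @rdname build_histogram
#' @export
md_histogram <- function(counts, bin_width = 1L) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("histogram has no mass")
  structure(list(counts = counts, n_levels = length(counts), total = total,
                 bin_width = as.integer(bin_width)),
            class = "md_histogram")
}

#' @export
print.md_histogram <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat(sprintf("<md_histogram %d levels, total %.0f, support [%d, %d]>\n",
              x$n_levels, x$total, min(nz), max(nz)))
  invisible(x)
}

#' Histogram CSV import/export
#'
#' Two-column CSV `level,count` with levels `0 .. n_levels-1`.
#'
#' @param hist an `md_histogram`.
#' @param path CSV path.
#' @return `write_histogram_csv` the path invisibly; `read_histogram_csv`
#'   an `md_histogram`.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(data.frame(level = seq_len(hist$n_levels) - 1L,
                              count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("level", "count") %in% names(df)))
  counts <- numeric(max(df$level) + 1L)
  counts[df$level + 1L] <- df$count
  md_histogram(counts)
}

# ---- the threshold-method registry ----------------------------------------

#' Registered global thresholding methods
#'
#' The fifteen-method roster of the classic ImageJ auto-threshold suite:
#' histogram-shape methods (Intermodes, Minimum, Triangle), clustering
#' methods (IsoData, Otsu, Mean, Percentile, Moments, MinError), and
#' entropy-based methods (Huang, Li, MaxEntropy, RenyiEntropy, Shanbhag,
#' Yen). The registry is data-driven; [auto_threshold()] dispatches on it.
#'
#' @return character vector of the 15 method names.
#' @export
threshold_methods <- function() names(.threshold_registry)

#' Automatic global threshold of a histogram
#'
#' Returns the threshold level `t` (0-based, in histogram-level units)
#' selected by the requested method. A pixel is counted as dense iff its
#' level is strictly greater than `t`. All methods are deterministic and
#' break ties toward the lower level.
#'
#' @param hist an `md_histogram` (see [build_histogram()]).
#' @param method one of [threshold_methods()].
#' @return integer level in `0 .. n_levels - 2`.
#' @export
auto_threshold <- function(hist, method) {
  stopifnot(inherits(hist, "md_histogram"))
  fn <- .threshold_registry[[match.arg(method, threshold_methods())]]
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied levels")
  as.integer(fn(hist$counts))
}

# Each method takes the raw counts vector (levels 0..n-1) and returns a
# 0-based level t; foreground is level > t.

# valid split points: both classes non-empty
.split_range <- function(counts) {
  nz <- which(counts > 0)
  if (length(nz) < 2L) stop("degenerate histogram")
  (nz[1] - 1L):(nz[length(nz)] - 2L)  # 0-based t with mass on both sides
}

.th_mean <- function(counts) {
  lev <- seq_along(counts) - 1
  floor(sum(lev * counts) / sum(counts))
}

.th_otsu <- function(counts) {
  p <- counts / sum(counts)
  lev <- seq_along(p) - 1
  w0 <- cumsum(p)
  mu <- cumsum(lev * p)
  muT <- mu[length(mu)]
  ts <- .split_range(counts)
  sb <- (muT * w0[ts + 1] - mu[ts + 1])^2 / (w0[ts + 1] * (1 - w0[ts + 1]))
  ts[which.max(sb)]
}

# Kittler-Illingworth minimum-error criterion, exhaustive scan. Class
# variances are floored at 1/12 (quantization variance) so that delta-spike
# classes stay finite.
.minerr_criterion <- function(counts, ts) {
  p <- counts / sum(counts)
  lev <- seq_along(p) - 1
  w0 <- cumsum(p); s1 <- cumsum(lev * p); s2 <- cumsum(lev^2 * p)
  W0 <- w0[ts + 1]; W1 <- 1 - W0
  M0 <- s1[ts + 1] / W0
  M1 <- (s1[length(s1)] - s1[ts + 1]) / W1
  V0 <- pmax(s2[ts + 1] / W0 - M0^2, 1 / 12)
  V1 <- pmax((s2[length(s2)] - s2[ts + 1]) / W1 - M1^2, 1 / 12)
  1 + 2 * (W0 * log(sqrt(V0)) + W1 * log(sqrt(V1))) -
    2 * (W0 * log(W0) + W1 * log(W1))
}

.th_minerror <- function(counts) {
  ts <- .split_range(counts)
  ts[which.min(.minerr_criterion(counts, ts))]
}

#' Kittler-Illingworth minimum-error threshold
#'
#' The level minimizing the two-Gaussian minimum-classification-error cost,
#' found by exhaustive scan over all split points with mass on both sides;
#' ties broken toward the lower level. Used both in the 15-method roster
#' and for breast/background separation during preprocessing.
#'
#' @inheritParams auto_threshold
#' @return integer level.
#' @export
min_error_threshold <- function(hist) {
  stopifnot(inherits(hist, "md_histogram"))
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied levels")
  as.integer(.th_minerror(hist$counts))
}

.th_huang <- function(counts) {
  # Huang & Wang: minimize fuzzy (Shannon) entropy of the membership map
  nz <- which(counts > 0)
  first <- nz[1] - 1L; last <- nz[length(nz)] - 1L
  C <- last - first
  p <- counts
  lev <- seq_along(p) - 1
  s1 <- cumsum(lev * p); n1 <- cumsum(p)
  tot1 <- s1[length(s1)]; totn <- n1[length(n1)]
  ts <- .split_range(counts)
  best <- Inf; best_t <- ts[1]
  for (t in ts) {
    mu0 <- s1[t + 1] / n1[t + 1]
    mu1 <- (tot1 - s1[t + 1]) / (totn - n1[t + 1])
    mu <- ifelse(lev <= t, 1 / (1 + abs(lev - mu0) / C),
                 1 / (1 + abs(lev - mu1) / C))
    h <- -(mu * log(mu) + (1 - mu) * log(pmax(1 - mu, .Machine$double.xmin)))
    h[mu >= 1] <- 0
    S <- sum(p * h)
    if (S < best) { best <- S; best_t <- t }
  }
  best_t
}

# iterated 3-point mean smoothing until the histogram is bimodal
.smooth_to_bimodal <- function(counts, max_iter = 10000L) {
  h <- counts / sum(counts)
  n <- length(h)
  peaks_of <- function(h) {
    which(h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n]) + 1L
  }
  it <- 0L
  while (length(peaks_of(h)) > 2L) {
    h <- (c(h[1], h[-n]) + h + c(h[-1], h[n])) / 3
    it <- it + 1L
    if (it >= max_iter)
      stop("histogram could not be smoothed to bimodality (method failure)")
  }
  pk <- peaks_of(h)
  if (length(pk) < 2L)
    stop("histogram is unimodal after smoothing (method failure)")
  list(h = h, peaks = pk - 1L)  # 0-based peak levels
}

.th_intermodes <- function(counts) {
  sm <- .smooth_to_bimodal(counts)
  floor((sm$peaks[1] + sm$peaks[2]) / 2)
}

.th_minimum <- function(counts) {
  sm <- .smooth_to_bimodal(counts)
  idx <- (sm$peaks[1] + 1L):(sm$peaks[2] + 1L)  # 1-based between peaks
  idx[which.min(sm$h[idx])] - 1L
}

.th_isodata <- function(counts) {
  # Ridler-Calvard iterative intermeans
  lev <- seq_along(counts) - 1
  rng <- range(which(counts > 0)) - 1L
  t <- floor(sum(lev * counts) / sum(counts))
  t <- min(max(t, rng[1]), rng[2] - 1L)
  for (i in 1:1000) {
    lo <- counts[lev <= t]; hi <- counts[lev > t]
    m0 <- sum(lev[lev <= t] * lo) / sum(lo)
    m1 <- sum(lev[lev > t] * hi) / sum(hi)
    tn <- floor((m0 + m1) / 2)
    tn <- min(max(tn, rng[1]), rng[2] - 1L)
    if (tn == t) break
    t <- tn
  }
  t
}

.th_li <- function(counts) {
  # Li & Tam iterative minimum cross-entropy
  lev <- seq_along(counts) - 1
  tot <- sum(counts)
  t <- sum(lev * counts) / tot
  eps <- .Machine$double.eps
  for (i in 1:1000) {
    below <- lev <= t
    n0 <- sum(counts[below]); n1 <- tot - n0
    m0 <- if (n0 > 0) sum(lev[below] * counts[below]) / n0 else 0
    m1 <- if (n1 > 0) sum(lev[!below] * counts[!below]) / n1 else 0
    m0 <- max(m0, eps); m1 <- max(m1, eps)
    if (abs(m0 - m1) < eps) break
    tn <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(tn - t) < 0.5) { t <- tn; break }
    t <- tn
  }
  rng <- .split_range(counts)
  min(max(floor(t), rng[1]), rng[length(rng)])
}

.th_maxentropy <- function(counts) {
  # Kapur-Sahoo-Wong: maximize total Shannon entropy of the two classes
  p <- counts / sum(counts)
  ts <- .split_range(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cw <- cumsum(p); cpl <- cumsum(plogp)
  totpl <- cpl[length(cpl)]
  best <- -Inf; best_t <- ts[1]
  for (t in ts) {
    w0 <- cw[t + 1]; w1 <- 1 - w0
    h0 <- -(cpl[t + 1] / w0) + log(w0)
    h1 <- -((totpl - cpl[t + 1]) / w1) + log(w1)
    H <- h0 + h1
    if (H > best) { best <- H; best_t <- t }
  }
  best_t
}

.th_moments <- function(counts) {
  # Tsai moment-preserving: match the first three moments with a two-level
  # image, then threshold at the p0-tile of the histogram
  p <- counts / sum(counts)
  lev <- seq_along(p) - 1
  m1 <- sum(lev * p); m2 <- sum(lev^2 * p); m3 <- sum(lev^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  pd <- (z1 - m1) / (z1 - z0)  # fraction of pixels below threshold
  cum <- cumsum(p)
  ts <- .split_range(counts)
  ts[which.min(abs(cum[ts + 1] - pd))]
}

.th_percentile <- function(counts, ptile = 0.5) {
  cum <- cumsum(counts / sum(counts))
  ts <- .split_range(counts)
  ts[which.min(abs(cum[ts + 1] - ptile))]
}

.renyi_scan <- function(p, alpha) {
  # maximize the two-class Renyi entropy of order alpha
  cw <- cumsum(p)
  cpa <- cumsum(p^alpha)
  tot <- cpa[length(cpa)]
  ts <- which(cw > 0 & cw < 1) - 1L
  ts <- ts[ts < length(p) - 1L]
  best <- -Inf; best_t <- ts[1]
  for (t in ts) {
    w0 <- cw[t + 1]; w1 <- 1 - w0
    h0 <- log(cpa[t + 1] / w0^alpha) / (1 - alpha)
    h1 <- log((tot - cpa[t + 1]) / w1^alpha) / (1 - alpha)
    H <- h0 + h1
    if (H > best) { best <- H; best_t <- t }
  }
  best_t
}

.th_renyi <- function(counts) {
  # Sahoo et al.: combine the optimal thresholds at Renyi orders 1/2, 1, 2
  p <- counts / sum(counts)
  t1 <- .renyi_scan(p, 0.5)
  t2 <- .th_maxentropy(counts)       # alpha -> 1 limit is Shannon/Kapur
  t3 <- .renyi_scan(p, 2)
  st <- sort(c(t1, t2, t3))
  ts1 <- st[1]; ts2 <- st[2]; ts3 <- st[3]
  if (abs(ts1 - ts2) <= 5) {
    if (abs(ts2 - ts3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(ts2 - ts3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  cw <- cumsum(p)
  P1 <- function(t) cw[t + 1]
  omega <- P1(ts3) - P1(ts1)
  floor(ts1 * (P1(ts1) + 0.25 * omega * b[1]) +
        0.25 * ts2 * omega * b[2] +
        ts3 * (1 - P1(ts3) + 0.25 * omega * b[3]) + 0.5)
}

.th_shanbhag <- function(counts) {
  # Shanbhag's fuzzy-information measure: minimize |I_background - I_object|
  p <- counts / sum(counts)
  n <- length(p)
  cw <- cumsum(p)
  ts <- .split_range(counts)
  best <- Inf; best_t <- ts[1]
  for (t in ts) {
    w0 <- cw[t + 1]; w1 <- 1 - w0
    term <- 0.5 / w0
    ih <- 2:(t + 1)  # 1-based bins for levels 1..t
    ent_back <- if (t >= 1)
      -sum(p[ih] * log(1 - term * cw[ih - 1L])) * term else 0
    term <- 0.5 / w1
    ih <- (t + 2):(n - 1)  # levels t+1 .. n-2
    ent_obj <- if (length(ih) > 0 && ih[1] <= n - 1)
      -sum(p[ih] * log(1 - term * (1 - cw[ih + 1L]))) * term else 0
    v <- abs(ent_back - ent_obj)
    if (v < best) { best <- v; best_t <- t }
  }
  best_t
}

.th_triangle <- function(counts) {
  # Zack's geometric method: largest perpendicular distance between the
  # histogram and the chord from its peak to the far tail end
  h <- counts / sum(counts)
  n <- length(h)
  nz <- which(h > 0)
  lo <- max(nz[1] - 1L, 1L)          # one bin outside the support
  hi <- min(nz[length(nz)] + 1L, n)
  peak <- which.max(h)               # ties -> lowest
  flip <- (peak - lo) >= (hi - peak) # long tail on the left: mirror
  if (flip) {
    h <- rev(h)
    peak <- n + 1L - peak
    hi <- n + 1L - lo
  }
  # chord from (peak, h[peak]) to (hi, h[hi]); scan between
  xs <- peak:hi
  d <- (h[peak] - h[hi]) * (xs - peak) + (hi - peak) * (h[peak] - h[xs])
  t1 <- xs[which.max(d)]
  if (flip) t1 <- n + 1L - t1
  # clamp so that both classes keep mass (degenerate spike histograms)
  rng <- .split_range(counts)
  min(max(t1 - 1L, rng[1]), rng[length(rng)])
}

.th_yen <- function(counts) {
  # Yen's maximum-correlation criterion
  p <- counts / sum(counts)
  cw <- cumsum(p)
  cp2 <- cumsum(p^2)
  tot2 <- cp2[length(cp2)]
  ts <- .split_range(counts)
  best <- -Inf; best_t <- ts[1]
  for (t in ts) {
    w0 <- cw[t + 1]; w1 <- 1 - w0
    a <- cp2[t + 1]; b <- tot2 - cp2[t + 1]
    TC <- -log(a * b) + 2 * log(w0 * w1)
    if (TC > best) { best <- TC; best_t <- t }
  }
  best_t
}

.threshold_registry <- list(
  IsoData      = .th_isodata,
  Huang        = .th_huang,
  Intermodes   = .th_intermodes,
  Li           = .th_li,
  MaxEntropy   = .th_maxentropy,
  Mean         = .th_mean,
  MinError     = .th_minerror,
  Minimum      = .th_minimum,
  Moments      = .th_moments,
  Otsu         = .th_otsu,
  Percentile   = .th_percentile,
  RenyiEntropy = .th_renyi,
  Shanbhag     = .th_shanbhag,
  Triangle     = .th_triangle,
  Yen          = .th_yen
)

# ---- applying a threshold --------------------------------------------------

#' Convert a histogram level to an intensity cut
#'
#' A threshold computed on an `n_levels` histogram of a deeper image refers
#' to level units; the corresponding intensity cut is the top intensity of
#' that bin, so "level > t" and "intensity > cut" select the same pixels.
#'
#' @param level 0-based histogram level.
#' @param bit_depth image bit depth.
#' @param n_levels histogram levels the threshold was computed at.
#' @return intensity value.
#' @export
level_to_intensity <- function(level, bit_depth, n_levels = 256L) {
  binw <- 2^bit_depth / n_levels
  as.integer((level + 1) * binw - 1)
}

#' Apply an intensity threshold within the breast
#'
#' Pixels with intensity strictly greater than `level` inside the breast
#' mask are dense. The dense-area fraction (dense pixels / breast area) is
#' the percent-density numerator/denominator ratio for that threshold.
#'
#' @param image a [gray_image].
#' @param mask a [breast_mask] (or logical matrix).
#' @param level intensity cut (see [level_to_intensity()]).
#' @return a list of class `dense_mask`: `mask` (logical), `area` (px),
#'   `fraction` (dense / breast area, in `[0, 1]`).
#' @export
apply_threshold <- function(image, mask, level) {
  stopifnot(is_gray_image(image))
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  stopifnot(is.logical(m), all(dim(m) == dim(image$pixels)))
  dense <- m & (image$pixels > level)
  structure(list(mask = dense, area = sum(dense),
                 fraction = sum(dense) / sum(m)),
            class = "dense_mask")
}
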