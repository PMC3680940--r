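# Independent oracle implementations used to cross-check the package.
# Every function here recomputes a published objective with naive loops,
# deliberately sharing no code with the package internals.

# seeded random test histogram: two-Gaussian mixture plus a uniform floor
random_bimodal_hist <- function(seed) {
  set.seed(seed)
  n <- sample(2000:6000, 1)
  w <- runif(1, 0.3, 0.7)
  m1 <- runif(1, 40, 95); s1 <- runif(1, 8, 22)
  m2 <- runif(1, 140, 215); s2 <- runif(1, 8, 25)
  v <- c(rnorm(round(n * w), m1, s1), rnorm(n - round(n * w), m2, s2))
  v <- pmin(pmax(round(v), 0), 255)
  counts <- tabulate(v + 1L, nbins = 256)
  counts + sample(0:2, 256, replace = TRUE)
}

# valid split points (mass on both sides), 0-based
oracle_splits <- function(h) {
  n <- length(h)
  ts <- integer(0)
  for (t in 0:(n - 2)) {
    if (sum(h[1:(t + 1)]) > 0 && sum(h[(t + 2):n]) > 0) ts <- c(ts, t)
  }
  ts
}

oracle_class_stats <- function(h, t) {
  lev <- seq_along(h) - 1
  lo <- lev <= t
  n0 <- sum(h[lo]); n1 <- sum(h[!lo])
  m0 <- sum(lev[lo] * h[lo]) / n0
  m1 <- sum(lev[!lo] * h[!lo]) / n1
  v0 <- sum(h[lo] * (lev[lo] - m0)^2) / n0
  v1 <- sum(h[!lo] * (lev[!lo] - m1)^2) / n1
  list(w0 = n0 / sum(h), w1 = n1 / sum(h), m0 = m0, m1 = m1, v0 = v0, v1 = v1)
}

oracle_otsu <- function(h) {
  best <- -Inf; bt <- NA
  for (t in oracle_splits(h)) {
    s <- oracle_class_stats(h, t)
    sb <- s$w0 * s$w1 * (s$m0 - s$m1)^2
    if (sb > best) { best <- sb; bt <- t }
  }
  bt
}

oracle_minerror <- function(h) {
  best <- Inf; bt <- NA
  for (t in oracle_splits(h)) {
    s <- oracle_class_stats(h, t)
    v0 <- max(s$v0, 1 / 12); v1 <- max(s$v1, 1 / 12)
    J <- 1 + 2 * (s$w0 * log(sqrt(v0)) + s$w1 * log(sqrt(v1))) -
      2 * (s$w0 * log(s$w0) + s$w1 * log(s$w1))
    if (J < best) { best <- J; bt <- t }
  }
  bt
}

oracle_mean <- function(h) {
  lev <- seq_along(h) - 1
  floor(sum(lev * h) / sum(h))
}

oracle_huang <- function(h) {
  lev <- seq_along(h) - 1
  nz <- which(h > 0)
  C <- (nz[length(nz)] - nz[1])
  best <- Inf; bt <- NA
  for (t in oracle_splits(h)) {
    s <- oracle_class_stats(h, t)
    mu <- ifelse(lev <= t, 1 / (1 + abs(lev - s$m0) / C),
                 1 / (1 + abs(lev - s$m1) / C))
    hf <- ifelse(mu >= 1, 0,
                 -(mu * log(mu) + (1 - mu) * log(pmax(1 - mu, 1e-300))))
    S <- sum(h * hf)
    if (S < best) { best <- S; bt <- t }
  }
  bt
}

oracle_maxentropy <- function(h) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA
  for (t in oracle_splits(h)) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    p0 <- p[1:(t + 1)] / w0; p1 <- p[(t + 2):length(p)] / w1
    H <- -sum(p0[p0 > 0] * log(p0[p0 > 0])) - sum(p1[p1 > 0] * log(p1[p1 > 0]))
    if (H > best) { best <- H; bt <- t }
  }
  bt
}

oracle_yen <- function(h) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA
  for (t in oracle_splits(h)) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    a <- sum(p[1:(t + 1)]^2); b <- sum(p[(t + 2):length(p)]^2)
    TC <- -log(a * b) + 2 * log(w0 * w1)
    if (TC > best) { best <- TC; bt <- t }
  }
  bt
}

oracle_moments <- function(h) {
  p <- h / sum(h)
  lev <- seq_along(p) - 1
  m1 <- sum(lev * p); m2 <- sum(lev^2 * p); m3 <- sum(lev^3 * p)
  cd <- m2 - m1 * m1
  c0 <- (m1 * m3 - m2 * m2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(c1 * c1 - 4 * c0)
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  pfrac <- (z1 - m1) / (z1 - z0)
  best <- Inf; bt <- NA
  cum <- 0
  for (t in oracle_splits(h)) {
    cum_t <- sum(p[1:(t + 1)])
    if (abs(cum_t - pfrac) < best) { best <- abs(cum_t - pfrac); bt <- t }
  }
  bt
}

oracle_percentile <- function(h, ptile = 0.5) {
  p <- h / sum(h)
  best <- Inf; bt <- NA
  for (t in oracle_splits(h)) {
    d <- abs(sum(p[1:(t + 1)]) - ptile)
    if (d < best) { best <- d; bt <- t }
  }
  bt
}

oracle_renyi_order <- function(h, alpha) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA
  for (t in 0:(length(p) - 2)) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    h0 <- log(sum((p[1:(t + 1)] / w0)^alpha)) / (1 - alpha)
    h1 <- log(sum((p[(t + 2):length(p)] / w1)^alpha)) / (1 - alpha)
    if (h0 + h1 > best) { best <- h0 + h1; bt <- t }
  }
  bt
}

oracle_renyi <- function(h) {
  t1 <- oracle_renyi_order(h, 0.5)
  t2 <- oracle_maxentropy(h)
  t3 <- oracle_renyi_order(h, 2)
  st <- sort(c(t1, t2, t3))
  if (abs(st[1] - st[2]) <= 5) {
    b <- if (abs(st[2] - st[3]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    b <- if (abs(st[2] - st[3]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  p <- h / sum(h)
  cum <- cumsum(p)
  omega <- cum[st[3] + 1] - cum[st[1] + 1]
  floor(st[1] * (cum[st[1] + 1] + 0.25 * omega * b[1]) +
        0.25 * st[2] * omega * b[2] +
        st[3] * (1 - cum[st[3] + 1] + 0.25 * omega * b[3]) + 0.5)
}

oracle_shanbhag <- function(h) {
  p <- h / sum(h)
  n <- length(p)
  cum <- cumsum(p)
  best <- Inf; bt <- NA
  for (t in oracle_splits(h)) {
    w0 <- cum[t + 1]; w1 <- 1 - w0
    term <- 0.5 / w0
    eb <- if (t >= 1) {
      l <- 1:t
      -sum(p[l + 1] * log(1 - term * cum[l])) * term
    } else 0
    term <- 0.5 / w1
    eo <- if (t + 1 <= n - 2) {
      l <- (t + 1):(n - 2)
      -sum(p[l + 1] * log(1 - term * (1 - cum[l + 2]))) * term
    } else 0
    v <- abs(eb - eo)
    if (v < best) { best <- v; bt <- t }
  }
  bt
}

oracle_triangle <- function(h) {
  p <- h / sum(h)
  n <- length(p)
  nz <- which(p > 0)
  lo <- max(nz[1] - 1L, 1L)
  hi <- min(nz[length(nz)] + 1L, n)
  peak <- which.max(p)
  flip <- (peak - lo) >= (hi - peak)
  if (flip) { p <- rev(p); peak <- n + 1L - peak; hi <- n + 1L - lo }
  # perpendicular distance from (x, p[x]) to the chord (peak,p[peak])-(hi,p[hi])
  x1 <- peak; y1 <- p[peak]; x2 <- hi; y2 <- p[hi]
  best <- -Inf; bx <- peak
  for (x in peak:hi) {
    d <- (y1 - y2) * (x - x1) + (x2 - x1) * (y1 - p[x])
    if (d > best) { best <- d; bx <- x }
  }
  if (flip) bx <- n + 1L - bx
  ts <- oracle_splits(h)
  min(max(bx - 1L, ts[1]), ts[length(ts)])
}

oracle_isodata <- function(h) {
  lev <- seq_along(h) - 1
  rng <- range(which(h > 0)) - 1L
  t <- floor(sum(lev * h) / sum(h))
  t <- min(max(t, rng[1]), rng[2] - 1L)
  repeat {
    s <- oracle_class_stats(h, t)
    tn <- floor((s$m0 + s$m1) / 2)
    tn <- min(max(tn, rng[1]), rng[2] - 1L)
    if (tn == t) break
    t <- tn
  }
  t
}

oracle_li <- function(h) {
  lev <- seq_along(h) - 1
  tot <- sum(h)
  t <- sum(lev * h) / tot
  eps <- .Machine$double.eps
  for (i in 1:1000) {
    lo <- lev <= t
    n0 <- sum(h[lo]); n1 <- tot - n0
    m0 <- max(if (n0 > 0) sum(lev[lo] * h[lo]) / n0 else 0, eps)
    m1 <- max(if (n1 > 0) sum(lev[!lo] * h[!lo]) / n1 else 0, eps)
    if (abs(m0 - m1) < eps) break
    tn <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(tn - t) < 0.5) { t <- tn; break }
    t <- tn
  }
  nz <- which(h > 0) - 1L
  min(max(floor(t), nz[1]), nz[length(nz)] - 1L)
}

oracle_smooth_bimodal <- function(h, max_iter = 10000L) {
  p <- h / sum(h)
  n <- length(p)
  npeaks <- function(p) {
    k <- 0
    for (i in 2:(n - 1)) if (p[i] > p[i - 1] && p[i] >= p[i + 1]) k <- k + 1
    k
  }
  it <- 0
  while (npeaks(p) > 2) {
    q <- p
    for (i in 1:n) {
      a <- if (i == 1) p[1] else p[i - 1]
      b <- if (i == n) p[n] else p[i + 1]
      q[i] <- (a + p[i] + b) / 3
    }
    p <- q
    it <- it + 1
    if (it >= max_iter) return(NULL)
  }
  pk <- integer(0)
  for (i in 2:(n - 1)) if (p[i] > p[i - 1] && p[i] >= p[i + 1]) pk <- c(pk, i - 1L)
  if (length(pk) < 2) return(NULL)
  list(p = p, peaks = pk)
}

oracle_intermodes <- function(h) {
  sm <- oracle_smooth_bimodal(h)
  if (is.null(sm)) return(NULL)
  floor((sm$peaks[1] + sm$peaks[2]) / 2)
}

oracle_minimum <- function(h) {
  sm <- oracle_smooth_bimodal(h)
  if (is.null(sm)) return(NULL)
  best <- Inf; bt <- NA
  for (l in sm$peaks[1]:sm$peaks[2]) {
    if (sm$p[l + 1] < best) { best <- sm$p[l + 1]; bt <- l }
  }
  bt
}

threshold_oracles <- list(
  IsoData = oracle_isodata, Huang = oracle_huang,
  Intermodes = oracle_intermodes, Li = oracle_li,
  MaxEntropy = oracle_maxentropy, Mean = oracle_mean,
  MinError = oracle_minerror, Minimum = oracle_minimum,
  Moments = oracle_moments, Otsu = oracle_otsu,
  Percentile = oracle_percentile, RenyiEntropy = oracle_renyi,
  Shanbhag = oracle_shanbhag, Triangle = oracle_triangle,
  Yen = oracle_yen
)

# ---- other oracles ---------------------------------------------------------

# AUC by exhaustive case-control pair counting (ties count 1/2)
oracle_auc_paircount <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) for (y in ys)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}

# DeLong variance of a single AUC by direct placement enumeration
oracle_delong_var <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  v10 <- sapply(xs, function(x) sum((x > ys) + 0.5 * (x == ys)) / n)
  v01 <- sapply(ys, function(y) sum((xs > y) + 0.5 * (xs == y)) / m)
  var(v10) / m + var(v01) / n
}

# full-likelihood lasso objective
lasso_objective <- function(X, y, b0, beta, lambda, penalized = NULL) {
  if (is.null(penalized)) penalized <- rep(TRUE, length(beta))
  sum((y - b0 - X %*% beta)^2) / 2 + lambda * sum(abs(beta[penalized]))
}

# ISTA (proximal gradient) minimizer of the gaussian lasso objective,
# an algorithm entirely different from coordinate descent
oracle_lasso_ista <- function(X, y, lambda, iters = 200000L) {
  n <- nrow(X); p <- ncol(X)
  Xc <- cbind(1, X)
  L <- max(eigen(crossprod(Xc), only.values = TRUE)$values)
  b <- numeric(p + 1)
  for (i in seq_len(iters)) {
    g <- crossprod(Xc, Xc %*% b - y)
    bn <- b - g / L
    bn[-1] <- sign(bn[-1]) * pmax(abs(bn[-1]) - lambda / L, 0)
    if (max(abs(bn - b)) < 1e-12) { b <- bn; break }
    b <- bn
  }
  list(b0 = b[1], beta = b[-1])
}
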