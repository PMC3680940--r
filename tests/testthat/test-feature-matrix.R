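toy_matrix <- function() {
  m <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  m
}

test_that("filter_missing drops by count and imputes zero", {
  m <- toy_matrix()
  m[, "b"] <- NaN                 # all 5 undefined
  m[1, "a"] <- NaN                # one undefined
  out <- filter_missing(m, max_nan = 2)
  expect_identical(colnames(out), c("a", "c"))
  expect_identical(attr(out, "dropped_columns"), "b")
  expect_equal(unname(out[1, "a"]), 0)

  clean <- toy_matrix()
  expect_equal(filter_missing(clean, 2), clean, ignore_attr = TRUE)
  m2 <- toy_matrix(); m2[] <- NaN
  expect_error(filter_missing(m2, 1), "all columns dropped")
})

test_that("filter_missing fraction variant matches the count form", {
  m <- toy_matrix()
  m[1:2, "c"] <- NaN
  expect_identical(colnames(filter_missing(m, max_nan_frac = 0.4)),
                   colnames(filter_missing(m, max_nan = 2)))
})

test_that("PCA matches the eigendecomposition oracle to 1e-8", {
  set.seed(31)
  x <- matrix(rnorm(500), 50, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  basis <- fit_pca(x, var_frac = 1)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  # eigenvalues: svd d^2/(n-1)... compare variance fractions instead
  expect_equal(basis$var_frac_all, ev$values / sum(ev$values),
               tolerance = 1e-8)
  for (j in 1:10) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(basis$loadings[, j]), v, tolerance = 1e-8,
                 info = paste("component", j))
  }
})

test_that("the retained-component rule brackets the variance fraction", {
  set.seed(32)
  x <- matrix(rnorm(400), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  b <- fit_pca(x, 0.9)
  cv <- cumsum(b$var_frac_all)
  expect_gte(cv[b$k], 0.9)
  if (b$k > 1) expect_lt(cv[b$k - 1], 0.9)

  rank1 <- outer(rnorm(20), c(1, 2, 3))
  colnames(rank1) <- c("a", "b", "c")
  expect_identical(fit_pca(rank1, 0.5)$k, 1L)
  expect_error(fit_pca(matrix(0, 5, 2, dimnames = list(NULL, c("a", "b")))),
               "zero-variance")
})

test_that("projection centers by training means and is orthogonal", {
  set.seed(33)
  x <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("f", 1:10)))
  b <- fit_pca(x, 0.95)
  sc <- project(x, b)
  expect_equal(colMeans(sc), rep(0, ncol(sc)), tolerance = 1e-10,
               ignore_attr = TRUE)
  cv <- stats::cov(sc)
  expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))),
               tolerance = 1e-10)
  means_row <- matrix(b$center, 1, dimnames = list(NULL, b$columns))
  expect_equal(unname(project(means_row, b)[1, ]), rep(0, b$k),
               tolerance = 1e-12)
  expect_error(project(x[, 1:5], b), "lacks basis columns")
})

test_that("the basis depends only on training rows", {
  set.seed(34)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("f", 1:10)))
  b1 <- fit_pca(x, 0.9)
  b2 <- fit_pca(x, 0.9)   # refit: deterministic
  expect_identical(b1$loadings, b2$loadings)
  test_rows <- matrix(rnorm(100), 10, 10,
                      dimnames = list(NULL, paste0("f", 1:10)))
  p1 <- project(test_rows, b1)
  p2 <- project(test_rows[sample(10), ], b1)
  expect_equal(sort(p1[, 1]), sort(p2[, 1]))  # projection row-wise only
})

test_that("reconstruction error decreases monotonically in k", {
  set.seed(35)
  x <- matrix(rnorm(400), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  b <- fit_pca(x, 1)
  xc <- sweep(x, 2, b$center)
  err <- vapply(1:10, function(k) {
    L <- b$loadings[, 1:k, drop = FALSE]
    sum((xc - xc %*% L %*% t(L))^2)
  }, 0)
  expect_true(all(diff(err) <= 1e-8))
})

test_that("a PCA basis survives a JSON round-trip", {
  set.seed(36)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  b <- fit_pca(x, 0.9)
  f <- withr::local_tempfile(fileext = ".json")
  write_pca_json(b, f)
  b2 <- read_pca_json(f)
  expect_equal(project(x, b), project(x, b2), tolerance = 1e-12)
})
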