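test_that("rolling-ball subtraction flattens backgrounds and keeps small objects", {
  const <- gray_image(matrix(120L, 40, 40), 8L)
  out <- rolling_ball_subtract(const, 10)
  expect_true(all(out$pixels == 0L))

  img <- disc_image(64, 32, 32, 5, fg = 200L, bg = 40L)
  sub <- rolling_ball_subtract(img, 25)
  expect_true(all(sub$pixels <= img$pixels))            # bound
  inner <- disc_mask(64, 32, 32, 3)
  expect_gt(mean(sub$pixels[inner]), 120)               # disc preserved
  expect_lt(mean(sub$pixels[!disc_mask(64, 32, 32, 8)]), 20)
})

test_that("denoise removes salt noise and roughly preserves the mean", {
  const <- gray_image(matrix(33L, 20, 20), 8L)
  expect_identical(denoise(const, "median", 3)$pixels, const$pixels)

  salt <- matrix(50L, 20, 20); salt[10, 10] <- 255L
  den <- denoise(gray_image(salt, 8L), "median", 3)
  expect_equal(den$pixels[10, 10], 50L)

  set.seed(4)
  px <- matrix(as.integer(sample(80:180, 900, TRUE)), 30, 30)
  g <- denoise(gray_image(px, 8L), "gaussian", 1.5)
  expect_lt(abs(mean(g$pixels) - mean(px)) / mean(px), 0.01)
})

test_that("watershed splits touching discs but not single convex objects", {
  two <- disc_mask(64, 22, 32, 12) | disc_mask(64, 44, 32, 12)
  lab2 <- watershed_split(two)
  expect_identical(attr(lab2, "n_labels"), 2L)
  expect_true(all((lab2 > 0) == two))      # labels partition the mask

  one <- disc_mask(64, 32, 32, 14)
  expect_identical(attr(watershed_split(one), "n_labels"), 1L)

  none <- matrix(FALSE, 16, 16)
  expect_identical(attr(watershed_split(none), "n_labels"), 0L)
})

test_that("watershed label count is at least the component count", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    lab <- watershed_split(m)
    cc <- label_components(m, 8L)
    expect_gte(attr(lab, "n_labels"), attr(cc, "n_labels"))
    expect_true(all((lab > 0) == m))
  }
})

test_that("find_edges responds to steps and ignores constants and offsets", {
  const <- gray_image(matrix(90L, 20, 20), 8L)
  expect_true(all(find_edges(const)$pixels == 0L))

  px <- matrix(20L, 20, 20); px[, 11:20] <- 220L
  e <- find_edges(gray_image(px, 8L))
  expect_true(all(e$pixels[, 10] > 0))
  expect_true(all(e$pixels[, c(1:8, 13:20)] == 0))

  shifted <- gray_image(px + 30L, 8L)
  expect_identical(find_edges(shifted)$pixels, e$pixels)
})

test_that("thinning yields 1-px centerlines", {
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_identical(thin(line), line)

  bar <- matrix(FALSE, 30, 30); bar[14:16, 6:25] <- TRUE
  sk <- thin(bar)
  expect_true(sum(sk) >= 16 && sum(sk) <= 20)

  expect_identical(thin(matrix(FALSE, 16, 16)), matrix(FALSE, 16, 16))
})

test_that("measure_objects reproduces definitional statistics", {
  px <- matrix(0L, 20, 20)
  px[6:15, 6:15] <- 7L
  img <- gray_image(px, 8L)
  lab <- label_components(px > 0L)
  o <- measure_objects(lab, img)
  expect_equal(o$area, 100)
  expect_equal(o$mean_gray, 7)
  expect_equal(o$integrated_density, 700)
  expect_equal(o$modal_gray, 7)
  expect_equal(o$median_gray, 7)
  expect_equal(o$solidity, 1, tolerance = 0.05)
  expect_equal(o$major / o$minor, 1, tolerance = 1e-6)
})

test_that("integrated density equals area times mean gray", {
  ph <- std_phantom()
  dm <- apply_threshold(ph$image, ph$mask, 1300L)
  o <- measure_objects(label_components(dm$mask), ph$image)
  expect_equal(o$integrated_density, o$area * o$mean_gray, tolerance = 1e-9)
})

test_that("circularity of rasterized discs approaches 1 and is monotone in radius", {
  circ_of <- function(r) {
    n <- 2 * r + 11
    img <- disc_image(n, (n + 1) / 2, (n + 1) / 2, r)
    o <- measure_objects(label_components(img$pixels > 100L), img)
    o$circularity
  }
  expect_lt(abs(circ_of(50) - 1), 0.05)
  expect_gte(measure_objects(
    label_components(disc_mask(120, 60, 60, 50)),
    gray_image(matrix(10L, 120, 120), 8L))$solidity, 0.98)
})

test_that("single-pixel objects get undefined shape statistics", {
  px <- matrix(0L, 16, 16); px[4, 4] <- 9L
  o <- measure_objects(label_components(px > 0L), gray_image(px, 8L))
  expect_true(is.nan(o$circularity))
  expect_true(is.nan(o$solidity))
})

test_that("size-class summaries bin, conserve and mark empty classes", {
  obj <- data.frame(label = 1:3, area = c(50, 500, 5000),
                    perimeter = c(10, 50, 100), circularity = 0.8,
                    solidity = 0.9, mean_gray = c(10, 20, 30),
                    modal_gray = 10, median_gray = 10,
                    integrated_density = c(500, 10000, 150000),
                    skewness = 0, kurtosis = 0, major = 5, minor = 3,
                    angle = 10)
  sm <- summarize_sizeclass(obj, c(1, 101, 1001, Inf), breast_area = 10000)
  expect_equal(sm$count, c(1, 1, 1))
  expect_equal(sum(sm$total_area), sum(obj$area))
  expect_equal(sm$average_size, sm$total_area / sm$count)
  expect_equal(sm$area_fraction, 100 * sm$total_area / 10000)

  sm2 <- summarize_sizeclass(obj[obj$area < 1000, ], c(1, 101, 1001, Inf),
                             10000)
  expect_equal(sm2$count[3], 0)
  expect_true(is.nan(sm2$average_size[3]))
  expect_true(all(is.nan(unlist(sm2[3, c("mean_gray", "circularity",
                                         "skewness")]))))
  expect_error(summarize_sizeclass(obj, c(100, 1, Inf), 10), "increasing")
})

test_that("the feature layout is stable and extraction follows it", {
  lay <- feature_layout()
  expect_length(lay$slots, 1008)
  expect_false(any(duplicated(lay$slots)))
  lay2 <- feature_layout()
  expect_identical(lay$hash, lay2$hash)

  ph <- std_phantom()
  fv <- extract_features(ph$image, ph$mask)
  expect_identical(names(fv), lay$slots)
  fv2 <- extract_features(ph$image, ph$mask)
  expect_identical(fv, fv2)  # bit-exact determinism
})

test_that("whole-breast area fractions are consistent with apply_threshold", {
  ph <- std_phantom()
  fv <- extract_features(ph$image, ph$mask)
  h <- build_histogram(ph$image, ph$mask)
  for (m in c("Otsu", "Moments", "MaxEntropy")) {
    t <- auto_threshold(h, m)
    cut <- level_to_intensity(t, ph$image$bit_depth, h$n_levels)
    dm <- apply_threshold(ph$image, ph$mask, cut)
    # variant A 5+ class excludes sub-5-px specks; allow that deficit only
    af <- fv[paste0(m, "_A_ge5_area_fraction")]
    expect_lte(af, 100 * dm$fraction + 1e-9)
    expect_gt(af, 100 * dm$fraction - 1.5)
  }
})

test_that("a phantom with no dense tissue yields zero counts and NaN slots", {
  ph <- generate_phantom(phantom_spec(seed = 21, target_pd = 0, tag = FALSE,
                                      width = 128L, height = 128L))
  img <- ph$image
  m <- background_mask(img)
  fv <- extract_features(img, m)
  # high-entropy methods may still cut texture noise; Otsu/Moments split the
  # breast's own base level, so check definitional slots instead
  expect_true(all(is.finite(fv[c("wb_mean", "wb_area", "edge_mean")])))
  expect_true(anyNA(fv))
})
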