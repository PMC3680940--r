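test_that("histograms count masked pixels and conserve totals", {
  img <- gray_image(matrix(7L, 16, 16), 8L)
  h <- build_histogram(img)
  expect_equal(h$counts[8], 256)
  expect_equal(sum(h$counts), 256)

  px <- matrix(c(rep(0L, 128), rep(255L, 128)), 16, 16)
  h2 <- build_histogram(gray_image(px, 8L))
  expect_equal(h2$counts[c(1, 256)], c(128, 128))

  px12 <- matrix(as.integer(sample(0:4095, 400, TRUE)), 20, 20)
  h12 <- build_histogram(gray_image(px12, 12L))
  expect_equal(h12$total, 400)
  expect_equal(h12$bin_width, 16L)

  m <- matrix(FALSE, 16, 16); m[1:4, 1:4] <- TRUE
  hm <- build_histogram(img, m)
  expect_equal(hm$total, 16)
  expect_error(build_histogram(img, matrix(FALSE, 16, 16)), "empty mask")
})

test_that("histogram CSV round-trips", {
  h <- md_histogram(random_bimodal_hist(1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  expect_equal(read_histogram_csv(f)$counts, h$counts)
})

test_that("two delta spikes are split between the classes by every method", {
  counts <- numeric(256)
  counts[51] <- 400; counts[201] <- 600   # levels 50 and 200
  h <- md_histogram(counts)
  for (m in threshold_methods()) {
    t <- auto_threshold(h, m)
    expect_gte(t, 50)
    expect_lt(t, 200)
  }
})

test_that("Mean is the floor of the histogram mean level", {
  h <- md_histogram(random_bimodal_hist(2))
  lev <- 0:255
  expect_identical(auto_threshold(h, "Mean"),
                   as.integer(floor(sum(lev * h$counts) / h$total)))
})

test_that("minimum-error threshold sits at the symmetry point of a symmetric histogram", {
  counts <- dnorm(0:255, 80, 12) + dnorm(0:255, 175, 12)
  counts <- round(1e5 * (counts + rev(counts)))  # exactly symmetric about 127.5
  t <- min_error_threshold(md_histogram(counts))
  expect_true(abs(t - 127.5) <= 1.5)
})

test_that("degenerate single-level histograms are rejected", {
  counts <- numeric(256); counts[10] <- 50
  h <- md_histogram(counts)
  expect_error(min_error_threshold(h), "degenerate")
  expect_error(auto_threshold(h, "Otsu"), "degenerate")
})

test_that("every method matches its independent oracle on structured histograms", {
  # smoke subset; the full 200-histogram sweep runs in the acceptance suite
  for (s in 1:8) {
    counts <- random_bimodal_hist(s)
    h <- md_histogram(counts)
    for (m in threshold_methods()) {
      expect_identical(auto_threshold(h, m),
                       as.integer(threshold_oracles[[m]](counts)),
                       info = paste(m, "seed", s))
    }
  }
})

test_that("thresholds are invariant to scaling the counts", {
  counts <- random_bimodal_hist(9)
  h1 <- md_histogram(counts)
  h5 <- md_histogram(counts * 5)
  for (m in threshold_methods())
    expect_identical(auto_threshold(h1, m), auto_threshold(h5, m), info = m)
})

test_that("apply_threshold obeys bounds, truth and monotonicity", {
  ph <- std_phantom()
  img <- ph$image; mask <- ph$mask
  lo <- apply_threshold(img, mask, min(img$pixels[mask$mask]) - 1L)
  hi <- apply_threshold(img, mask, max(img$pixels))
  expect_equal(lo$fraction, 1)
  expect_equal(hi$fraction, 0)
  expect_true(all(!lo$mask | mask$mask))  # dense subset of breast

  # oracle cut: with vignetting off, dense tissue sits at base + boost and
  # the midpoint is the exact class boundary of the generating model
  flat <- generate_phantom(phantom_spec(seed = 7, target_pd = 30,
                                        vignette = 0, tag = FALSE))
  fmask <- breast_mask(flat$truth$breast_mask)
  fr <- apply_threshold(flat$image, fmask, 1450L)$fraction
  expect_lt(abs(fr - 0.30), 0.02)

  fracs <- vapply(seq(0, 4000, by = 250),
                  function(l) apply_threshold(img, mask, l)$fraction, 0)
  expect_true(all(diff(fracs) <= 0))
})
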