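# Shared fixtures, built once per test run.

std_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(phantom_spec(seed = 7, target_pd = 30))
      img <- crop_tag(ph$image)
      mask <- background_mask(img)
      cache <<- list(raw = ph$image, image = img, mask = mask,
                     truth = ph$truth)
    }
    cache
  }
})

# rasterized disc mask/image helpers
disc_mask <- function(n, cx, cy, r) {
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  (row - cy)^2 + (col - cx)^2 <= r^2
}

disc_image <- function(n, cx, cy, r, fg = 200L, bg = 10L, bit_depth = 8L) {
  px <- matrix(bg, n, n)
  px[disc_mask(n, cx, cy, r)] <- fg
  gray_image(px, bit_depth)
}
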