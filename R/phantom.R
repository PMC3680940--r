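#' Phantom mammogram specification
#'
#' Describes a synthetic mediolateral-oblique-like phantom: a bright
#' half-elliptical "breast" on a dark film background, dense tissue as the
#' upper quantile of a smoothed Gaussian random field inside the breast
#' (hit exactly at the requested percent density), an optional bright
#' corner identification tag, multiplicative vignetting toward the breast
#' edge, and additive Gaussian noise. The seed fully determines the image.
#'
#' Defaults state a 256 x 256, 12-bit phantom: film background 150, breast
#' base 1000, dense tissue +900, tag 3500, noise sd 15 — separations in
#' the same spirit as a digitized film mammogram at 12-bit range.
#'
#' @param width,height image size in pixels.
#' @param bit_depth 8, 12 or 16 (default 12, the film-digitization range).
#' @param target_pd target percent density in `[0, 100]`.
#' @param axes_frac half-ellipse semi-axes as fractions of (width, height).
#' @param blob_scale Gaussian smoothing sigma (px) of the dense-tissue
#'   random field; larger values give fewer, larger dense blobs.
#' @param background,breast_level,dense_boost,tag_level intensity levels.
#' @param vignette vignetting strength in `[0, 1)` at the breast edge.
#' @param tag add a corner identification tag?
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 256L, height = 256L, bit_depth = 12L,
                         target_pd = 20, axes_frac = c(0.70, 0.42),
                         blob_scale = 6, background = 150,
                         breast_level = 1000, dense_boost = 900,
                         tag_level = 3500, vignette = 0.25, tag = TRUE,
                         noise_sd = 15, seed = 1L) {
  stopifnot(target_pd >= 0, target_pd <= 100, blob_scale > 0,
            vignette >= 0, vignette < 1, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 bit_depth = as.integer(bit_depth), target_pd = target_pd,
                 axes_frac = axes_frac, blob_scale = blob_scale,
                 background = background, breast_level = breast_level,
                 dense_boost = dense_boost, tag_level = tag_level,
                 vignette = vignette, tag = tag, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a phantom mammogram with known ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image]) and `truth`: `breast_mask`,
#'   `dense_mask`, `tag_mask` (logical matrices, recorded before noise),
#'   `pd` (= 100 * dense / breast pixels, exact), `dense_area`,
#'   `breast_area`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$height; nc <- spec$width
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # half-ellipse anchored on the left edge, vertically centered
  a <- spec$axes_frac[1] * nc   # horizontal semi-axis
  b <- spec$axes_frac[2] * nr   # vertical semi-axis
  er <- ((col - 1) / a)^2 + ((row - nr / 2) / b)^2
  breast <- er <= 1
  breast_area <- sum(breast)
  n_dense <- round(spec$target_pd / 100 * breast_area)
  if (n_dense > breast_area)
    stop("target PD not achievable for this breast area")
  with_seed(spec$seed, {
    field <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$blob_scale)
    dense <- matrix(FALSE, nr, nc)
    if (n_dense > 0) {
      vals <- field[breast]
      ord <- order(vals, decreasing = TRUE)
      sel <- which(breast)[ord[seq_len(n_dense)]]
      dense[sel] <- TRUE
    }
    img <- matrix(spec$background, nr, nc)
    vig <- 1 - spec$vignette * pmin(sqrt(er), 1)
    img[breast] <- (spec$breast_level +
                    spec$dense_boost * dense[breast]) * vig[breast]
    img <- gaussian_blur(img, 0.8)  # soften edges as film/optics would
    tag_mask <- matrix(FALSE, nr, nc)
    if (spec$tag) {
      tr <- 1:max(8, round(nr * 0.08))
      tc <- (nc - max(11, round(nc * 0.125)) + 1):nc
      tag_mask[tr, tc] <- TRUE
      img[tag_mask] <- spec$tag_level
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, sd = spec$noise_sd)
    mx <- 2^spec$bit_depth - 1
    img <- matrix(as.integer(pmin(pmax(round(img), 0), mx)), nr, nc)
    list(image = gray_image(img, spec$bit_depth),
         truth = list(breast_mask = breast, dense_mask = dense,
                      tag_mask = tag_mask,
                      pd = 100 * n_dense / breast_area,
                      dense_area = n_dense, breast_area = breast_area))
  })
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic case-control cohort of phantoms
#'
#' Per-subject target percent density is drawn right-skewed: sqrt(PD) from
#' a truncated normal (defaults mean 3.32 = sqrt(11), sd 1.5, support
#' [0.5, 9], matching a control-group median PD of ~11% and an upper range
#' of ~80%); cases are shifted upward by `pd_shift` on the sqrt(PD) scale.
#' The default shift 0.8 reproduces the case/control median split of
#' ~17% vs ~11%. Each subject gets its own derived seed, so the cohort is
#' reproducible from (`seed`, template) alone.
#'
#' @param n_cases,n_controls subject counts.
#' @param pd_shift case shift on the sqrt(PD) scale (>= 0), default 0.8.
#' @param template a [phantom_spec()] providing everything but
#'   `target_pd`/`seed`.
#' @param seed cohort seed.
#' @param sqrt_pd_mean,sqrt_pd_sd,sqrt_pd_range distribution of
#'   control-group sqrt(PD).
#' @return list: `images` (list of [gray_image]), `truth` (data.frame with
#'   id, status, target_pd, true_pd, dense_area, breast_area, seed),
#'   `labels` (data.frame id, status).
#' @export
generate_cohort <- function(n_cases, n_controls, pd_shift = 0.8,
                            template = phantom_spec(), seed = 1L,
                            sqrt_pd_mean = 3.32, sqrt_pd_sd = 1.5,
                            sqrt_pd_range = c(0.5, 9)) {
  stopifnot(pd_shift >= 0, n_cases >= 1, n_controls >= 1)
  n <- n_cases + n_controls
  status <- c(rep(1L, n_cases), rep(0L, n_controls))
  with_seed(seed, {
    sq <- rtrunc_norm(n, sqrt_pd_mean + pd_shift * status, sqrt_pd_sd,
                      sqrt_pd_range[1], sqrt_pd_range[2])
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    ids <- sprintf("img%04d", seq_len(n))
    images <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- template
      sp$target_pd <- sq[i]^2
      sp$seed <- subject_seeds[i]
      ph <- generate_phantom(sp)
      images[[i]] <- ph$image
      truth[[i]] <- data.frame(id = ids[i], status = status[i],
                               target_pd = sq[i]^2, true_pd = ph$truth$pd,
                               dense_area = ph$truth$dense_area,
                               breast_area = ph$truth$breast_area,
                               seed = subject_seeds[i])
    }
    names(images) <- ids
    list(images = images, truth = do.call(rbind, truth),
         labels = data.frame(id = ids, status = status))
  })
}

#' Write a generated cohort to disk
#'
#' Images as ASCII PGM (or PNG), plus `labels.csv` (id,status),
#' `truth.csv` (id,pd,dense_area,breast_area) and `manifest.json` echoing
#' the template and seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @param format `"pgm"` or `"png"`.
#' @param template,seed echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("pgm", "png"),
                         template = NULL, seed = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$images))
    save_image(cohort$images[[id]],
               file.path(dir, paste0(id, ".", format)))
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth[, c("id", "true_pd", "dense_area",
                                    "breast_area")],
                   file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(template = if (!is.null(template))
                              unclass(template),
                            seed = seed, n = nrow(cohort$labels)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
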