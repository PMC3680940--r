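#' Grayscale image container
#'
#' A `gray_image` wraps a 2-D matrix of non-negative integer intensities
#' together with its bit depth. Digitized film mammograms are typically
#' scanned at 12-bit dynamic range; phantoms may use 8 or 16 bits. The
#' matrix is stored row = image row, origin at the top-left corner.
#'
#' @param pixels integer (or whole-number numeric) matrix of intensities.
#' @param bit_depth one of 8, 12 or 16; all intensities must be at most
#'   `2^bit_depth - 1`.
#' @return an object of class `gray_image` with elements `pixels`
#'   (integer matrix) and `bit_depth`.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16 x 16 pixels")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("pixels contain missing values")
  mx <- bitwShiftL(1L, bit_depth) - 1L
  if (min(pixels) < 0L || max(pixels) > mx)
    stop("intensities out of range for declared bit depth")
  structure(list(pixels = pixels, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%d, %d]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

#' Breast-region binary mask
#'
#' A binary raster aligned to a [gray_image], marking the breast region.
#' `breast_area` (the total breast area, in pixels) is the denominator of
#' percent density: PD = 100 * dense area / breast area.
#'
#' @param mask logical matrix.
#' @return object of class `breast_mask` with elements `mask` and
#'   `breast_area`.
#' @export
breast_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (anyNA(mask)) stop("mask contains missing values")
  structure(list(mask = mask, breast_area = sum(mask)), class = "breast_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask %d x %d, breast_area = %d px (%.1f%%)>\n",
              nrow(x$mask), ncol(x$mask), x$breast_area,
              100 * x$breast_area / length(x$mask)))
  invisible(x)
}

# ---- file formats ----------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments start with '#')
  tok <- character(0)
  buf <- ""
  while (length(tok) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  }
  if (length(vals) != n) stop("truncated PGM data: ", path)
  bd <- if (maxval <= 255L) 8L else if (maxval <= 4095L) 12L else 16L
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE), bit_depth = bd)
}

write_pgm_ascii <- function(img, path) {
  px <- img$pixels
  maxval <- bitwShiftL(1L, img$bit_depth) - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  writeLines(apply(px, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a grayscale image
#'
#' Reads single-channel PNG or PGM (ASCII `P2` or binary `P5`) rasters into a
#' [gray_image]. PGM carries its own maximum value, from which the bit depth
#' (8/12/16) is inferred. PNG files store 8- or 16-bit samples; for 12-bit
#' data stored in a 16-bit PNG pass `bit_depth = 12`.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @param bit_depth optional override of the declared bit depth (PNG only).
#' @param as_gray collapse an RGB(A) PNG to luminance? Default `FALSE`:
#'   a multi-channel image without this flag is an error.
#' @return a [gray_image].
#' @export
load_image <- function(path, bit_depth = NULL, as_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    img <- read_pgm(path)
    if (!is.null(bit_depth)) img <- gray_image(img$pixels, bit_depth)
    return(img)
  }
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    if (length(dim(arr)) == 3L) {
      if (!as_gray)
        stop("multi-channel PNG; pass as_gray = TRUE to convert to luminance")
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    }
    # readPNG scales to [0,1] by 2^depth - 1; recover integer codes
    info <- attr(arr, "info")
    file_bd <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth
               else if (max(arr) <= 1 && any(abs(arr * 255 - round(arr * 255)) > 1e-9)) 16L
               else 8L
    codes <- round(arr * (2^file_bd - 1))
    bd <- if (is.null(bit_depth)) as.integer(file_bd) else as.integer(bit_depth)
    if (bd == 12L && file_bd == 16L) codes <- round(codes / 16)
    return(gray_image(matrix(as.integer(codes), nrow(codes), ncol(codes)),
                      bit_depth = bd))
  }
  stop("unsupported image format: .", ext, " (PNG and PGM are supported)")
}

#' Write a grayscale image or mask
#'
#' `save_image()` writes a [gray_image] as ASCII PGM (any bit depth) or PNG
#' (8/16-bit). `save_mask()` persists a binary mask as an 8-bit 0/255 image.
#'
#' @param img a [gray_image].
#' @param path destination ending in `.pgm` or `.png`.
#' @return the path, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is_gray_image(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm_ascii(img, path))
  if (ext == "png") {
    if (img$bit_depth > 8L)
      stop("PNG output is 8-bit only; write ", img$bit_depth,
           "-bit images as PGM")
    png::writePNG(img$pixels / 255, path)
    return(invisible(path))
  }
  stop("unsupported output format: .", ext)
}

#' @param mask a [breast_mask] or logical matrix.
#' @rdname save_image
#' @export
save_mask <- function(mask, path) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  img <- gray_image(matrix(ifelse(m, 255L, 0L), nrow(m), ncol(m)), 8L)
  save_image(img, path)
}
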