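#' Filter feature columns by missingness
#'
#' Keeps the columns whose count of undefined values (`NA`/`NaN`) is
#' strictly below `max_nan`, then replaces the remaining undefined entries
#' with zero — the convention under which downstream PCA and model fitting
#' operate. The default of 200 follows the working rule used with cohorts
#' of ~3,000 images ("variables with less than 200 NaN values");
#' `max_nan_frac` expresses the same cut as a fraction of rows for cohorts
#' of other sizes.
#'
#' @param matrix numeric feature matrix (rows = images, named columns).
#' @param max_nan count threshold; a column is kept iff `#NaN < max_nan`.
#' @param max_nan_frac optional fraction of rows; overrides `max_nan`.
#' @return the filtered matrix with zeros imputed; attribute
#'   `dropped_columns` lists removed column names.
#' @export
filter_missing <- function(matrix, max_nan = 200L, max_nan_frac = NULL) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (!is.null(max_nan_frac)) max_nan <- max_nan_frac * nrow(matrix)
  stopifnot(max_nan >= 0)
  nnan <- colSums(is.na(matrix))
  keep <- nnan < max_nan
  if (!any(keep)) stop("all columns dropped by the missingness filter")
  out <- matrix[, keep, drop = FALSE]
  out[is.na(out)] <- 0
  attr(out, "dropped_columns") <- colnames(matrix)[!keep]
  out
}

#' Principal-component basis of a training feature matrix
#'
#' Centers the columns by their training means (no scaling by default, the
#' variables enter raw) and computes the principal components, retaining
#' the smallest number of components whose cumulative variance fraction
#' reaches `var_frac` (default 0.90). Loadings carry a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param train numeric matrix, rows = training images.
#' @param var_frac fraction of total variance to capture, in `(0, 1]`.
#' @param scale. standardize columns to unit variance first? Default
#'   `FALSE`.
#' @return object of class `pca_basis`: `columns`, `center` (training
#'   means), `scale`, `loadings` (columns = components, orthonormal),
#'   `var_frac_all` (per-component variance fractions, non-increasing),
#'   `k` (retained components).
#' @export
fit_pca <- function(train, var_frac = 0.90, scale. = FALSE) {
  stopifnot(is.matrix(train), var_frac > 0, var_frac <= 1)
  ctr <- colMeans(train)
  x <- sweep(train, 2L, ctr)
  scl <- rep(1, ncol(train))
  if (scale.) {
    scl <- apply(train, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(x, 2L, scl, "/")
  }
  s <- svd(x)
  ev <- s$d^2
  if (sum(ev) <= 0) stop("zero-variance matrix: PCA undefined")
  vf <- ev / sum(ev)
  k <- which(cumsum(vf) >= var_frac - 1e-12)[1]
  load <- s$v
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(train)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(columns = colnames(train), center = ctr, scale = scl,
                 scaled = scale., loadings = load, var_frac_all = vf,
                 k = as.integer(k)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis: %d columns -> %d PCs (%.1f%% variance)>\n",
              length(x$columns), x$k, 100 * sum(x$var_frac_all[seq_len(x$k)])))
  invisible(x)
}

#' Project a feature matrix onto a fitted PCA basis
#'
#' Centers (and optionally scales) by the *training* statistics stored in
#' the basis and multiplies by the retained loadings. Test rows never refit
#' the basis.
#'
#' @param matrix numeric matrix containing at least the basis columns.
#' @param basis a `pca_basis` from [fit_pca()].
#' @return score matrix (rows preserved, columns `PC1..PCk`).
#' @export
project <- function(matrix, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  missing_cols <- setdiff(basis$columns, colnames(matrix))
  if (length(missing_cols))
    stop("matrix lacks basis columns: ", paste(utils::head(missing_cols, 5),
                                               collapse = ", "))
  x <- matrix[, basis$columns, drop = FALSE]
  x <- sweep(x, 2L, basis$center)
  if (basis$scaled) x <- sweep(x, 2L, basis$scale, "/")
  x %*% basis$loadings[, seq_len(basis$k), drop = FALSE]
}

#' Serialize / restore a PCA basis as JSON
#'
#' @param basis a `pca_basis`.
#' @param path JSON file path.
#' @return `write_pca_json` the path invisibly; `read_pca_json` the basis.
#' @export
write_pca_json <- function(basis, path) {
  jsonlite::write_json(
    list(columns = basis$columns, center = basis$center, scale = basis$scale,
         scaled = basis$scaled, loadings = basis$loadings,
         var_frac_all = basis$var_frac_all, k = basis$k),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- o$loadings
  rownames(load) <- o$columns
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(columns = o$columns, center = o$center, scale = o$scale,
                 scaled = o$scaled, loadings = load,
                 var_frac_all = o$var_frac_all, k = as.integer(o$k)),
            class = "pca_basis")
}
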