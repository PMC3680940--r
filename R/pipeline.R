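#' Extract features for a set of images
#'
#' Runs tag removal, breast-region extraction and the full fixed-layout
#' feature battery per image. Inputs may be file paths (PNG/PGM) or
#' in-memory [gray_image] objects (e.g. from [generate_cohort()]). With
#' `keep_going = TRUE` a failing image is skipped with a warning rather
#' than aborting the run.
#'
#' @param images named list of [gray_image]s, or character vector of paths
#'   (ids = file names without extension).
#' @param layout an `md_layout` (see [feature_layout()]).
#' @param auto_crop run automatic tag removal first?
#' @param keep_going skip unreadable/failing images with a warning?
#' @param ... passed to [extract_features()].
#' @return numeric feature matrix, rows = image ids, columns = layout
#'   slots; failed images are absent.
#' @export
md_extract <- function(images, layout = feature_layout(), auto_crop = TRUE,
                       keep_going = TRUE, ...) {
  if (is.character(images)) {
    ids <- sub("\\.[^.]+$", "", basename(images))
    paths <- images
    get_img <- function(i) load_image(paths[i])
  } else {
    ids <- names(images) %||% sprintf("img%04d", seq_along(images))
    get_img <- function(i) images[[i]]
  }
  rows <- list()
  for (i in seq_along(ids)) {
    fv <- tryCatch({
      img <- get_img(i)
      if (auto_crop) img <- crop_tag(img)
      mask <- background_mask(img)
      extract_features(img, mask, layout, ...)
    }, error = function(e) {
      if (!keep_going) stop(e)
      warning("image '", ids[i], "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(fv)) rows[[ids[i]]] <- fv
  }
  if (!length(rows)) stop("no image produced features")
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  out
}

#' Random train/test partition of image ids
#'
#' Seeded random split (default ~50/50), stratified by status when labels
#' are supplied, mirroring the usual model-building / model-assessment
#' partition of a case-control cohort.
#'
#' @param ids character vector of image ids.
#' @param ratio training fraction.
#' @param seed RNG seed.
#' @param status optional 0/1 labels (same order as `ids`) for
#'   stratification.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
md_partition <- function(ids, ratio = 0.5, seed = 1L, status = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  with_seed(seed, {
    if (is.null(status)) {
      tr <- sample(ids, round(ratio * length(ids)))
    } else {
      stopifnot(length(status) == length(ids))
      tr <- unlist(lapply(unique(status), function(s) {
        grp <- ids[status == s]
        sample(grp, round(ratio * length(grp)))
      }))
    }
    list(train = sort(tr), test = sort(setdiff(ids, tr)))
  })
}

#' Train the full model bundle
#'
#' The end-to-end training path: missingness filter, PCA to the requested
#' variance fraction, cross-validated lambda, then the percent-density
#' mimic model (gaussian lasso on sqrt(PD)) and the three case-control
#' risk scores (penalized logistic; score 2 with PD forced in unpenalized,
#' score 3 with PD penalized).
#'
#' @param features feature matrix of the training images (rows = ids).
#' @param reference_pd named (by id) or aligned reference percent density.
#' @param status named or aligned 0/1 labels; `NULL` skips the scores.
#' @param cfg a [cv_config()].
#' @param var_frac PCA variance fraction (default 0.90).
#' @param max_nan,max_nan_frac missingness filter (see [filter_missing()]).
#' @return object of class `md_bundle`: `basis`, `pd_model`, `scores`
#'   (list of three `score_model`s or `NULL`), `dropped_columns`, `cfg`.
#' @export
md_train <- function(features, reference_pd, status = NULL,
                     cfg = cv_config(), var_frac = 0.90, max_nan = 200L,
                     max_nan_frac = NULL) {
  ids <- rownames(features)
  reference_pd <- align_by_id(reference_pd, ids, "reference_pd")
  if (!is.null(status)) status <- align_by_id(status, ids, "status")
  filt <- filter_missing(features, max_nan, max_nan_frac)
  basis <- fit_pca(filt, var_frac)
  pcs <- project(filt, basis)
  pd_model <- train_pd_model(pcs, reference_pd, cfg)
  scores <- NULL
  if (!is.null(status)) {
    scores <- lapply(1:3, function(s)
      train_score_model(pcs, status, s, pd = reference_pd, cfg = cfg))
    names(scores) <- paste0("score", 1:3)
  }
  structure(list(basis = basis, pd_model = pd_model, scores = scores,
                 dropped_columns = attr(filt, "dropped_columns"),
                 cfg = cfg),
            class = "md_bundle")
}

align_by_id <- function(x, ids, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(ids, names(x))
    if (length(miss))
      stop(what, " missing for ids: ", paste(utils::head(miss, 5),
                                             collapse = ", "))
    return(unname(x[ids]))
  }
  if (length(x) != length(ids))
    stop(what, " must be named by id or aligned to the feature rows")
  x
}

#' Apply a trained bundle to a feature table
#'
#' @param bundle an `md_bundle` from [md_train()].
#' @param features feature matrix (same layout as in training).
#' @return data.frame: id, mimic_pd, and score1..score3 when available.
#' @export
md_apply <- function(bundle, features) {
  stopifnot(inherits(bundle, "md_bundle"))
  x <- features
  x[is.na(x)] <- 0  # the training-time NaN -> 0 convention
  pcs <- project(x, bundle$basis)
  out <- data.frame(id = rownames(features),
                    mimic_pd = predict_pd(bundle$pd_model, pcs))
  if (!is.null(bundle$scores))
    for (nm in names(bundle$scores))
      out[[nm]] <- compute_score(bundle$scores[[nm]], pcs)
  out
}

#' Evaluate a trained bundle on a held-out table
#'
#' Applies the bundle and computes the full [evaluation_report()]. Overlap
#' between training and evaluation ids (when the bundle records them) is
#' reported as a warning, not an error.
#'
#' @param bundle an `md_bundle`.
#' @param features held-out feature matrix.
#' @param reference_pd named or aligned reference PD.
#' @param status named or aligned 0/1 labels (optional).
#' @param train_ids optional training ids for an overlap check.
#' @return an `evaluation_report`; the applied predictions are attached as
#'   attribute `predictions`.
#' @export
md_evaluate <- function(bundle, features, reference_pd, status = NULL,
                        train_ids = NULL) {
  ids <- rownames(features)
  if (!is.null(train_ids) && length(intersect(ids, train_ids)))
    warning("evaluation ids overlap the training set")
  reference_pd <- align_by_id(reference_pd, ids, "reference_pd")
  if (!is.null(status)) status <- align_by_id(status, ids, "status")
  preds <- md_apply(bundle, features)
  scores <- if (!is.null(bundle$scores))
    preds[, intersect(names(preds), paste0("score", 1:3)), drop = FALSE]
  rep <- evaluation_report(reference_pd, preds$mimic_pd,
                           scores = if (!is.null(status)) scores,
                           status = status)
  attr(rep, "predictions") <- preds
  rep
}

#' Serialize / restore a model bundle as JSON
#'
#' @param bundle an `md_bundle`.
#' @param path JSON destination.
#' @return the path invisibly; `read_bundle_json` the bundle.
#' @export
write_bundle_json <- function(bundle, path) {
  o <- list(
    basis = list(columns = bundle$basis$columns,
                 center = bundle$basis$center, scale = bundle$basis$scale,
                 scaled = bundle$basis$scaled,
                 loadings = bundle$basis$loadings,
                 var_frac_all = bundle$basis$var_frac_all,
                 k = bundle$basis$k),
    pd_model = local({ m <- unclass(bundle$pd_model)
                       m$cv <- unclass(m$cv); m$coef <- as.list(m$coef); m }),
    scores = lapply(bundle$scores, function(s) {
      s <- unclass(s); s$cv <- unclass(s$cv); s$coef <- as.list(s$coef); s }),
    dropped_columns = bundle$dropped_columns,
    cfg = unclass(bundle$cfg))
  jsonlite::write_json(o, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_bundle_json
#' @export
read_bundle_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- o$basis
  load <- basis$loadings
  rownames(load) <- basis$columns
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  basis <- structure(list(columns = basis$columns, center = basis$center,
                          scale = basis$scale, scaled = basis$scaled,
                          loadings = load, var_frac_all = basis$var_frac_all,
                          k = as.integer(basis$k)),
                     class = "pca_basis")
  fix_named <- function(m, cls) {
    m$coef <- unlist(m$coef) %||% stats::setNames(numeric(0), character(0))
    if (!is.null(m$cv)) {
      m$cv$lambda_min <- if (length(m$cv$lambda_min)) m$cv$lambda_min
      m$cv$lambda_max <- if (length(m$cv$lambda_max)) m$cv$lambda_max
      class(m$cv) <- "cv_config"
    }
    structure(m, class = cls)
  }
  pd_model <- fix_named(o$pd_model, "pd_model")
  scores <- if (!is.null(o$scores) && length(o$scores))
    lapply(o$scores, fix_named, cls = "score_model")
  structure(list(basis = basis, pd_model = pd_model, scores = scores,
                 dropped_columns = o$dropped_columns,
                 cfg = structure(o$cfg, class = "cv_config")),
            class = "md_bundle")
}
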