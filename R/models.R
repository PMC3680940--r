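#' Cross-validation configuration
#'
#' Settings for repeated k-fold likelihood cross-validation of the lasso
#' shrinkage parameter. The reference workflow is tenfold cross-validation
#' repeated 100 times, with the per-repeat optimal lambdas averaged
#' (arithmetically) into a single mean lambda.
#'
#' @param folds number of folds (>= 2), default 10.
#' @param repeats number of repeats (>= 1), default 100.
#' @param seed RNG seed controlling fold assignment.
#' @param lambda_min,lambda_max optional search bounds; when `NULL` the
#'   upper bound is the smallest lambda with all penalized coefficients
#'   zero and the lower bound is `1e-3` times that.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, repeats = 100L, seed = 1L,
                      lambda_min = NULL, lambda_max = NULL) {
  stopifnot(folds >= 2L, repeats >= 1L)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), lambda_min = lambda_min,
                 lambda_max = lambda_max),
            class = "cv_config")
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# weighted lasso by cyclic coordinate descent on
#   0.5 * sum w (z - b0 - X beta)^2 + lambda * sum_{j penalized} |beta_j|
# returns list(b0, beta)
cd_lasso_wls <- function(X, z, w, lambda, penalized, tol = 1e-7,
                         max_sweeps = 2000L, beta = NULL, b0 = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(beta)) beta <- numeric(p)
  if (is.null(b0)) b0 <- sum(w * z) / sum(w)
  wx2 <- colSums(w * X^2)
  r <- z - b0 - drop(X %*% beta)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    b0_new <- b0 + sum(w * r) / sum(w)
    r <- r - (b0_new - b0)
    delta <- max(delta, abs(b0_new - b0))
    b0 <- b0_new
    for (j in seq_len(p)) {
      if (wx2[j] <= 0) next
      rho <- sum(w * X[, j] * r) + wx2[j] * beta[j]
      bj <- if (penalized[j]) soft_threshold(rho, lambda) / wx2[j]
            else rho / wx2[j]
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(b0 = b0, beta = beta)
}

#' Lasso-penalized model fit
#'
#' Fits an l1-penalized linear (`gaussian`) or logistic (`binomial`) model
#' by cyclic coordinate descent (IRLS outer loop for the binomial family).
#' The objective is on the full-likelihood scale,
#' `-logLik + lambda * sum(|beta_j|)` over the penalized coefficients
#' (residual sum of squares / 2 for the gaussian family); the intercept
#' and any covariates named in `unpenalized` are excluded from the penalty.
#'
#' @param X numeric covariate matrix with column names.
#' @param y response (numeric, or 0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda non-negative shrinkage parameter.
#' @param unpenalized character vector of column names left unpenalized.
#' @param tol convergence tolerance on coefficient updates (default 1e-7).
#' @param standardize scale columns to unit variance before fitting (the
#'   fitted coefficients are returned on the original scale)? Without it a
#'   single lambda is meaningless when covariate scales differ by orders of
#'   magnitude, as covariance-PCA scores of raw image features do.
#' @return object of class `md_lasso`: `intercept`, `coef` (named),
#'   `lambda`, `family`, `unpenalized`, `loglik`, `deviance`.
#' @export
fit_lasso <- function(X, y, family = c("gaussian", "binomial"), lambda,
                      unpenalized = NULL, tol = 1e-7, standardize = FALSE) {
  family <- match.arg(family)
  stopifnot(is.matrix(X), lambda >= 0, nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  scl <- rep(1, ncol(X))
  if (standardize) {
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(X, 2L, scl, "/")
  }
  penalized <- !(colnames(X) %in% unpenalized)
  n <- nrow(X)
  if (family == "gaussian") {
    fit <- cd_lasso_wls(X, y, rep(1, n), lambda, penalized, tol = tol)
    eta <- fit$b0 + drop(X %*% fit$beta)
    rss <- sum((y - eta)^2)
    ll <- -rss / 2
    dev <- rss
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    b0 <- log(mean(y) / (1 - mean(y)))
    beta <- numeric(ncol(X))
    dev_old <- Inf
    for (it in seq_len(100L)) {
      eta <- b0 + drop(X %*% beta)
      pr <- 1 / (1 + exp(-eta))
      w <- pmax(pr * (1 - pr), 1e-6)
      z <- eta + (y - pr) / w
      fit <- cd_lasso_wls(X, z, w, lambda, penalized, tol = tol,
                          beta = beta, b0 = b0)
      b0 <- fit$b0; beta <- fit$beta
      if (any(abs(beta) > 1e6)) {
        j <- which.max(abs(beta))
        stop("divergence (possible separation) on covariate ", colnames(X)[j])
      }
      eta <- b0 + drop(X %*% beta)
      pr <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
      dev <- -2 * sum(y * log(pr) + (1 - y) * log(1 - pr))
      if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
      dev_old <- dev
    }
    fit <- list(b0 = b0, beta = beta)
    ll <- -dev / 2
  }
  structure(list(intercept = fit$b0,
                 coef = stats::setNames(fit$beta / scl, colnames(X)),
                 lambda = lambda, family = family,
                 unpenalized = unpenalized %||% character(0),
                 loglik = ll, deviance = dev),
            class = "md_lasso")
}

#' @export
print.md_lasso <- function(x, ...) {
  cat(sprintf("<md_lasso %s: lambda = %.4g, %d/%d nonzero coefficients>\n",
              x$family, x$lambda, sum(x$coef != 0), length(x$coef)))
  invisible(x)
}

# out-of-fold predictive log-likelihood at a given lambda
cv_loglik <- function(X, y, family, lambda, unpenalized, fold_id, tol) {
  ll <- 0
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- fit_lasso(X[tr, , drop = FALSE], y[tr], family, lambda,
                     unpenalized, tol = tol)
    eta <- fit$intercept + drop(X[!tr, , drop = FALSE] %*% fit$coef)
    if (family == "gaussian") {
      ll <- ll - sum((y[!tr] - eta)^2) / 2
    } else {
      pr <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
      ll <- ll + sum(y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr))
    }
  }
  ll
}

#' Select the lasso shrinkage parameter by repeated cross-validation
#'
#' For each repeat, folds are assigned by a seeded shuffle (stratified by
#' case status for the binomial family); the lambda maximizing the
#' out-of-fold log-likelihood is located by golden-section search on the
#' log-lambda scale within the configured bounds. The returned lambda is
#' the arithmetic mean of the per-repeat optima. Deterministic for a given
#' seed.
#'
#' @inheritParams fit_lasso
#' @param cfg a [cv_config()].
#' @return the mean optimal lambda; attribute `per_repeat` holds the
#'   per-repeat optima.
#' @export
cv_lambda <- function(X, y, family = c("gaussian", "binomial"),
                      unpenalized = NULL, cfg = cv_config(), tol = 1e-6,
                      standardize = FALSE) {
  family <- match.arg(family)
  n <- nrow(X)
  stopifnot(n >= cfg$folds)
  if (standardize) {
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(X, 2L, scl, "/")  # lambda then refers to unit-scale covariates
  }
  # lambda upper bound from the KKT condition at the all-zero penalized
  # model: residuals are taken from the fit of the unpenalized covariates
  # alone (the intercept-only fit when there are none)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  pen <- !(colnames(X) %in% unpenalized)
  if (any(!pen)) {
    Xu <- X[, !pen, drop = FALSE]
    fit0 <- if (family == "binomial")
      stats::glm.fit(cbind(1, Xu), y, family = stats::binomial())
    else stats::lm.fit(cbind(1, Xu), y)
    resid0 <- y - if (family == "binomial") fit0$fitted.values
                  else fit0$fitted.values
  } else {
    resid0 <- y - mean(y)
  }
  lmax <- cfg$lambda_max %||% max(abs(crossprod(X[, pen, drop = FALSE],
                                                resid0)))
  lmin <- cfg$lambda_min %||% (1e-3 * lmax)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  gr <- (sqrt(5) - 1) / 2
  optima <- numeric(cfg$repeats)
  for (rep_i in seq_len(cfg$repeats)) {
    if (family == "binomial") {
      fold_id <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold_id[idx] <- sample(rep_len(seq_len(cfg$folds), length(idx)))
      }
    } else {
      fold_id <- sample(rep_len(seq_len(cfg$folds), n))
    }
    f <- function(loglambda)
      cv_loglik(X, y, family, exp(loglambda), unpenalized, fold_id, tol)
    a <- log(lmin); b <- log(lmax)
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    while (b - a > 0.05) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- f(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- f(x1)
      }
    }
    optima[rep_i] <- exp((a + b) / 2)
  }
  structure(mean(optima), per_repeat = optima)
}

# ---- the percent-density mimic and the risk scores -------------------------

#' Train the percent-density mimic model
#'
#' Regresses the square-root of the reference percent density (the
#' transformation that makes PD approximately normal) on the principal
#' components with a lasso penalty, at the lambda chosen by repeated
#' cross-validation.
#'
#' @param pcs PC-score matrix of the training images.
#' @param pd reference percent density (0-100) per training image.
#' @param cfg a [cv_config()].
#' @param lambda optional fixed lambda (skips cross-validation).
#' @param standardize scale covariates to unit variance inside the
#'   penalized fit (default `TRUE`; covariance-PCA scores span orders of
#'   magnitude, under which an unstandardized l1 penalty is degenerate).
#' @return object of class `pd_model` (also `md_lasso`-like): `intercept`,
#'   `coef`, `lambda`, `cv` (config echo).
#' @export
train_pd_model <- function(pcs, pd, cfg = cv_config(), lambda = NULL,
                           standardize = TRUE) {
  stopifnot(all(pd >= 0 & pd <= 100))
  y <- sqrt(pd)
  if (is.null(lambda))
    lambda <- as.numeric(cv_lambda(pcs, y, "gaussian", cfg = cfg,
                                   standardize = standardize))
  fit <- fit_lasso(pcs, y, "gaussian", lambda, standardize = standardize)
  structure(list(intercept = fit$intercept, coef = fit$coef,
                 lambda = lambda, family = "gaussian",
                 transform = "sqrt", cv = cfg),
            class = c("pd_model"))
}

#' Predict percent density from the mimic model
#'
#' The linear predictor (intercept plus coefficient-PC products) lives on
#' the square-root-PD scale; it is floored at 0, squared, and capped at
#' 100 to give a percent density.
#'
#' @param model a `pd_model`.
#' @param pcs PC-score matrix with the model's columns.
#' @return numeric vector of percent densities in `[0, 100]`.
#' @export
predict_pd <- function(model, pcs) {
  stopifnot(inherits(model, "pd_model"))
  miss <- setdiff(names(model$coef), colnames(pcs))
  if (length(miss)) stop("missing PC columns: ", paste(miss, collapse = ", "))
  eta <- model$intercept +
    drop(pcs[, names(model$coef), drop = FALSE] %*% model$coef)
  pmin(pmax(eta, 0)^2, 100)
}

#' Train a case-control risk score
#'
#' Penalized logistic regression of case status on the principal
#' components, in three flavours: score 1 uses the PCs alone; score 2 adds
#' the reference PD as an *unpenalized* covariate (forcing the PCs to pick
#' up only information orthogonal to PD); score 3 adds PD inside the
#' penalty. In every flavour the resulting score of an image is the sum of
#' the nonzero PC coefficients times the PC values — the PD coefficient is
#' never part of the score.
#'
#' @param pcs PC-score matrix of the training images.
#' @param status 0/1 case-control labels.
#' @param score 1, 2 or 3.
#' @param pd reference percent density (required for scores 2 and 3).
#' @param cfg a [cv_config()].
#' @param lambda optional fixed lambda (skips cross-validation).
#' @param standardize see [train_pd_model()]; default `TRUE`.
#' @return object of class `score_model`: `score`, `coef` (PC coefficients
#'   only), `pd_coef`, `intercept`, `lambda`.
#' @export
train_score_model <- function(pcs, status, score, pd = NULL,
                              cfg = cv_config(), lambda = NULL,
                              standardize = TRUE) {
  stopifnot(score %in% 1:3, all(status %in% c(0, 1)))
  if (score %in% 2:3 && is.null(pd)) stop("scores 2 and 3 require pd")
  X <- if (score == 1) pcs else cbind(PD = sqrt(pd), pcs)
  unpen <- if (score == 2) "PD" else NULL
  if (is.null(lambda))
    lambda <- as.numeric(cv_lambda(X, status, "binomial", unpenalized = unpen,
                                   cfg = cfg, standardize = standardize))
  fit <- fit_lasso(X, status, "binomial", lambda, unpenalized = unpen,
                   standardize = standardize)
  pc_coef <- fit$coef[setdiff(names(fit$coef), "PD")]
  structure(list(score = as.integer(score),
                 coef = pc_coef[pc_coef != 0],
                 pd_coef = if (score == 1) NA_real_ else unname(fit$coef["PD"]),
                 intercept = fit$intercept, lambda = lambda,
                 family = "binomial", cv = cfg),
            class = "score_model")
}

#' Compute a risk score for images
#'
#' Sum of the model's nonzero PC coefficients times the image's PC values;
#' any PD term of the underlying fit is excluded by construction.
#'
#' @param model a `score_model`.
#' @param pcs PC-score matrix.
#' @return numeric score per row.
#' @export
compute_score <- function(model, pcs) {
  stopifnot(inherits(model, "score_model"))
  if (length(model$coef) == 0) return(rep(0, nrow(pcs)))
  miss <- setdiff(names(model$coef), colnames(pcs))
  if (length(miss)) stop("missing PC columns: ", paste(miss, collapse = ", "))
  drop(pcs[, names(model$coef), drop = FALSE] %*% model$coef)
}

#' Serialize / restore fitted models as JSON
#'
#' @param model a `pd_model` or `score_model`.
#' @param path JSON destination.
#' @return the path invisibly; `read_model_json` the model object.
#' @export
write_model_json <- function(model, path) {
  o <- unclass(model)
  o$.class <- class(model)[1]
  o$cv <- unclass(o$cv)
  o$coef <- as.list(o$coef)  # named object, not a bare array
  jsonlite::write_json(o, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- o$.class
  o$.class <- NULL
  o$coef <- unlist(o$coef) %||% stats::setNames(numeric(0), character(0))
  if (!is.null(o$cv)) {
    o$cv$lambda_min <- if (length(o$cv$lambda_min)) o$cv$lambda_min
    o$cv$lambda_max <- if (length(o$cv$lambda_max)) o$cv$lambda_max
    class(o$cv) <- "cv_config"
  }
  structure(o, class = cls)
}
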