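#' Pearson correlation with Fisher confidence interval
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @param level confidence level (default 0.95).
#' @return list `r`, `ci` (length-2), `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y` against means `m = (x + y)/2`: mean difference,
#' limits of agreement `mean(d) +/- 1.96 sd(d)`, and the least-squares
#' slope/intercept and correlation of `d` on `m` (a proportional-bias
#' check).
#'
#' @param x,y paired measurements (n >= 3).
#' @return list `mean_diff`, `lower`, `upper`, `sd_diff`, `slope`,
#'   `intercept`, `r`, `n`.
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  d <- x - y
  m <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  if (stats::var(m) > 0) {
    slope <- sum((m - mean(m)) * (d - md)) / sum((m - mean(m))^2)
    intercept <- md - slope * mean(m)
    r <- if (sdd > 0) pearson_ci(d, m)$r else 0
  } else {
    slope <- 0; intercept <- md; r <- 0
  }
  if (sdd == 0) { slope <- 0; intercept <- md; r <- 0 }
  list(mean_diff = md, lower = md - 1.96 * sdd, upper = md + 1.96 * sdd,
       sd_diff = sdd, slope = slope, intercept = intercept, r = r, n = n)
}

#' Odds-ratio profile over categories of a measure
#'
#' Cuts the measure into categories (`[breaks[i], breaks[i+1])`, lowest
#' category = reference) and fits an unconditional logistic regression of
#' case status on the category indicators; ORs are `exp(coef)` with Wald
#' confidence intervals. With a single 2x2 split this equals the
#' cross-product odds ratio. The default breaks implement a low (<5%)
#' reference with the upper categories merged above 25%.
#'
#' @param values the measure (e.g. percent density).
#' @param status 0/1 case-control labels.
#' @param breaks category edges (default `c(0, 5, 10, 25, 100.01)`).
#' @param level confidence level.
#' @return data.frame: category, n_case, n_control, or, lower, upper.
#' @export
category_or <- function(values, status, breaks = c(0, 5, 10, 25, 100.01),
                        level = 0.95) {
  stopifnot(all(status %in% c(0, 1)))
  cat_f <- cut(values, breaks, right = FALSE, include.lowest = TRUE)
  if (any(is.na(cat_f))) stop("values outside category breaks")
  tab <- table(cat_f, status)
  if (tab[1, "0"] == 0 || tab[1, "1"] == 0)
    stop("reference category empty in one group")
  fit <- stats::glm(status ~ cat_f, family = stats::binomial())
  co <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(category = levels(cat_f),
             n_case = as.integer(tab[, "1"]),
             n_control = as.integer(tab[, "0"]),
             or = c(1, exp(co)),
             lower = c(NA, exp(co - q * se)),
             upper = c(NA, exp(co + q * se)),
             row.names = NULL)
}

# placement values (structural components) of the DeLong construction
delong_placements <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  vx <- vapply(xs, function(x) mean(psi(x, ys)), 0)  # V10
  vy <- vapply(ys, function(y) mean(psi(xs, y)), 0)  # V01
  list(auc = mean(vx), vx = vx, vy = vy, m = m, n = n)
}

#' ROC area under the curve with DeLong variance
#'
#' AUC as the normalized Mann-Whitney statistic (ties counted 1/2,
#' equivalent to the trapezoidal ROC area), with standard error and
#' confidence interval from the DeLong structural-components covariance.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 case-control labels (both classes present).
#' @param level confidence level.
#' @return list `auc`, `se`, `ci`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pl <- delong_placements(scores, labels)
  s2 <- stats::var(pl$vx) / pl$m + stats::var(pl$vy) / pl$n
  se <- sqrt(s2)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = pl$auc, se = se,
       ci = pmin(pmax(c(pl$auc - q * se, pl$auc + q * se), 0), 1),
       n_case = pl$m, n_control = pl$n)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided test of equal AUC for two scores measured on the same
#' subjects, using the DeLong covariance of the paired placement values.
#'
#' @param scores_a,scores_b paired scores on identical subjects.
#' @param labels 0/1 labels.
#' @return list `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  sx <- stats::cov(cbind(pa$vx, pb$vx))
  sy <- stats::cov(cbind(pa$vy, pb$vy))
  var_delta <- (sx[1, 1] + sx[2, 2] - 2 * sx[1, 2]) / pa$m +
               (sy[1, 1] + sy[2, 2] - 2 * sy[1, 2]) / pa$n
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    if (abs(delta) < 1e-12) return(list(auc_a = pa$auc, auc_b = pb$auc,
                                        delta = 0, se = 0, z = 0, p = 1))
    stop("degenerate variance in DeLong comparison")
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = sqrt(var_delta),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Goodness-of-fit table for a set of logistic risk models
#'
#' Fits each requested covariate combination by (unpenalized) logistic
#' regression and reports, per model: residual deviance, `P1` = likelihood
#' ratio test against the intercept-only null, `P2` = likelihood ratio
#' test against the nested reference model named in `nested` (e.g. the
#' PD-only model for a PD + score model), and `AIC = deviance + 2 *
#' n_parameters`. The null row reports the null deviance.
#'
#' @param models named list; each element a character vector of covariate
#'   column names in `data`.
#' @param status 0/1 outcome.
#' @param data data.frame of covariates.
#' @param nested optional named character vector mapping a model name to
#'   the model it should be LRT-compared against for `P2`.
#' @return data.frame: model, deviance, df, p1, p2, aic.
#' @export
deviance_table <- function(models, status, data, nested = NULL) {
  stopifnot(all(status %in% c(0, 1)))
  null_fit <- stats::glm(status ~ 1, family = stats::binomial())
  fits <- lapply(models, function(v) {
    stopifnot(all(v %in% names(data)))
    stats::glm(stats::reformulate(v, response = "status"),
               family = stats::binomial(),
               data = cbind(data, status = status))
  })
  rows <- list(data.frame(model = "Null",
                          deviance = stats::deviance(null_fit),
                          df = 1L, p1 = NA_real_, p2 = NA_real_,
                          aic = stats::deviance(null_fit) + 2))
  for (nm in names(models)) {
    f <- fits[[nm]]
    dev <- stats::deviance(f)
    k <- length(stats::coef(f))
    p1 <- stats::pchisq(stats::deviance(null_fit) - dev, df = k - 1,
                        lower.tail = FALSE)
    p2 <- NA_real_
    if (!is.null(nested) && nm %in% names(nested)) {
      ref <- nested[[nm]]
      if (!ref %in% names(models)) stop("nested reference not in models: ", ref)
      if (!all(models[[ref]] %in% models[[nm]]))
        stop("non-nested comparison requested: ", nm, " vs ", ref)
      fr <- fits[[ref]]
      p2 <- stats::pchisq(stats::deviance(fr) - dev,
                          df = k - length(stats::coef(fr)),
                          lower.tail = FALSE)
    }
    rows[[nm]] <- data.frame(model = nm, deviance = dev, df = k,
                             p1 = p1, p2 = p2, aic = dev + 2 * k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort descriptive summary with two-group tests
#'
#' Mean (SD) with Student t and Wilcoxon rank-sum p-values for numeric
#' characteristics; frequency (percent, one decimal) with chi-square
#' p-values for categorical ones; split by a 0/1 group label.
#'
#' @param data data.frame of subject characteristics.
#' @param group 0/1 vector (e.g. case status), same length as `nrow(data)`.
#' @return data.frame with one row per variable (level): variable, level,
#'   type, group1/group0 display values, p_t, p_wilcoxon, p_chisq.
#' @export
summarize_cohort <- function(data, group) {
  stopifnot(nrow(data) == length(group), all(group %in% c(0, 1)))
  if (!any(group == 0) || !any(group == 1)) stop("empty group")
  rows <- list()
  for (nm in names(data)) {
    v <- data[[nm]]
    if (is.numeric(v)) {
      g1 <- v[group == 1]; g0 <- v[group == 0]
      tt <- tryCatch(stats::t.test(g1, g0)$p.value, error = function(e) NA_real_)
      ww <- tryCatch(stats::wilcox.test(g1, g0, exact = FALSE)$p.value,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = NA_character_, type = "numeric",
        group1 = sprintf("%.1f (%.1f)", mean(g1), stats::sd(g1)),
        group0 = sprintf("%.1f (%.1f)", mean(g0), stats::sd(g0)),
        p_t = tt, p_wilcoxon = ww, p_chisq = NA_real_)
    } else {
      f <- factor(v)
      tab <- table(f, group)
      pc <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                     error = function(e) NA_real_)
      for (lv in levels(f)) {
        n1 <- sum(f == lv & group == 1); n0 <- sum(f == lv & group == 0)
        rows[[length(rows) + 1]] <- data.frame(
          variable = nm, level = lv, type = "categorical",
          group1 = sprintf("%d (%.1f)", n1, 100 * n1 / sum(group == 1)),
          group0 = sprintf("%d (%.1f)", n0, 100 * n0 / sum(group == 0)),
          p_t = NA_real_, p_wilcoxon = NA_real_, p_chisq = pc)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full evaluation report of a trained model bundle
#'
#' Computes the complete statistical battery on a held-out table:
#' Pearson r with CI between reference and mimic PD, Bland-Altman
#' agreement, categorical odds-ratio profiles for both measures, AUCs with
#' DeLong comparison, and the deviance/LRT/AIC table over the standard
#' eight model combinations (null; reference PD; mimic PD; score 1;
#' reference/mimic PD + scores 2 and 3).
#'
#' @param reference_pd reference percent density per image.
#' @param mimic_pd predicted percent density per image.
#' @param scores data.frame or named list with elements `score1`, `score2`,
#'   `score3` (may be `NULL` to skip the risk battery).
#' @param status 0/1 case-control labels (may be `NULL` to skip).
#' @param or_breaks category edges for the odds-ratio profile.
#' @return a list of class `evaluation_report`.
#' @export
evaluation_report <- function(reference_pd, mimic_pd, scores = NULL,
                              status = NULL,
                              or_breaks = c(0, 5, 10, 25, 100.01)) {
  rep <- list(
    pearson = pearson_ci(reference_pd, mimic_pd),
    bland_altman = bland_altman(reference_pd, mimic_pd)
  )
  if (!is.null(status)) {
    rep$or_reference <- tryCatch(
      category_or(reference_pd, status, or_breaks), error = function(e) NULL)
    rep$or_mimic <- tryCatch(
      category_or(mimic_pd, status, or_breaks), error = function(e) NULL)
    rep$auc_reference <- roc_auc(reference_pd, status)
    rep$auc_mimic <- roc_auc(mimic_pd, status)
    rep$delong <- delong_compare(reference_pd, mimic_pd, status)
    if (!is.null(scores)) {
      dat <- data.frame(ref_pd = sqrt(reference_pd),
                        mimic_pd = sqrt(mimic_pd),
                        score1 = scores$score1, score2 = scores$score2,
                        score3 = scores$score3)
      models <- list(
        "Reference PD" = "ref_pd",
        "Mimic PD" = "mimic_pd",
        "Score 1" = "score1",
        "Reference PD + score 2" = c("ref_pd", "score2"),
        "Reference PD + score 3" = c("ref_pd", "score3"),
        "Mimic PD + score 2" = c("mimic_pd", "score2"),
        "Mimic PD + score 3" = c("mimic_pd", "score3"))
      nested <- c("Reference PD + score 2" = "Reference PD",
                  "Reference PD + score 3" = "Reference PD",
                  "Mimic PD + score 2" = "Mimic PD",
                  "Mimic PD + score 3" = "Mimic PD")
      rep$deviance_table <- deviance_table(models, status, dat, nested)
    }
  }
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (95%% CI %.3f to %.3f, n = %d)\n",
              x$pearson$r, x$pearson$ci[1], x$pearson$ci[2], x$pearson$n))
  cat(sprintf("Bland-Altman: mean diff %.3f, limits [%.3f, %.3f]\n",
              x$bland_altman$mean_diff, x$bland_altman$lower,
              x$bland_altman$upper))
  if (!is.null(x$auc_reference))
    cat(sprintf("AUC reference %.3f, mimic %.3f (DeLong p = %.3f)\n",
                x$auc_reference$auc, x$auc_mimic$auc, x$delong$p))
  if (!is.null(x$deviance_table)) {
    cat("Deviance table:\n")
    print(x$deviance_table)
  }
  invisible(x)
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report an `evaluation_report`.
#' @param json_path,tsv_path destinations (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, digits = NA,
                         auto_unbox = TRUE, dataframe = "rows", na = "null")
  if (!is.null(tsv_path) && !is.null(report$deviance_table))
    utils::write.table(report$deviance_table, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(report)
}
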