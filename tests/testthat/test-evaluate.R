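test_that("pearson_ci handles exact and toy cases", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  expect_equal(pearson_ci(x, x)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)

  set.seed(51)
  y <- x + rnorm(10)
  got <- pearson_ci(x, y)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    ((10 - 1) * stats::sd(x) * stats::sd(y))
  expect_equal(got$r, direct, tolerance = 1e-12)
  z <- atanh(direct)
  expect_equal(got$ci,
               tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(7)),
               tolerance = 1e-12)
  expect_error(pearson_ci(rep(1, 5), y[1:5]), "constant")
})

test_that("bland_altman reports exact limits of agreement", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))
  expect_equal(ba0$slope, 0)

  ba1 <- bland_altman(x, x + 1)
  expect_equal(ba1$mean_diff, -1)
  expect_equal(ba1$sd_diff, 0)

  set.seed(52)
  a <- rnorm(30, 20, 5); b <- a + rnorm(30)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$lower, mean(d) - 1.96 * stats::sd(d), tolerance = 1e-12)
  expect_equal(ba$upper, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  lmfit <- stats::lm(d ~ I((a + b) / 2))
  expect_equal(ba$slope, unname(stats::coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(ba$intercept, unname(stats::coef(lmfit)[1]), tolerance = 1e-10)
})

test_that("2x2 odds ratios equal the cross-product (family-history check)", {
  # 207 of 1498 cases vs 119 of 1495 controls with a family history
  status <- c(rep(1, 1498), rep(0, 1495))
  fh <- c(rep(1, 207), rep(0, 1291), rep(1, 119), rep(0, 1376))
  or <- category_or(fh, status, breaks = c(0, 1, 2))
  cross <- (207 * 1376) / (119 * 1291)
  expect_equal(or$or[2], cross, tolerance = 1e-6)
  expect_equal(round(cross, 2), 1.85)
})

test_that("identical case/control distributions give unit odds ratios", {
  v <- rep(c(2, 7, 15, 40), times = c(20, 15, 10, 5))
  status <- rep(c(1, 0), each = 50)
  or <- category_or(c(v, v), status)
  expect_equal(or$or, rep(1, nrow(or)), tolerance = 1e-8)
})

test_that("ROC AUC equals exhaustive pair counting (n <= 12, with ties)", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(1:6, n, TRUE)  # heavy ties
    got <- roc_auc(scores, labels)
    expect_equal(got$auc, oracle_auc_paircount(scores, labels),
                 info = paste("case", i))
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
})

test_that("AUC of an uninformative score is near one half", {
  set.seed(54)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.04)
})

test_that("DeLong variance and comparison match direct enumeration", {
  set.seed(55)
  labels <- c(rep(1, 8), rep(0, 9))
  a <- rnorm(17); b <- a + rnorm(17, sd = 0.7)
  got <- roc_auc(a, labels)
  expect_equal(got$se^2, oracle_delong_var(a, labels), tolerance = 1e-12)

  same <- delong_compare(a, a, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  ab <- delong_compare(a, b, labels)
  ba <- delong_compare(b, a, labels)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
})

test_that("deviance table reproduces nested-model likelihood ratio tests", {
  set.seed(56)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); zero <- rep(0, n)
  status <- rbinom(n, 1, plogis(0.4 * x1))
  dat <- data.frame(x1 = x1, x2 = x2, zero = zero)
  tab <- deviance_table(list(A = "x1", AB = c("x1", "x2"),
                             AZ = c("x1", "zero")),
                        status, dat, nested = c(AB = "A", AZ = "A"))
  expect_equal(tab$deviance[tab$model == "AZ"],
               tab$deviance[tab$model == "A"], tolerance = 1e-8)
  expect_equal(tab$p2[tab$model == "AZ"], 1, tolerance = 1e-6)

  fitA <- stats::glm(status ~ x1, family = binomial())
  fitAB <- stats::glm(status ~ x1 + x2, family = binomial())
  expect_equal(tab$p2[tab$model == "AB"],
               stats::pchisq(deviance(fitA) - deviance(fitAB), 1,
                             lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(tab$p1[tab$model == "A"],
               stats::pchisq(tab$deviance[1] - deviance(fitA), 1,
                             lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(tab$aic, tab$deviance + 2 * tab$df)
  # deviance non-increasing under nesting
  expect_lte(tab$deviance[tab$model == "AB"],
             tab$deviance[tab$model == "A"] + 1e-10)
  expect_error(deviance_table(list(A = "x1", B = "x2"), status, dat,
                              nested = c(B = "A")), "non-nested")
})

test_that("cohort summaries print percentages and test statistics", {
  grp <- c(rep(1, 1498), rep(0, 1495))
  fh <- factor(c(rep("yes", 207), rep("no", 1291),
                 rep("yes", 119), rep("no", 1376)), levels = c("no", "yes"))
  sm <- summarize_cohort(data.frame(family_history = fh), grp)
  expect_equal(sm$group1[sm$level == "yes"], "207 (13.8)")
  expect_equal(sm$group0[sm$level == "yes"], "119 (8.0)")
  expect_lt(sm$p_chisq[1], 0.001)

  toy <- data.frame(age = c(61, 63, 60, 65, 62, 64))
  g <- c(1, 1, 1, 0, 0, 0)
  sm2 <- summarize_cohort(toy, g)
  g1 <- toy$age[g == 1]; g0 <- toy$age[g == 0]
  tstat <- (mean(g1) - mean(g0)) /
    sqrt(var(g1) / 3 + var(g0) / 3)
  expect_equal(sm2$p_t, stats::t.test(g1, g0)$p.value)
  expect_equal(stats::t.test(g1, g0)$statistic[[1]], tstat, tolerance = 1e-12)

  same <- data.frame(v = rep(c(1, 2, 3), 4))
  expect_equal(summarize_cohort(same, rep(c(1, 0), 6))$p_t, 1,
               tolerance = 0.05)
})
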