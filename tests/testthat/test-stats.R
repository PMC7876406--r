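test_that("the mixed ANOVA matches a hand sums-of-squares oracle on a toy table", {
  tab <- expand.grid(subject = sprintf("S%d", 1:8), visit = 1:2,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$subject %in% sprintf("S%d", 1:4), "healthy", "patient")
  set.seed(3)
  tab$score <- stats::rnorm(16) + ifelse(tab$group == "patient", 1.2, 0)
  fit <- mixed_anova(tab)
  expect_equal(fit$F, split_plot_F_oracle(tab), tolerance = 1e-10)
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, 6)
  expect_equal(fit$p, stats::pf(fit$F, 1, 6, lower.tail = FALSE))
})

test_that("degenerate mixed-ANOVA inputs behave sensibly", {
  tab <- expand.grid(subject = sprintf("S%d", 1:8), visit = 1:2,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$subject %in% sprintf("S%d", 1:4), "healthy", "patient")
  tab$score <- 5
  fit <- mixed_anova(tab)
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  # complete separation with (near-)zero within-group variance
  tab$score <- ifelse(tab$group == "patient", 10, 0) +
    as.numeric(factor(tab$subject)) * 1e-7
  fit2 <- mixed_anova(tab)
  expect_lt(fit2$p, 1e-6)
  # a group with a single subject is an error
  bad <- tab[tab$subject != "S5", ]
  bad <- bad[bad$subject != "S6", ]
  bad <- bad[bad$subject != "S7", ]
  expect_error(mixed_anova(bad), "2 complete subjects")
})

test_that("the mixed-ANOVA effect size is Cohen's d on subject means", {
  tab <- expand.grid(subject = sprintf("S%d", 1:10), visit = 1:2,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$subject %in% sprintf("S%d", 1:5), "healthy", "patient")
  set.seed(4)
  tab$score <- stats::rnorm(20)
  fit <- mixed_anova(tab)
  sm <- tapply(tab$score, tab$subject, mean)
  gg <- tapply(tab$group, tab$subject, `[`, 1)
  g1 <- sm[gg == "healthy"]; g2 <- sm[gg == "patient"]
  sp <- sqrt((4 * var(g1) + 4 * var(g2)) / 8)
  expect_equal(fit$effect_size, (mean(g2) - mean(g1)) / sp)
})

test_that("Levene's test matches a one-way ANOVA on absolute deviations", {
  set.seed(5)
  v <- c(stats::rnorm(12, 0, 1), stats::rnorm(12, 0, 3))
  g <- rep(c("a", "b"), each = 12)
  lt <- levene_test(v, g)
  dev <- abs(v - ave(v, g))
  oracle <- summary(stats::aov(dev ~ factor(g)))[[1]]
  expect_equal(lt$statistic, oracle[1, "F value"], tolerance = 1e-10)
  expect_equal(lt$p, oracle[1, "Pr(>F)"], tolerance = 1e-10)
  # identical deviation patterns: statistic 0
  v0 <- c(1, 2, 3, 1, 2, 3)
  lt0 <- levene_test(v0, rep(c("a", "b"), each = 3))
  expect_equal(lt0$statistic, 0)
})

test_that("a tenfold variance ratio is detected at moderate sample size", {
  set.seed(6)
  v <- c(stats::rnorm(30, 0, 1), stats::rnorm(30, 0, 10))
  lt <- levene_test(v, rep(c("a", "b"), each = 30))
  expect_lt(lt$p, 0.01)
})

test_that("Welch's t from summaries matches the closed form and full-data test", {
  w <- welch_t_from_summary(0, 1, 100, 1, 1, 100)
  expect_equal(w$t, -7.0711, tolerance = 1e-4)
  expect_equal(w$df, 198, tolerance = 0.01)
  expect_equal(welch_t_from_summary(5, 2, 30, 5, 3, 20)$t, 0)
  # property: agrees with t.test on the same data
  set.seed(7)
  x <- stats::rnorm(40, 0, 1); y <- stats::rnorm(25, 0.7, 2)
  w2 <- welch_t_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 25)
  tt <- stats::t.test(x, y)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w2$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w2$p, tt$p.value, tolerance = 1e-10)
})

test_that("ROC analysis equals exhaustive pair counting, with ties and orientation", {
  pair_count_auc <- function(scores, labels) {
    p <- scores[labels == "patient"]; h <- scores[labels == "healthy"]
    tot <- 0
    for (a in p) for (b in h) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(p) * length(h))
  }
  r <- roc_analysis(c(2, 4, 1, 3), c("patient", "patient", "healthy", "healthy"))
  expect_equal(r$auc, 0.75)
  set.seed(8)
  for (i in 1:30) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    scores <- c(round(stats::rnorm(n1, 0.5), 1), round(stats::rnorm(n2), 1))
    labels <- rep(c("patient", "healthy"), c(n1, n2))
    raw <- pair_count_auc(scores, labels)
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, max(raw, 1 - raw), tolerance = 1e-12)
    expect_gte(r$auc, 0.5)
  }
})

test_that("perfect separation yields AUC, sensitivity and specificity of one", {
  r <- roc_analysis(c(10, 11, 12, 1, 2, 3),
                    rep(c("patient", "healthy"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_analysis(1:5, rep("healthy", 5)), "both classes")
})

test_that("ROC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- stats::rnorm(60)
  labels <- rep(c("patient", "healthy"), 30)
  r <- roc_analysis(scores, labels)
  pr <- pROC::roc(labels, scores, levels = c("healthy", "patient"),
                  direction = if (r$orientation > 0) "<" else ">",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("ICC matches the variance-component oracle and its boundary cases", {
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- x1
  expect_equal(icc_two_visit(x1, x2)$icc, 1)
  # hand-computed mean squares on a 5-subject toy table
  v1 <- c(9, 6, 8, 7, 10)
  v2 <- c(8, 5, 9, 6, 9)
  x <- cbind(v1, v2); n <- 5; k <- 2
  rm_ <- rowMeans(x); cm <- colMeans(x); g <- mean(x)
  MSR <- k * sum((rm_ - g)^2) / (n - 1)
  MSC <- n * sum((cm - g)^2) / (k - 1)
  MSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g)^2) /
    ((n - 1) * (k - 1))
  icc_hand <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  expect_equal(icc_two_visit(v1, v2)$icc, icc_hand, tolerance = 1e-12)
  expect_error(icc_two_visit(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("independent visits give near-zero ICC and structured visits recover it", {
  set.seed(10)
  iccs <- replicate(40, icc_two_visit(stats::rnorm(20), stats::rnorm(20))$icc)
  expect_lt(abs(mean(iccs)), 0.12)
  # subjects with between-SD 1 and visit noise SD 1: true ICC = 0.5
  mean_icc <- mean(replicate(25, {
    s <- stats::rnorm(39)
    icc_two_visit(s + stats::rnorm(39), s + stats::rnorm(39))$icc
  }))
  expect_lt(abs(mean_icc - 0.5), 0.1)
})

test_that("age summaries reproduce hand-computed values", {
  a <- describe_ages(c(14, 18), c(0, 0))
  expect_equal(a$mean_years, 16.0)
  expect_equal(a$sd_years, 2.83)
  expect_equal(describe_ages(c(15, 15, 15), c(6, 6, 6))$sd_years, 0)
  raw <- describe_ages(c(14, 18), c(6, 3), digits = NULL)
  expect_equal(raw$mean_years, (14.5 + 18.25) / 2)
})
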