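#' Mixed group x visit ANOVA (split-plot)
#'
#' Repeated-measures ANOVA with group (healthy, patient) as a
#' between-subjects factor and visit as a within-subjects factor; the
#' between-group F is tested against the subject-within-group stratum.
#' Subjects missing any visit are dropped listwise. The effect size is
#' Cohen's d on subject-mean scores with the pooled SD.
#'
#' @param scores data.frame with columns `subject`, `visit`, `group`,
#'   `score`.
#' @return A `group_comparison` list: `F`, `df1`, `df2`, `p`,
#'   `effect_size`, `n_per_group`, plus `visit_F`, `visit_p` and
#'   `interaction_F`, `interaction_p` from the within stratum.
#' @export
mixed_anova <- function(scores) {
  stopifnot(all(c("subject", "visit", "group", "score") %in% names(scores)))
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  n_visits <- length(unique(scores$visit))
  complete <- names(which(table(scores$subject) == n_visits))
  scores <- scores[scores$subject %in% complete, , drop = FALSE]
  grp_of <- tapply(scores$group, scores$subject, function(g) g[1])
  if (any(table(grp_of) < 2) || length(unique(scores$group)) < 2)
    stop("need at least 2 complete subjects per group", call. = FALSE)
  df <- data.frame(
    subject = factor(scores$subject), visit = factor(scores$visit),
    group = factor(scores$group), score = scores$score
  )
  fit <- stats::aov(score ~ group * visit + Error(subject), data = df)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[[length(sm)]][[1]]
  g_row <- grep("^group", trimws(rownames(between)))[1]
  r_row <- grep("Residuals", rownames(between))
  F_g <- between[g_row, "F value"]
  df1 <- between[g_row, "Df"]
  df2 <- between[r_row, "Df"]
  if (is.na(F_g)) { # zero residual variance: guard
    F_g <- Inf
  }
  p_g <- stats::pf(F_g, df1, df2, lower.tail = FALSE)
  if (between[g_row, "Sum Sq"] < 1e-24) { F_g <- 0; p_g <- 1 }
  subj_means <- tapply(df$score, df$subject, mean)
  subj_group <- tapply(as.character(df$group), df$subject, function(g) g[1])
  gs <- split(subj_means, subj_group)
  n1 <- length(gs[[1]]); n2 <- length(gs[[2]])
  sp <- sqrt(((n1 - 1) * stats::var(gs[[1]]) + (n2 - 1) * stats::var(gs[[2]])) /
               (n1 + n2 - 2))
  d <- if (sp > 0) (mean(gs[[2]]) - mean(gs[[1]])) / sp else 0
  v_row <- grep("^visit", trimws(rownames(within)))[1]
  i_row <- grep(":", rownames(within))[1]
  structure(
    list(F = unname(F_g), df1 = df1, df2 = df2, p = unname(p_g),
         effect_size = unname(d),
         n_per_group = vapply(gs, length, 0L),
         visit_F = within[v_row, "F value"],
         visit_p = within[v_row, "Pr(>F)"],
         interaction_F = within[i_row, "F value"],
         interaction_p = within[i_row, "Pr(>F)"]),
    class = "group_comparison"
  )
}

#' Levene's test for equality of group variances
#'
#' One-way ANOVA on absolute deviations from the group means
#' (mean-centered Levene).
#'
#' @param values Numeric vector.
#' @param group Group labels.
#' @return List: `statistic`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(values, group) {
  group <- factor(group)
  stopifnot(all(table(group) >= 2))
  lt <- car::leveneTest(values, group, center = mean)
  list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df1 = lt[1, "Df"], df2 = lt[2, "Df"])
}

#' Welch's t statistic from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List: `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' ROC analysis for patient-vs-control discrimination
#'
#' AUC by the rank (Mann-Whitney) formulation with mid-rank tie
#' correction, patients as positives. Orientation is flipped when needed so
#' AUC >= 0.5 (`orientation = -1` means lower scores indicate patients).
#' The reported operating point maximizes Youden's J over all thresholds.
#'
#' @param scores Numeric vector.
#' @param labels Labels; values equal to `positive` are the patients.
#' @param positive Positive-class label (default "patient").
#' @return A `roc_result` list: `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `orientation`.
#' @export
roc_analysis <- function(scores, labels, positive = "patient") {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                       # mid-ranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  orientation <- 1
  s <- scores
  if (auc < 0.5) {
    auc <- 1 - auc
    orientation <- -1
    s <- -scores
  }
  thr <- sort(unique(s))
  cuts <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  best <- c(j = -Inf, sens = NA, spec = NA, thr = NA)
  for (ct in cuts) {
    sens <- mean(s[pos] > ct)
    spec <- mean(s[!pos] <= ct)
    j <- sens + spec - 1
    if (j > best["j"]) best <- c(j = j, sens = sens, spec = spec, thr = ct)
  }
  structure(
    list(auc = auc, sensitivity = unname(best["sens"]),
         specificity = unname(best["spec"]),
         threshold = unname(best["thr"]) * orientation,
         orientation = orientation),
    class = "roc_result"
  )
}

#' Two-visit intraclass correlation (absolute agreement)
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1)): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from
#' the two-way mean squares.
#'
#' @param visit1,visit2 Paired numeric vectors (>= 3 subjects).
#' @return An `icc_result` list: `icc`, `model`.
#' @export
icc_two_visit <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2), length(visit1) >= 3)
  x <- cbind(visit1, visit2)
  n <- nrow(x); k <- 2
  if (stats::var(as.numeric(x)) < 1e-24)
    stop("zero total variance: ICC undefined", call. = FALSE)
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  structure(list(icc = icc, model = "two-way mixed, absolute agreement, single measurement"),
            class = "icc_result")
}

#' Mean and SD of ages given as years + months
#'
#' Decimal years = years + months / 12; sample SD (n-1 denominator).
#'
#' @param years Integer vector of whole years.
#' @param months Integer vector of additional months (0-11).
#' @param digits Rounding applied to the returned values (default: mean to
#'   1 decimal, SD to 2, the conventional reporting precision); `NULL`
#'   disables rounding.
#' @return List: `mean_years`, `sd_years`, `n`.
#' @export
describe_ages <- function(years, months = 0, digits = c(1, 2)) {
  stopifnot(length(years) >= 2)
  age <- years + months / 12
  m <- mean(age)
  s <- stats::sd(age)
  if (!is.null(digits)) {
    m <- round(m, digits[1])
    s <- round(s, digits[2])
  }
  list(mean_years = m, sd_years = s, n = length(age))
}

#' Benjamini-Hochberg adjustment helper (off by default in reporting)
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
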