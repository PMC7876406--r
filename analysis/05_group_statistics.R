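#!/usr/bin/env Rscript
# Step 5: group-comparison statistics over the score tables from steps 3-4:
# mixed group x visit ANOVA with Levene/Welch follow-up, ROC
# (AUC/sensitivity/specificity), test-retest ICC and effect sizes, one row
# per score -- plus the multi-parameter radar plot per task.

suppressPackageStartupMessages(library(stepnet))

scores <- load_scores("results")
bna <- scores$bna_scores
erpv <- scores$erpv_scores

score_tables <- list()
if (!is.null(bna)) {
  for (ms in unique(bna$main_step)) for (at in c("amplitude", "latency")) {
    sub <- bna[bna$main_step == ms & bna$attribute == at & bna$matched, ]
    if (!nrow(sub)) next
    score_tables[[sprintf("%s %s", ms, at)]] <- data.frame(
      subject = sub$subject, visit = sub$visit, group = sub$group,
      score = sub$percentile)
  }
}
for (cond in unique(erpv$condition)) {
  sub <- erpv[erpv$condition == cond, ]
  score_tables[[sprintf("ERPv %s", cond)]] <- data.frame(
    subject = sub$subject, visit = sub$visit, group = sub$group,
    score = sub$normalized_erpv)
}

rows <- NULL
for (nm in names(score_tables)) {
  tab <- score_tables[[nm]]
  fit <- tryCatch(mixed_anova(tab), error = function(e) NULL)
  if (is.null(fit)) next
  lev <- levene_test(tab$score, tab$group)
  welch <- if (lev$p < 0.05) {
    g <- split(tab$score, tab$group)
    welch_t_from_summary(mean(g[[1]]), sd(g[[1]]), length(g[[1]]),
                         mean(g[[2]]), sd(g[[2]]), length(g[[2]]))$t
  } else NA_real_
  roc <- roc_analysis(tab$score, tab$group)
  wide <- reshape(tab, idvar = c("subject", "group"), timevar = "visit",
                  direction = "wide")
  icc <- tryCatch(icc_two_visit(wide$score.1, wide$score.2)$icc,
                  error = function(e) NA_real_)
  rows <- rbind(rows, data.frame(
    score = nm, F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
    levene_p = lev$p, welch_t = welch, auc = roc$auc,
    specificity = roc$specificity, sensitivity = roc$sensitivity,
    icc = icc, effect_size = fit$effect_size
  ))
}
rows[, -1] <- round(rows[, -1], 4)
utils::write.table(rows, "results/group_statistics.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(rows)

# multi-parameter score radar plot (percentile scores only)
if (!is.null(bna) && sum(bna$matched) > 0) {
  mp <- aggregate(percentile ~ group + main_step + attribute,
                  bna[bna$matched, ], mean)
  se <- aggregate(percentile ~ group + main_step + attribute,
                  bna[bna$matched, ], function(x) sd(x) / sqrt(length(x)))
  mp$score <- paste(mp$main_step, substr(mp$attribute, 1, 3))
  mp$mean <- mp$percentile
  mp$se <- se$percentile
  if (length(unique(mp$score)) >= 3) {
    dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
    grDevices::pdf("results/figures/multi_parameter_scores.pdf", 6, 6)
    plot_mps(mp[, c("score", "group", "mean", "se")])
    grDevices::dev.off()
    message("radar plot: results/figures/multi_parameter_scores.pdf")
  }
}
message("group statistics written to results/group_statistics.tsv")
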