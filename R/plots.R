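#' Multi-parameter score radar plot
#'
#' Displays group mean percentile scores (with standard-error whiskers) on
#' a radar layout, one spoke per score, patients against controls --
#' the at-a-glance profile plot of the score battery.
#'
#' @param score_table data.frame with columns `score` (spoke label),
#'   `group`, `mean`, `se`.
#' @param main Plot title.
#' @param colors Named colors for the two groups.
#' @return Invisibly, the spoke angles.
#' @export
plot_mps <- function(score_table,
                     main = "Multi-parameter score profile",
                     colors = c(healthy = "grey40", patient = "darkorange")) {
  labs <- unique(score_table$score)
  k <- length(labs)
  stopifnot(k >= 3)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k   # clockwise from top
  graphics::plot(0, 0, type = "n", xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  for (r in c(25, 50, 75, 100) / 100) {
    graphics::polygon(r * cos(seq(0, 2 * pi, length.out = 120)),
                      r * sin(seq(0, 2 * pi, length.out = 120)),
                      border = "grey85")
  }
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey85")
  graphics::text(1.25 * cos(ang), 1.25 * sin(ang), labs, cex = 0.7)
  for (g in unique(score_table$group)) {
    sub <- score_table[score_table$group == g, ]
    sub <- sub[match(labs, sub$score), ]
    r <- sub$mean / 100
    graphics::polygon(r * cos(ang), r * sin(ang), border = colors[[g]],
                      lwd = 2)
    if (!is.null(sub$se)) {
      r_lo <- pmax(0, (sub$mean - sub$se) / 100)
      r_hi <- pmin(1, (sub$mean + sub$se) / 100)
      graphics::polygon(r_lo * cos(ang), r_lo * sin(ang),
                        border = colors[[g]], lty = 2)
      graphics::polygon(r_hi * cos(ang), r_hi * sin(ang),
                        border = colors[[g]], lty = 2)
    }
  }
  graphics::legend("bottomright", legend = unique(score_table$group),
                   col = colors[unique(score_table$group)], lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(ang)
}
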