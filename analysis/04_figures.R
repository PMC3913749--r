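#!/usr/bin/env Rscript

# Step 4: figures. Scatter plots of precision and mixture parameters
# against age with regression lines (per load), and bar contrasts of the
# exposure groups. Base graphics, one multi-panel PDF.
#
# Reads results/estimates.csv; writes results/figures.pdf.

suppressPackageStartupMessages(library(vwmix))

est <- utils::read.csv("results/estimates.csv")
report <- analyze_cohort(est)
sl <- report$subject_level

pdf("results/figures.pdf", width = 10, height = 7)
op <- par(mfrow = c(2, 3), mar = c(4, 4, 2.5, 1))

panel <- function(y, label, ylab) {
  plot(sl$age, y, pch = 19, col = "grey40", xlab = "age (years)",
       ylab = ylab, main = label)
  abline(lm(y ~ sl$age), lwd = 2, col = "firebrick")
}
panel(sl$precision_low, "precision, 1 item", "precision (1/rad, chance-corrected)")
panel(sl$precision_high, "precision, 3 items", "precision (1/rad, chance-corrected)")
panel(sl$sigma_high, "circular SD, 3 items", expression(sigma ~ "(rad)"))
panel(sl$beta_high, "misreport rate, 3 items", expression(beta))
panel(sl$gamma_high, "uniform rate, 3 items", expression(gamma))

# exposure contrast bars: subject-mean precision by group x load
agg <- aggregate(precision ~ exposure + load, est, mean)
bp <- matrix(agg$precision[order(agg$load, agg$exposure)], nrow = 2,
             dimnames = list(c("200 ms", "2 s"), c("1 item", "3 items")))
barplot(bp, beside = TRUE, legend.text = TRUE, ylab = "mean precision (1/rad)",
        main = "exposure duration", args.legend = list(x = "topright"))
par(op)
dev.off()
cat("wrote results/figures.pdf\n")
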