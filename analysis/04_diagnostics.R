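#!/usr/bin/env Rscript
# Goodness of fit for the final model: CWRES table and the
# prediction-corrected visual predictive check (500 replicates at desk
# scale; the full-analysis convention is 1,000). Writes both tables and a
# four-panel GOF figure plus the pc-VPC figure.

suppressPackageStartupMessages(library(polyBpopPK))

cohort <- read_pk_dataset("results/cohort.csv")
fit <- pop_fit(cohort, settings = list(compute_se = FALSE))

res <- pop_cwres(cohort, fit)
write.csv(res, "results/cwres.csv", row.names = FALSE)
cat(sprintf("CWRES over %d observations: mean %.3f, SD %.3f\n",
            nrow(res), mean(res$CWRES), sd(res$CWRES)))

model_hat <- population_model(theta = fit$theta, omega2 = fit$omega2,
                              sigma = fit$sigma)
vpc <- pop_vpc(cohort, model_hat, n_replicates = 500, seed = 271828)
write.csv(as.data.frame(vpc), "results/vpc_summary.csv", row.names = FALSE)
med <- vpc[vpc$percentile == 50, ]
cat(sprintf("pc-VPC: observed median inside its 90%% band in %d/%d bins\n",
            sum(med$observed >= med$sim_lo & med$observed <= med$sim_hi),
            nrow(med)))

png("results/gof.png", width = 1200, height = 1200, res = 150)
op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
plot(res$TIME, res$CWRES, xlab = "Time (h)", ylab = "CWRES",
     main = "CWRES vs time"); abline(h = c(-2, 0, 2), lty = c(3, 1, 3))
plot(res$PRED, res$CWRES, xlab = "PRED (mg/L)", ylab = "CWRES",
     main = "CWRES vs PRED"); abline(h = c(-2, 0, 2), lty = c(3, 1, 3))
plot(res$IPRED, res$DV, xlab = "IPRED (mg/L)", ylab = "Observed (mg/L)",
     main = "DV vs IPRED"); abline(0, 1)
plot(res$PRED, res$DV, xlab = "PRED (mg/L)", ylab = "Observed (mg/L)",
     main = "DV vs PRED"); abline(0, 1)
par(op); dev.off()

png("results/vpc.png", width = 1000, height = 700, res = 150)
plot(NA, xlim = range(vpc$bin_time), ylim = range(c(vpc$sim_lo, vpc$sim_hi,
                                                    vpc$observed)),
     xlab = "Time (h)", ylab = "Prediction-corrected concentration (mg/L)",
     main = "pc-VPC")
for (p in unique(vpc$percentile)) {
  b <- vpc[vpc$percentile == p, ]
  polygon(c(b$bin_time, rev(b$bin_time)), c(b$sim_lo, rev(b$sim_hi)),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(b$bin_time, b$observed, col = "red", lwd = 2,
        lty = if (p == 50) 1 else 2)
}
dev.off()

cat("Wrote results/cwres.csv, results/vpc_summary.csv,",
    "results/gof.png, results/vpc.png\n")
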