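#!/usr/bin/env Rscript
# Summarize the ABC posterior: triangle plot, credible intervals, pairwise
# correlations on the best-fitting subset, and the recovery check against the
# known ground truth of the synthetic dataset.
#
# Outputs (results/):
#   triangle_plot.png
#   credible_intervals.csv
#   correlations_best20.csv
#   recovery_check.csv

library(epiboly)
dir.create("results", showWarnings = FALSE)

tb <- read.csv("results/abc_reference_table.csv")
meta <- jsonlite::read_json("results/abc_fit_meta.json", simplifyVector = TRUE)
post <- as_abc_posterior(tb, meta$threshold)
truth <- read_dataset("results/synthetic_dataset")$truth$theta_star

png("results/triangle_plot.png", width = 1400, height = 1400, res = 160)
triangle_plot(post, bins = 20, truth = unlist(truth[1:4]))
dev.off()

ci <- credible_intervals(post, level = 0.95)
write.csv(cbind(bound = rownames(ci), as.data.frame(ci)),
          "results/credible_intervals.csv", row.names = FALSE)
print(round(ci, 3))

cm <- pairwise_correlations(post, fraction = 0.2)
write.csv(cbind(parameter = rownames(cm), as.data.frame(cm)),
          "results/correlations_best20.csv", row.names = FALSE)
message(sprintf("corr(F/k, k/b) on the best 20%%: %.2f  (expected negative: ridge)",
                cm["F_over_k", "k_over_b"]))

rec <- data.frame(
  parameter = c("F_over_k", "k_over_b", "alpha", "rho_unstressed"),
  truth = unlist(truth[1:4]),
  lower = ci["lower", ], upper = ci["upper", ],
  in_ci = unlist(truth[1:4]) >= ci["lower", ] &
    unlist(truth[1:4]) <= ci["upper", ]
)
rec$joint_fk_kb_in_hdr <- hdr2d_contains(post, "F_over_k", "k_over_b",
                                         truth$F_over_k, truth$k_over_b,
                                         level = 0.95, bins = 10)
write.csv(rec, "results/recovery_check.csv", row.names = FALSE)
print(rec, digits = 3)
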