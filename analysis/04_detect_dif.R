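#!/usr/bin/env Rscript
# Stage 4 -- hybrid logistic regression DIF analysis, pairwise by covariate.
#
# For every item and every group pair of each covariate, three nested
# logistic models conditioned on the EAP trait are compared by likelihood
# ratio (alpha = 0.01); McFadden R2 differences grade the magnitude
# (0.035 / 0.07 bands). The area covariate carries the injected DIF; gender
# and age-band are null covariates and act as negative controls.

suppressMessages(library(epicesdif))

m <- load_responses("results/cohort/responses.csv",
                    covariates = c("area", "gender", "age_band"))
m <- reverse_items(m, c(1, 5))
m10 <- subset_responses(m, items = 1:10)   # stage 3 removed item 11

truth <- read.delim("results/cohort/true_params.tsv")
true_dif <- sort(unique(truth$item[truth$dif]))
cat("ground-truth DIF items (area):", paste(true_dif, collapse = ", "), "\n\n")

for (cv in c("area", "gender", "age_band")) {
  res <- detect_dif(m10, cv)
  tab <- dif_table(res)
  write.table(tab, sprintf("results/table3_dif_%s.tsv", cv), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hits <- unique(res$item[res$flagged])
  cat(sprintf("%s: flagged item(s) %s after %d purification round(s)\n", cv,
              if (length(hits)) paste(hits, collapse = ", ") else "none",
              attr(res, "purify_iterations")))
  if (cv == "area") {
    print(tab[tab$classification != "no-DIF/not-assessed", ], row.names = FALSE)
  }
}
cat("\nexpect the area analysis to recover the injected items and the null\n")
cat("covariates to flag at most the occasional false positive (alpha 0.01).\n")
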