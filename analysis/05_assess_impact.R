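#!/usr/bin/env Rscript
# Stage 5 -- what do the detected DIFs do to the score?
#
# The latent trait is re-estimated letting DIF-flagged items carry
# area-specific parameters (anchor items link the scale, area latent
# distributions freed). Pearson correlations compare the weighted sum score
# with both latent estimates, and the two estimates with each other. The
# score and the trait run in opposite directions, so score-trait
# correlations are negative by construction.

suppressMessages(library(epicesdif))

m_raw <- load_responses("results/cohort/responses.csv",
                        covariates = c("area", "gender", "age_band"))
m10 <- subset_responses(reverse_items(m_raw, c(1, 5)), items = 1:10)

score <- epices_score(m_raw, epices_unit_config(11))
bank <- fit_grm(m10)
th_naive <- eap_scores(m10, bank)
dif_res <- detect_dif(m10, "area", theta = th_naive)
th_aware <- theta_dif_aware(m10, "area", dif_res)

rep <- correlation_report(score, th_naive, th_aware)
print(rep)
jsonlite::write_json(unclass(rep), "results/impact_area.json",
                     auto_unbox = TRUE, digits = 10)
free <- attr(th_aware, "bank")
if (inherits(free, "multigroup_bank")) {
  cat("items freed per area:", paste(free$free_items, collapse = ", "), "\n")
  print(free$group_dist, row.names = FALSE)
}
cat("strong naive/aware agreement means the detected DIFs, though real,\n")
cat("do not upend the ranking of respondents -- the score remains usable.\n")
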