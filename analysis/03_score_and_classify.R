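#!/usr/bin/env Rscript
# Compute the Ricotem- and Ricotem+ scores from the three assay AUCs of the
# simulated cohort, assign responder groups at the 25%/50% cut-offs, and
# tabulate them against the laboratory phenotype. Also prints the two
# published worked examples (healthy vs severe deficiency) normalized to
# percent of the Extem AUC. Writes results/scores.csv.

suppressPackageStartupMessages(library(ricotem))

co <- read_cohort_csv("results/cohort/cohort.csv")
scores <- co[, c("patient_id", "true_class", "phenotype", "ricotem_minus",
                 "ricotem_plus", "responder")]
write.csv(scores, "results/scores.csv", row.names = FALSE)

cat("Responder group vs laboratory phenotype (cut-offs 25% / 50%):\n")
print(table(responder = co$responder, phenotype = co$phenotype))

cat("\nWorked examples (percent of the Extem AUC):\n")
ex <- data.frame(
  subject = c("healthy", "severe deficiency"),
  auc_rico_pct = c(5.5, 75.9),
  auc_rico_haemate_pct = c(14.0, 6.2))
ex$ricotem_plus <- ricotem_plus(ex$auc_rico_pct, ex$auc_rico_haemate_pct, 100)
ex$responder <- classify_responder(ex$auc_rico_pct, ex$ricotem_plus)
print(ex, digits = 3)
cat("\nThe healthy subject's supplemented clot is slightly *stronger*",
    "\n(negative Ricotem+, normal responder); in severe VWF deficiency the",
    "\nconcentrate restores agglutination and Ricotem+ reaches 69.7%",
    "\n(high responder) -> candidate for VWF substitution.\n")
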