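#!/usr/bin/env Rscript
# Run the advisory bleeding-management extension on three worked cases: a
# bleeding patient with a high Ricotem+ (VWF concentrate worth considering),
# a bleeding patient whose score shows no concentrate effect, and a bleeding
# patient without a Ricotem panel after the standard steps are exhausted.
# Writes results/recommendations.json.

suppressPackageStartupMessages(library(ricotem))

cases <- list(
  high_responder = bleeding_case(TRUE, ricotem_plus_pct = 69.7),
  no_effect = bleeding_case(TRUE, ricotem_plus_pct = -8.5),
  panel_missing = bleeding_case(TRUE, prior_steps_exhausted = TRUE))

recs <- lapply(cases, recommend)
for (nm in names(recs)) {
  cat("\n--", nm, "--\n")
  if (length(recs[[nm]]$actions) == 0L) {
    cat("   no actions from the Ricotem+ path\n")
  } else {
    print(recs[[nm]]$rule_trace[, c("rule_id", "action")], row.names = FALSE)
  }
}
cat("\n", recs[[1]]$disclaimer, "\n")
write_report(recs, "results/recommendations.json")
cat("\nReport written to results/recommendations.json\n")
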