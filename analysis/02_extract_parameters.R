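#!/usr/bin/env Rscript
# Read the simulated trace files back from results/cohort/ and extract the
# standard viscoelastic parameters (CT, CFT, MCF) and the 30-minute
# velocity-curve area for every channel of every patient. Writes
# results/clot_parameters.csv.
#
# Run after analysis/01_simulate_cohort.R.

suppressPackageStartupMessages(library(ricotem))

files <- list.files("results/cohort", pattern = "^traces_.*\\.csv$",
                    full.names = TRUE)
if (length(files) == 0L)
  stop("no trace files found - run analysis/01_simulate_cohort.R first")

rows <- do.call(rbind, lapply(files, function(f) {
  pid <- sub("^traces_(.*)\\.csv$", "\\1", basename(f))
  traces <- read_trace_csv(f)
  cbind(patient_id = pid, do.call(rbind, lapply(traces, clot_parameters)))
}))
rownames(rows) <- NULL
write.csv(rows, "results/clot_parameters.csv", row.names = FALSE)

cat("Extracted parameters for", length(files), "patients x",
    length(unique(rows$channel)), "channels -> results/clot_parameters.csv\n\n")
cat("Channel medians:\n")
agg <- aggregate(cbind(ct_s, mcf_mm, auc30) ~ channel, data = rows,
                 FUN = median, na.action = na.pass, na.rm = TRUE)
print(agg, digits = 4)
cat("\nNote how the ristocetin channel's AUC collapses only in subjects",
    "\nwith functional VWF; CFT is frequently absent (clot never reaches",
    "\n20 mm) in strongly agglutinated samples.\n")
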