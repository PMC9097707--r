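#!/usr/bin/env Rscript
# Stage 2: sample-level quality control and genome-wide methylation levels.
# Reproduces the study's QC logic (mean coverage >= 1X, covered-site median
# >= 5X, global methylation below the 97th percentile of the remaining
# samples) and the global picture: ~0.5% of CpGs methylated in controls and
# natural stressors, a ~10-fold drop in azacytidine F1 with near-complete
# recovery in F2/F4.

source(file.path("analysis", "_common.R"))

demo <- load_demo()
qc <- qc_samples(demo$matrix, demo$sheet)
write_dmp_table(qc, file.path(RESULTS, "qc_report.tsv"))

cat(sprintf("%d of %d samples flagged by QC\n", sum(qc$flagged), nrow(qc)))

pm <- call_methylated_sites(demo$matrix)
glob <- aggregate(pct ~ treatment + generation,
                  data = data.frame(pct = pm[demo$sheet$sample_id],
                                    treatment = demo$sheet$treatment,
                                    generation = demo$sheet$generation),
                  FUN = function(x) round(mean(x), 3))
write_dmp_table(glob, file.path(RESULTS, "global_methylation.tsv"))
cat("global %CpGs methylated by treatment x generation:\n")
print(reshape(glob, idvar = "treatment", timevar = "generation",
              direction = "wide"), row.names = FALSE)
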