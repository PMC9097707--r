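#!/usr/bin/env Rscript
# Stage 1: simulate the study. A clonal Daphnia multigeneration design with
# four stressor lines (microcystin, temperature and azacytidine in
# experiment T1; zinc in T2) plus matched controls, three replicate animals
# per treatment x generation cell over F1/F2/F4. Planted DMPs (200 per
# natural stressor, 30-point effects, half persisting to F4) form the
# ground truth for the later stages; azacytidine acts through genome-wide
# hypomethylation instead of planted sites.

source(file.path("analysis", "_common.R"))

cfg <- demo_config()
ann <- simulate_annotation(cfg)
sim <- simulate_experiment(cfg, ann)
lh <- simulate_lifehistory(cfg)

write_gff3(ann, file.path(DATA, "annotation.gff3"))
write_go_map(ann$go_map, file.path(DATA, "gene_go_map.tsv"))
write_samplesheet(sim$sheet, file.path(DATA, "samplesheet.csv"))
write_dmp_table(sim$truth, file.path(DATA, "truth_table.tsv"))
write_dmp_table(lh, file.path(DATA, "life_history.tsv"))
write_bismark_coverage(sim$matrix, file.path(DATA, "coverage"), gzip = TRUE)

cat(sprintf("simulated %d CpGs x %d samples (%d planted DMPs, %d transgenerational)\n",
            nrow(sim$matrix$sites), length(sim$matrix$samples),
            nrow(sim$truth),
            sum(sim$truth$class == "transgenerational")))
cat(sprintf("genic CpG fraction: %.1f%% (target %.0f%%)\n",
            100 * mean(sim$site_info$genic), 100 * cfg$genic_fraction))
cat("coverage and annotation written under", DATA, "\n")
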