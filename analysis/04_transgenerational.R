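#!/usr/bin/env Rscript
# Stage 4: transgenerational DMP calling. Intersects each stressor's
# per-generation DMP sets (F1 & F2 & F4), summarizes persistence relative
# to F1, checks that the hypo/hyper direction is conserved across
# generations, pairs F1 against F4 effect sizes, runs the control-splitting
# two-stage alternative strategy, and tabulates cross-stressor sharing.

source(file.path("analysis", "_common.R"))

demo <- load_demo()
rows <- list(); tg_sets <- list()
for (st in stressor_names) {
  design <- comparison_design(demo$sheet, st)
  gt <- run_generation_tests(demo$matrix, design, fdr = 0.05)
  part <- intersect_generations(gt$dmps$F1, gt$dmps$F2, gt$dmps$F4)
  sign_tab <- check_sign_consistency(part, gt$results)
  pairs <- effect_size_pairs(gt$results$F1, gt$results$F4, part$center)
  write_dmp_table(pairs, file.path(RESULTS, sprintf("effect_pairs_%s.tsv", st)))
  alt <- alternative_two_stage(demo$matrix, design)
  tg_truth <- demo$truth$site[demo$truth$treatment == st &
                                demo$truth$class == "transgenerational"]
  rows[[st]] <- data.frame(
    stressor = st, f1_dmps = part$sizes[["F1"]],
    transgenerational = length(part$center),
    persistence_pct = if (part$sizes[["F1"]] > 0) persistence_fraction(part)
                      else NA,
    sign_consistent = attr(sign_tab, "fraction_consistent"),
    f1_f4_effect_cor = round(attr(pairs, "correlation"), 3),
    alternative_confirmed = nrow(alt),
    concordance_pct = if (length(part$center))
      round(strategy_concordance(part$center, alt$site), 1) else NA,
    recall_testable = if (length(intersect(tg_truth, gt$universe)))
      round(mean(intersect(tg_truth, gt$universe) %in% part$center), 2)
      else NA)
  tg_sets[[st]] <- part$center
}
tab <- do.call(rbind, rows)
write_dmp_table(tab, file.path(RESULTS, "transgenerational_summary.tsv"))
print(tab, row.names = FALSE)

cross <- cross_stressor_overlap(tg_sets)
write_dmp_table(cross$pairwise, file.path(RESULTS, "cross_stressor_overlap.tsv"))
cat("max pairwise cross-stressor overlap:", max(cross$pairwise$overlap), "\n")
for (st in stressor_names)
  writeLines(tg_sets[[st]], file.path(RESULTS, sprintf("transgen_%s.txt", st)))
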