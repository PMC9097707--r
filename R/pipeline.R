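#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end orchestration: simulate (annotation, counts, life history),
#' QC, per-generation differential methylation for every stressor,
#' transgenerational intersection with sign-consistency and effect-size
#' checks, overlap permutation tests, the alternative two-stage strategy,
#' positional and GO annotation, fitness effects, and recovery of the
#' planted truth. Every stage writes TSV/JSON artifacts into `outdir`; a
#' manifest (config hash, seed, package version) plus an aggregate summary
#' make the run reproducible: identical config and seed give identical
#' outputs.
#'
#' @param config A [sim_config()]; `config$master_seed` drives every stage
#'   stream (overridden by `seed` when given).
#' @param outdir Output directory (created).
#' @param seed Optional integer overriding `config$master_seed`.
#' @param fdr DMP-calling q-value cutoff.
#' @param n_perm_overlap Resamples for the overlap permutation tests.
#' @param n_perm_labels Label permutations of the whole analysis per
#'   stressor (0 disables this stage).
#' @param write_coverage Also write per-sample Bismark coverage files.
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         fdr = 0.05, n_perm_overlap = 1000,
                         n_perm_labels = 0, write_coverage = FALSE) {
  if (!is.null(seed)) config$master_seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[clonemeth] ", sprintf(...))

  ## stage: simulate
  log_msg("simulating genome annotation and experiment (%d CpGs)", config$n_cpgs)
  ann <- simulate_annotation(config)
  sim <- simulate_experiment(config, ann)
  write_gff3(ann, file.path(outdir, "annotation.gff3"))
  write_go_map(ann$go_map, file.path(outdir, "gene_go_map.tsv"))
  write_samplesheet(sim$sheet, file.path(outdir, "samplesheet.csv"))
  write_dmp_table(sim$truth, file.path(outdir, "truth_table.tsv"))
  if (write_coverage)
    write_bismark_coverage(sim$matrix, file.path(outdir, "coverage"))

  ## stage: qc
  qc <- qc_samples(sim$matrix, sim$sheet)
  write_dmp_table(qc, file.path(outdir, "qc_report.tsv"))
  log_msg("QC: %d/%d samples flagged", sum(qc$flagged), nrow(qc))

  stressors <- names(config$stressors)
  per_stressor <- list()
  transgen_sets <- list()
  universes <- list()
  for (st in stressors) {
    log_msg("testing stressor %s", st)
    design <- comparison_design(sim$sheet, st, config$generations)
    gt <- run_generation_tests(sim$matrix, design, fdr = fdr)
    for (g in config$generations)
      write_dmp_table(gt$results[[g]],
                      file.path(outdir, sprintf("dm_%s_%s.tsv", st, g)))
    part <- intersect_generations(gt$dmps[[1]], gt$dmps[[2]], gt$dmps[[3]])
    sign_tab <- check_sign_consistency(part, gt$results)
    pairs <- effect_size_pairs(gt$results[[1]],
                               gt$results[[length(gt$results)]], part$center)
    write_dmp_table(pairs, file.path(outdir, sprintf("effects_%s.tsv", st)))
    ov <- if (length(part$center) || any(part$counts > 0))
      overlap_permutation_test(
        lapply(gt$dmps, function(d) intersect(d$site, gt$universe)),
        gt$universe, n_perm = n_perm_overlap,
        seed = derive_seed(config$master_seed, paste0("overlap:", st)))
    else list(observed = 0L, p_value = 1, null_mean = 0)
    alt <- alternative_two_stage(sim$matrix, design, method = "wald")
    conc <- if (length(part$center))
      strategy_concordance(part$center, alt$site) else NA_real_
    truth_st <- sim$truth[sim$truth$treatment == st, ]
    tg_truth <- truth_st$site[truth_st$class == "transgenerational"]
    tg_testable <- intersect(tg_truth, gt$universe)
    recall <- if (length(tg_testable))
      mean(tg_testable %in% part$center) else NA_real_
    called_tg <- part$center
    precision <- if (length(called_tg))
      mean(called_tg %in% truth_st$site) else NA_real_
    lab_perm <- NULL
    if (n_perm_labels > 0) {
      lp <- permutation_null_run(
        sim$matrix, design, n_perm = n_perm_labels,
        seed = derive_seed(config$master_seed, paste0("labels:", st)),
        fdr = fdr)
      lab_perm <- list(n_transgen_total = sum(lp$n_transgen, na.rm = TRUE),
                       failed = length(lp$failed))
    }
    per_stressor[[st]] <- list(
      n_dmps = lapply(gt$dmps, nrow),
      venn = as.list(part$counts),
      n_transgen = length(part$center),
      persistence_pct = if (part$sizes[["F1"]] > 0)
        persistence_fraction(part) else NA_real_,
      sign_consistent_fraction = attr(sign_tab, "fraction_consistent"),
      effect_f1_f4_correlation = attr(pairs, "correlation"),
      overlap_p = ov$p_value, overlap_observed = ov$observed,
      alternative_n = nrow(alt), concordance_pct = conc,
      recall_transgen_testable = recall, precision_transgen = precision,
      n_transgen_planted = length(tg_truth),
      n_transgen_testable = length(tg_testable),
      label_permutation = lab_perm)
    transgen_sets[[st]] <- part$center
    universes[[st]] <- gt$universe
  }

  ## stage: cross-stressor overlap
  cross <- if (length(transgen_sets) >= 2) cross_stressor_overlap(transgen_sets)
           else list(pairwise = data.frame(overlap = integer(0)))
  shared_universe <- Reduce(intersect, universes)
  cross_test <- if (length(transgen_sets) >= 2 && length(shared_universe) > 0)
    tryCatch(cross_stressor_overlap_test(
      lapply(transgen_sets, function(s) intersect(s, shared_universe)),
      shared_universe, n_perm = n_perm_overlap,
      seed = derive_seed(config$master_seed, "cross")), error = function(e) NULL)
  else NULL

  ## stage: annotation + GO
  all_tg <- unique(unlist(transgen_sets, use.names = FALSE))
  asn <- assign_nearest_gene(if (length(all_tg)) all_tg else character(0), ann)
  write_dmp_table(asn, file.path(outdir, "transgen_annotation.tsv"))
  dist_tab <- if (length(all_tg))
    genomic_distribution(all_tg, sim$site_info$site, ann) else NULL
  clust <- gene_dmp_clustering(asn)
  tested_sites <- .parse_sites(unique(unlist(universes, use.names = FALSE)))
  bg_asn <- assign_nearest_gene(tested_sites, ann)
  bg_genes <- unique(stats::na.omit(bg_asn$gene_id[bg_asn$distance == 0]))
  study_genes <- unique(stats::na.omit(asn$gene_id[asn$distance == 0]))
  go <- if (length(study_genes) && length(bg_genes))
    go_enrichment(intersect(study_genes, bg_genes), bg_genes, ann$go_map) else NULL
  if (!is.null(go)) write_dmp_table(go, file.path(outdir, "go_enrichment.tsv"))

  ## stage: fitness
  lh <- simulate_lifehistory(config)
  fit <- fitness_effects(lh, n_boot = 1000,
                         seed = derive_seed(config$master_seed, "fitness-boot"))
  write_dmp_table(fit$effects, file.path(outdir, "fitness_effects.tsv"))

  summary <- list(
    n_cpgs = config$n_cpgs,
    n_samples = length(sim$matrix$samples),
    qc_flagged = sum(qc$flagged),
    per_stressor = per_stressor,
    cross_stressor = list(
      pairwise = cross$pairwise,
      max_pairwise = if (nrow(cross$pairwise)) max(cross$pairwise$overlap) else 0,
      tests = cross_test),
    genomic_distribution = dist_tab,
    clustering = list(fraction_multi = clust$fraction_multi,
                      median_distance = clust$median_distance),
    top_go = if (!is.null(go)) utils::head(go, 10) else NULL,
    fitness = fit$effects)
  write_report(summary, file.path(outdir, "summary.json"))
  manifest <- list(package = "clonemeth",
                   version = as.character(utils::packageVersion("clonemeth")),
                   seed = config$master_seed,
                   config_hash = rlang::hash(config),
                   config = config[setdiff(names(config), "stressors")],
                   stressors = config$stressors)
  write_report(manifest, file.path(outdir, "manifest.json"))
  log_msg("done; summary written to %s", file.path(outdir, "summary.json"))
  invisible(summary)
}
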