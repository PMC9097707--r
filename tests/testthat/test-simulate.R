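test_that("annotation layout is deterministic and respects the genic target", {
  cfg <- sim_config(n_cpgs = 20000, n_genes = 100, master_seed = 3L)
  ann1 <- simulate_annotation(cfg)
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann1$genes, ann2$genes)
  expect_identical(ann1$go_map, ann2$go_map)

  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(ann1, f1); write_gff3(ann2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # genes must not overlap and exons must stay inside their gene
  for (ch in unique(ann1$genes$chrom)) {
    g <- ann1$genes[ann1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  ex <- merge(ann1$exons, ann1$genes, by = "gene_id",
              suffixes = c("", ".gene"))
  expect_true(all(ex$start >= ex$start.gene & ex$end <= ex$end.gene))
  expect_true(all(lengths(ann1$go_map) >= 1 & lengths(ann1$go_map) <= 10))

  # genic CpG fraction close to the configured target, checked against an
  # independent brute-force containment scan
  sim <- simulate_experiment(cfg, ann1)
  genic_oracle <- vapply(seq_len(nrow(sim$site_info)), function(i) {
    g <- ann1$genes[ann1$genes$chrom == sim$site_info$chrom[i], ]
    any(sim$site_info$pos[i] >= g$start & sim$site_info$pos[i] <= g$end)
  }, TRUE)
  expect_equal(sim$site_info$genic, genic_oracle)
  expect_lt(abs(mean(genic_oracle) - cfg$genic_fraction), 0.05)
})

test_that("zero genes gives an all-intergenic annotation", {
  cfg <- sim_config(n_cpgs = 500, n_genes = 0, master_seed = 1L,
                    stressors = list())
  ann <- simulate_annotation(cfg)
  expect_identical(nrow(ann$genes), 0L)
  sim <- simulate_experiment(cfg, ann)
  expect_false(any(sim$site_info$genic))
})

test_that("count matrices respect count invariants and coverage calibration", {
  cfg <- small_config(n_cpgs = 12000)
  sim <- simulate_experiment(cfg)
  m <- sim$matrix
  expect_true(all(m$meth >= 0 & m$meth <= m$total))
  expect_true(is.integer(m$meth) && is.integer(m$total))
  # per-sample empirical mean coverage within 5% of the configured mean
  expect_true(all(abs(colMeans(m$total) - cfg$coverage_mean) <
                    0.05 * cfg$coverage_mean))
  # determinism: identical config gives identical counts
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim$matrix$meth, sim2$matrix$meth)
  expect_identical(sim$matrix$total, sim2$matrix$total)
})

test_that("planted DMPs shift case means in the planted direction", {
  cfg <- small_config(n_cpgs = 6000, n_planted = 60L, effect = 30,
                      persistence = 1, seed = 21L)
  sim <- simulate_experiment(cfg)
  m <- sim$matrix
  sheet <- sim$sheet
  # effect >= 20 points, coverage >= 5: case mean must exceed control mean
  # for hyper sites (and the reverse for hypo) in >= 95% of sites
  for (dir in c("hyper", "hypo")) {
    tr <- sim$truth[sim$truth$direction == dir &
                      sim$truth$class == "transgenerational", ]
    idx <- match(tr$site, m$key)
    cases <- sheet$sample_id[sheet$treatment == "microcystin"]
    ctrls <- sheet$sample_id[sheet$treatment == "control"]
    ci <- match(cases, m$samples); oi <- match(ctrls, m$samples)
    cov_ok <- rowMeans(m$total[idx, c(ci, oi)]) >= 5
    p_case <- rowSums(m$meth[idx, ci]) / pmax(rowSums(m$total[idx, ci]), 1)
    p_ctrl <- rowSums(m$meth[idx, oi]) / pmax(rowSums(m$total[idx, oi]), 1)
    gap <- if (dir == "hyper") p_case - p_ctrl else p_ctrl - p_case
    expect_gte(mean(gap[cov_ok] > 0), 0.95)
  }
})

test_that("null and boundary planting configurations behave as declared", {
  cfg0 <- small_config(n_planted = 0L, n_cpgs = 1500)
  sim0 <- simulate_experiment(cfg0)
  expect_identical(nrow(sim0$truth), 0L)

  cfg1 <- small_config(n_planted = 30L, persistence = 1, n_cpgs = 1500)
  sim1 <- simulate_experiment(cfg1)
  expect_true(all(sim1$truth$class == "transgenerational"))
  # truth sites exist in the matrix and classes are unique per site
  expect_true(all(sim1$truth$site %in% sim1$matrix$key))
  expect_identical(anyDuplicated(paste(sim1$truth$site, sim1$truth$treatment)), 0L)
})

test_that("azacytidine scaling depresses F1 methylation and resets later", {
  cfg <- sim_config(n_cpgs = 20000, master_seed = 5L,
                    stressors = default_stressors())
  sim <- simulate_experiment(cfg)
  pm <- call_methylated_sites(sim$matrix)
  sh <- sim$sheet
  lvl <- function(trt, gen) mean(pm[sh$sample_id[sh$treatment == trt &
                                                   sh$generation == gen]])
  # roughly 10-fold drop in F1, recovery towards (but below) control in F2/F4
  expect_lt(lvl("azacytidine", "F1"), 0.3 * lvl("control", "F1"))
  expect_gt(lvl("azacytidine", "F4"), 0.5 * lvl("control", "F4"))
  expect_lt(mean(c(lvl("azacytidine", "F2"), lvl("azacytidine", "F4"))),
            mean(c(lvl("control", "F2"), lvl("control", "F4"))))
})

test_that("life-history simulation has null, degenerate and planted regimes", {
  cfg <- small_config(n_cpgs = 500, n_planted = 0L)
  # null: no treatment effect anywhere; r should not differ from control
  lh0 <- simulate_lifehistory(cfg, n_per_cell = 120, brood_effect = 1)
  lh0 <- individual_fitness(lh0)
  f0 <- lh0[lh0$generation == "F0", ]
  tt <- stats::t.test(f0$r[f0$treatment == "microcystin"],
                      f0$r[f0$treatment == "control"])
  expect_gt(tt$p.value, 0.01)

  # degenerate: zero broods are flagged unreproductive
  lh <- simulate_lifehistory(cfg, n_per_cell = 5, base_brood1 = 0.0001,
                             base_brood2 = 0.0001)
  expect_true(all(lh$unreproductive[lh$brood1_size == 0 & lh$brood2_size == 0]))

  # planted -20% brood effect in the exposed generation is recoverable
  lh1 <- simulate_lifehistory(cfg, n_per_cell = 30, brood_effect = 0.8)
  fit <- fitness_effects(lh1, n_boot = 400, seed = 2)
  eff <- fit$effects
  f0row <- eff[eff$treatment == "microcystin" & eff$generation == "F0", ]
  expect_lt(f0row$upper, 0)
})
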