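## Synthetic WGBS generator: genome annotation, count matrices with planted
## persistence-controlled DMPs, and life-history tables.

#' Simulate a genome annotation
#'
#' Lays out non-overlapping genes (with exon sub-intervals) over
#' `n_chromosomes` chromosomes so that gene bodies cover about
#' `genic_fraction` of the genome, and assigns each gene 1-10 GO terms from a
#' synthetic vocabulary. Deterministic given `master_seed`.
#'
#' @param config A [sim_config()] object.
#' @return A `genome_annotation` list with elements `genes` (gene_id, chrom,
#'   start, end, strand), `exons` (gene_id, chrom, start, end),
#'   `go_map` (named list gene_id -> GO ids) and `chrom_lengths`.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$master_seed, "annotation"))
  n_chr <- config$n_chromosomes
  cpg_per_chr <- ceiling(config$n_cpgs / n_chr)
  chrom_len <- cpg_per_chr * 100L  # mean CpG spacing ~100 bp
  chroms <- paste0("chr", seq_len(n_chr))
  chrom_lengths <- stats::setNames(rep(chrom_len, n_chr), chroms)

  genes_per_chr <- diff(round(seq(0, config$n_genes, length.out = n_chr + 1)))
  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_len(n_chr)) {
    ng <- genes_per_chr[ci]
    if (ng == 0) next
    mean_len <- config$genic_fraction * chrom_len / ng
    if (ng * mean_len > chrom_len)
      stop("gene layout exceeds chromosome length; reduce n_genes or genic_fraction")
    glen <- stats::rgamma(ng, shape = 4, rate = 4 / mean_len)
    gap <- stats::rgamma(ng + 1, shape = 2,
                         rate = 2 / ((1 - config$genic_fraction) * chrom_len / (ng + 1)))
    tot <- sum(glen) + sum(gap)
    glen <- pmax(round(glen * chrom_len / tot), config$exons_per_gene * 2)
    gap <- pmax(round(gap * chrom_len / tot), 1)
    start <- cumsum(gap[seq_len(ng)]) + c(0, utils::head(cumsum(glen), -1)) + 1
    end <- pmin(start + glen - 1, chrom_len)
    for (gi in seq_len(ng)) {
      gid <- gid + 1L
      gene_id <- sprintf("gene%04d", gid)
      genes[[gid]] <- data.frame(gene_id = gene_id, chrom = chroms[ci],
                                 start = start[gi], end = end[gi],
                                 strand = sample(c("+", "-"), 1))
      ## alternate exon/intron segments inside the gene span
      k <- config$exons_per_gene
      w <- stats::rgamma(2 * k - 1, shape = 2, rate = 1)
      cuts <- round(cumsum(w) / sum(w) * glen[gi])
      seg <- pmax(cuts - c(0, utils::head(cuts, -1)), 1)
      bnd <- start[gi] + cumsum(c(0, seg))
      es <- bnd[seq(1, 2 * k - 1, by = 2)]
      ee <- pmin(bnd[seq(2, 2 * k, by = 2)] - 1, end[gi])
      ee <- pmax(ee, es)
      exons[[gid]] <- data.frame(gene_id = gene_id, chrom = chroms[ci],
                                 start = es, end = ee)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer())
  vocab <- sprintf("GO:SYN%04d", 1:50)
  go_map <- stats::setNames(lapply(seq_len(nrow(genes)), function(i)
    sort(sample(vocab, sample.int(10, 1)))), genes$gene_id)
  ann <- list(genes = genes, exons = exons, go_map = go_map,
              chrom_lengths = chrom_lengths)
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(x$chrom_lengths)))
  invisible(x)
}

## genic membership for sorted, non-overlapping genes on one chromosome
.in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  idx <- findInterval(pos, starts)
  idx >= 1 & pos <= ends[pmax(idx, 1)]
}

#' Simulate a multigenerational methylation experiment
#'
#' Generates per-sample CpG counts for the full exposure design: control and
#' stressor lines at generations F1/F2/F4 with `n_replicates` animals each,
#' planted DMPs with per-site persistence classes, and the azacytidine arm's
#' global multiplicative hypomethylation. Coverage is shared-propensity
#' Poisson; methylated counts are beta-binomial around the site x sample
#' mean. Returns the count matrix, the sample sheet and the truth table of
#' planted DMPs.
#'
#' Persistence classes: with probability `persistence_prob` a planted DMP is
#' `transgenerational` (active in F1, F2 and F4); otherwise it is `F1only`,
#' `F1F2` or `F1F4` with probabilities 0.5/0.25/0.25. Hypomethylating DMPs
#' are drawn only from the methylated mixture component; hypermethylating
#' DMPs from any site. Case means shifted outside [0, 1] are clamped and the
#' realized effect recorded in the truth table.
#'
#' @param config A [sim_config()] object.
#' @param annotation A `genome_annotation`, typically from
#'   [simulate_annotation()] with the same config.
#' @return A list with elements `matrix` ([meth_matrix()]), `sheet`
#'   (sample-sheet data.frame), `truth` (truth-table data.frame) and
#'   `site_info` (per-site chrom/pos/genic/component/baseline mean).
#' @export
simulate_experiment <- function(config, annotation = simulate_annotation(config)) {
  validate_sim_config(config)
  n <- config$n_cpgs
  chroms <- names(annotation$chrom_lengths)

  ## CpG positions, uniform over the genome
  set.seed(derive_seed(config$master_seed, "sites"))
  n_per <- diff(round(seq(0, n, length.out = length(chroms) + 1)))
  sites <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    pos <- sort(sample.int(annotation$chrom_lengths[ci], n_per[ci]))
    data.frame(chrom = chroms[ci], pos = pos)
  }))
  key <- paste0(sites$chrom, ":", sites$pos)
  genic <- logical(n)
  for (ch in chroms) {
    sel <- sites$chrom == ch
    g <- annotation$genes[annotation$genes$chrom == ch, ]
    genic[sel] <- .in_intervals(sites$pos[sel], g$start, g$end)
  }

  ## two-component baseline methylation, methylated component gene-body-enriched
  set.seed(derive_seed(config$master_seed, "baseline"))
  w <- ifelse(genic, config$genebody_enrichment, 1)
  p_comp <- pmin(config$baseline_methylated_fraction * w * n / sum(w), 1)
  comp <- stats::runif(n) < p_comp
  m0 <- numeric(n)
  hi <- config$high_meth_beta_params; lo <- config$low_meth_beta_params
  m0[comp] <- stats::rbeta(sum(comp), hi[1], hi[2])
  m0[!comp] <- stats::rbeta(sum(!comp), lo[1], lo[2])

  ## planted DMPs
  set.seed(derive_seed(config$master_seed, "planting"))
  classes <- c("F1only", "F1F2", "F1F4", "transgenerational")
  truth <- list()
  delta <- list()  # per stressor: numeric effect vector (proportion scale)
  active <- list() # per stressor: list of logical site masks per generation
  for (st in names(config$stressors)) {
    sp <- config$stressors[[st]]
    d <- numeric(n)
    if (sp$n_planted_dmps > 0) {
      n_hyper <- round(sp$n_planted_dmps * sp$hyper_fraction)
      n_hypo <- sp$n_planted_dmps - n_hyper
      meth_pool <- which(comp)
      if (n_hypo > length(meth_pool))
        stop("not enough methylated-component sites to plant hypomethylated DMPs")
      hypo <- sample(meth_pool, n_hypo)
      hyper <- sample(setdiff(seq_len(n), hypo), n_hyper)
      d[hypo] <- -sp$effect_size / 100
      d[hyper] <- sp$effect_size / 100
      planted <- c(hypo, hyper)
      cls <- ifelse(stats::runif(length(planted)) < sp$persistence_prob,
                    "transgenerational",
                    sample(c("F1only", "F1F2", "F1F4"), length(planted),
                           replace = TRUE, prob = c(0.5, 0.25, 0.25)))
      realized <- pmin(pmax(m0[planted] + d[planted], 0), 1) - m0[planted]
      truth[[st]] <- data.frame(
        site = key[planted], treatment = st,
        direction = ifelse(d[planted] > 0, "hyper", "hypo"),
        effect = sp$effect_size,
        realized_effect = round(100 * realized, 4),
        clamped = abs(realized - d[planted]) > 1e-9,
        class = cls)
    }
    delta[[st]] <- d
    msk <- function(gen) {
      if (is.null(truth[[st]])) return(logical(n))
      ok <- switch(gen,
                   F1 = classes,
                   F2 = c("F1F2", "transgenerational"),
                   F4 = c("F1F4", "transgenerational"))
      keep <- truth[[st]]$class %in% ok
      out <- logical(n)
      out[match(truth[[st]]$site[keep], key)] <- TRUE
      out
    }
    active[[st]] <- lapply(stats::setNames(config$generations,
                                           config$generations), msk)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(site = character(), treatment = character(),
               direction = character(), effect = numeric(),
               realized_effect = numeric(), clamped = logical(),
               class = character())
  rownames(truth) <- NULL

  ## sample sheet (controls are always emitted, even with no stressors)
  experiments <- unique(vapply(config$stressors, `[[`, "", "experiment"))
  if (length(experiments) == 0) experiments <- "T1"
  sheet <- list()
  for (ex in sort(experiments)) {
    trts <- c("control", names(config$stressors)[
      vapply(config$stressors, `[[`, "", "experiment") == ex])
    for (trt in trts) for (gen in config$generations)
      for (r in seq_len(config$n_replicates)) {
        sheet[[length(sheet) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_%s_r%d", ex, trt, gen, r),
          experiment = ex, treatment = trt, generation = gen,
          clone_line = config$clone_lines[(r - 1) %% length(config$clone_lines) + 1])
      }
  }
  sheet <- do.call(rbind, sheet)

  ## coverage propensities and library factors
  set.seed(derive_seed(config$master_seed, "coverage"))
  s_site <- stats::rgamma(n, shape = config$coverage_dispersion,
                          rate = config$coverage_dispersion)
  b <- exp(stats::rnorm(nrow(sheet), -config$library_factor_sd^2 / 2,
                        config$library_factor_sd))

  ## counts
  phi <- config$sample_dispersion
  meth <- matrix(0L, n, nrow(sheet)); total <- matrix(0L, n, nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    sm <- sheet[j, ]
    m <- m0
    if (sm$treatment == "azacytidine") {
      fac <- if (sm$generation == "F1") config$aza_f1_factor else
        config$aza_recovery_factor
      m <- m * fac
    }
    if (sm$treatment != "control" &&
        !is.null(active[[sm$treatment]][[sm$generation]])) {
      a <- active[[sm$treatment]][[sm$generation]]
      m[a] <- pmin(pmax(m0[a] + delta[[sm$treatment]][a], 0), 1)
    }
    set.seed(derive_seed(config$master_seed, paste0("counts:", sm$sample_id)))
    nt <- stats::rpois(n, config$coverage_mean * s_site * b[j])
    total[, j] <- nt
    meth[, j] <- rbetabinom(nt, m, phi)
  }
  mat <- meth_matrix(sites, meth, total, samples = sheet$sample_id)
  site_info <- data.frame(site = key, chrom = sites$chrom, pos = sites$pos,
                          genic = genic, methylated_component = comp,
                          baseline = m0)
  list(matrix = mat, sheet = sheet, truth = truth, site_info = site_info)
}

#' Beta-binomial sampler (intraclass-correlation parameterization)
#'
#' Draws `k ~ BetaBinomial(n, m, phi)` with `Var(k) = n m (1-m) (1 + (n-1) phi)`;
#' `phi = 0` reduces to the binomial.
#' @param n Integer vector of trial counts.
#' @param m Mean proportion (vector).
#' @param phi Overdispersion in `[0, 1)`.
#' @return Integer vector of successes.
#' @export
rbetabinom <- function(n, m, phi) {
  m <- rep_len(m, length(n))
  if (phi <= 0) return(stats::rbinom(length(n), n, m))
  q <- numeric(length(n))
  inner <- m > 0 & m < 1
  q[m >= 1] <- 1
  q[inner] <- stats::rbeta(sum(inner), m[inner] * (1 - phi) / phi,
                           (1 - m[inner]) * (1 - phi) / phi)
  stats::rbinom(length(n), n, q)
}

#' Simulate a life-history table
#'
#' Per individual: age (days) and size of the first and second brood, with
#' treatment x generation effects on brood sizes (stressors depress
#' reproduction in the exposed F0 and germ-cell-exposed F1 generations) and
#' clone-line random effects on the reproductive level.
#'
#' @param config A [sim_config()] object (stressor list and clone lines are
#'   reused; `master_seed` drives the RNG stream).
#' @param n_per_cell Individuals per treatment x generation cell.
#' @param generations Generations tracked (F0 includes the directly exposed
#'   mothers).
#' @param brood_effect Multiplier on stressor brood sizes in
#'   `effect_generations` (0.8 = a 20% reduction).
#' @param effect_generations Generations in which the stressor effect acts.
#' @param base_age1,base_gap Mean age at first brood and inter-brood gap, days.
#' @param age1_sd,gap_sd SDs of the brood ages, days.
#' @param base_brood1,base_brood2 Mean brood sizes (offspring).
#' @param clone_sd SD of the clone-line random effect on log brood size.
#' @return data.frame of `life_history` records with columns individual_id,
#'   experiment, treatment, generation, clone_line, age_first_repro,
#'   brood1_size, age_second_repro, brood2_size, unreproductive.
#' @export
simulate_lifehistory <- function(config, n_per_cell = 30,
                                 generations = c("F0", "F1", "F2", "F4"),
                                 brood_effect = 0.8,
                                 effect_generations = c("F0", "F1"),
                                 base_age1 = 8, base_gap = 3,
                                 age1_sd = 0.4, gap_sd = 0.3,
                                 base_brood1 = 20, base_brood2 = 25,
                                 clone_sd = 0.05) {
  validate_sim_config(config)
  set.seed(derive_seed(config$master_seed, "lifehistory"))
  experiments <- unique(vapply(config$stressors, `[[`, "", "experiment"))
  clone_eff <- stats::setNames(stats::rnorm(length(config$clone_lines), 0, clone_sd),
                               config$clone_lines)
  rows <- list()
  for (ex in sort(experiments)) {
    trts <- c("control", names(config$stressors)[
      vapply(config$stressors, `[[`, "", "experiment") == ex])
    for (trt in trts) for (gen in generations) {
      mult <- if (trt != "control" && gen %in% effect_generations)
        brood_effect else 1
      cl <- config$clone_lines[(seq_len(n_per_cell) - 1) %%
                                 length(config$clone_lines) + 1]
      age1 <- pmax(stats::rnorm(n_per_cell, base_age1, age1_sd), 2)
      age2 <- age1 + pmax(stats::rnorm(n_per_cell, base_gap, gap_sd), 0.5)
      lam1 <- base_brood1 * mult * exp(clone_eff[cl])
      lam2 <- base_brood2 * mult * exp(clone_eff[cl])
      b1 <- stats::rpois(n_per_cell, lam1)
      b2 <- stats::rpois(n_per_cell, lam2)
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = sprintf("%s_%s_%s_i%02d", ex, trt, gen, seq_len(n_per_cell)),
        experiment = ex, treatment = trt, generation = gen, clone_line = cl,
        age_first_repro = round(age1, 2), brood1_size = b1,
        age_second_repro = round(age2, 2), brood2_size = b2,
        unreproductive = b1 == 0 & b2 == 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
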