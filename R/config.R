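#' Simulation configuration
#'
#' Builds the configuration object that drives the synthetic WGBS generator.
#' Defaults emulate the statistical structure of low-coverage single-animal
#' bisulfite data from a clonal *Daphnia magna* multigenerational exposure
#' design: ~0.5% of CpGs in a methylated state, mean coverage 5.3X,
#' gene-body-enriched methylation, stressor-specific planted DMPs of which
#' about half persist through F2 and F4, and a drug (5-azacytidine) arm whose
#' effect is a genome-wide multiplicative hypomethylation in F1 with
#' near-complete resetting afterwards.
#'
#' Baseline methylation is a two-component mixture: most sites have a
#' near-zero methylation level drawn from `Beta(low_meth_beta_params)`, a
#' small fraction `baseline_methylated_fraction` is drawn from
#' `Beta(high_meth_beta_params)`. The methylated component is preferentially
#' placed inside gene bodies with odds multiplied by `genebody_enrichment`.
#' `baseline_methylated_fraction` is calibrated so that the packaged
#' methylated-site call rule (see [call_methylated_sites()]) yields ~0.50%
#' called sites at the default coverage.
#'
#' Per-site sequencing depth is `Poisson(coverage_mean * s * b)` where `s` is
#' a site-level propensity drawn from a Gamma with shape
#' `coverage_dispersion` and mean 1 (shared across samples, mimicking
#' mappability), and `b` a per-sample library factor (log-normal, sd
#' `library_factor_sd`).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_cpgs Total number of CpG sites across the genome.
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_gene Exons per gene.
#' @param genic_fraction Target fraction of the genome covered by gene bodies.
#' @param genebody_enrichment Odds multiplier for placing methylated-component
#'   sites inside gene bodies.
#' @param coverage_mean Mean per-site per-sample read depth (reads).
#' @param coverage_dispersion Gamma shape of the site-level coverage
#'   propensity; smaller values give more between-site depth variation.
#' @param library_factor_sd Log-scale SD of per-sample library size factors
#'   (0 by default: libraries sequenced to a common nominal depth, so
#'   per-sample mean coverage stays within a few percent of
#'   `coverage_mean`).
#' @param baseline_methylated_fraction Proportion of CpGs in the methylated
#'   mixture component.
#' @param high_meth_beta_params,low_meth_beta_params Beta shape pairs for the
#'   methylated and unmethylated mixture components.
#' @param sample_dispersion Beta-binomial overdispersion phi (in `[0, 1)`)
#'   across replicate animals.
#' @param stressors Named list of per-stressor settings; each element is a
#'   list with `n_planted_dmps`, `effect_size` (percentage points),
#'   `hyper_fraction`, `persistence_prob` and `experiment` ("T1" or "T2").
#' @param aza_f1_factor Multiplier applied to every site mean in azacytidine
#'   F1 cases (10-fold decrease by default).
#' @param aza_recovery_factor Multiplier in azacytidine F2/F4 cases
#'   (near-complete resetting).
#' @param n_replicates Replicate animals per treatment x generation cell.
#' @param generations Sequenced generations.
#' @param clone_lines Clone-line labels cycled over replicates.
#' @param master_seed Integer master seed; all stage streams derive from it
#'   (see [derive_seed()]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       n_cpgs = 50000,
                       n_genes = 400,
                       exons_per_gene = 5,
                       genic_fraction = 0.5,
                       genebody_enrichment = 25,
                       coverage_mean = 5.3,
                       coverage_dispersion = 0.3,
                       library_factor_sd = 0,
                       baseline_methylated_fraction = 0.0086,
                       high_meth_beta_params = c(8, 2),
                       low_meth_beta_params = c(0.2, 400),
                       sample_dispersion = 0.02,
                       stressors = default_stressors(),
                       aza_f1_factor = 0.1,
                       aza_recovery_factor = 0.9,
                       n_replicates = 3,
                       generations = c("F1", "F2", "F4"),
                       clone_lines = paste0("B", 1:5),
                       master_seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes), n_cpgs = as.integer(n_cpgs),
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    genic_fraction = genic_fraction, genebody_enrichment = genebody_enrichment,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    library_factor_sd = library_factor_sd,
    baseline_methylated_fraction = baseline_methylated_fraction,
    high_meth_beta_params = high_meth_beta_params,
    low_meth_beta_params = low_meth_beta_params,
    sample_dispersion = sample_dispersion,
    stressors = stressors,
    aza_f1_factor = aza_f1_factor, aza_recovery_factor = aza_recovery_factor,
    n_replicates = as.integer(n_replicates),
    generations = generations, clone_lines = clone_lines,
    master_seed = as.integer(master_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default stressor parameterization
#'
#' Three natural stressors (microcystin, temperature in experiment T1; zinc
#' in T2) each plant 200 DMPs with 30-percentage-point effects, half
#' hypermethylating, half of them persisting through F2 and F4. The
#' azacytidine arm plants no site-specific DMPs: its effect is the global
#' multiplicative scaling configured in [sim_config()].
#' @return Named list of stressor settings.
#' @export
default_stressors <- function() {
  nat <- function(exp) list(n_planted_dmps = 200L, effect_size = 30,
                            hyper_fraction = 0.5, persistence_prob = 0.5,
                            experiment = exp)
  list(microcystin = nat("T1"),
       temperature = nat("T1"),
       zinc = nat("T2"),
       azacytidine = list(n_planted_dmps = 0L, effect_size = 0,
                          hyper_fraction = 0.5, persistence_prob = 0.5,
                          experiment = "T1"))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$n_cpgs >= 1, cfg$n_genes >= 0,
            cfg$exons_per_gene >= 1, cfg$n_replicates >= 1)
  if (cfg$sample_dispersion < 0 || cfg$sample_dispersion >= 1)
    stop("sample_dispersion must lie in [0, 1)")
  props <- c(cfg$genic_fraction, cfg$baseline_methylated_fraction)
  if (any(props < 0 | props >= 1 + 1e-12))
    stop("proportions must lie in [0, 1)")
  if (cfg$coverage_mean <= 0 || cfg$coverage_dispersion <= 0)
    stop("coverage parameters must be positive")
  if (cfg$aza_f1_factor <= 0 || cfg$aza_f1_factor > 1 ||
      cfg$aza_recovery_factor <= 0 || cfg$aza_recovery_factor > 1)
    stop("aza factors must lie in (0, 1]")
  for (nm in names(cfg$stressors)) {
    s <- cfg$stressors[[nm]]
    if (s$n_planted_dmps < 0) stop("n_planted_dmps must be non-negative")
    if (s$n_planted_dmps > 0 && (s$effect_size <= 0 || s$effect_size > 100))
      stop("effect_size must lie in (0, 100]")
    if (s$hyper_fraction < 0 || s$hyper_fraction > 1 ||
        s$persistence_prob < 0 || s$persistence_prob > 1)
      stop("hyper_fraction and persistence_prob must lie in [0, 1]")
    if (!s$experiment %in% c("T1", "T2")) stop("experiment must be T1 or T2")
  }
  invisible(cfg)
}

#' Derive a child seed from a master seed
#'
#' Deterministic key-derivation for per-stage RNG streams: the child seed is
#' `(master * 48271 + stage_hash) mod (2^31 - 1)` where `stage_hash` is a
#' polynomial hash of the stage name. Stages are therefore independently
#' reproducible from the master seed alone.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage key, e.g. `"annotation"` or `"counts:F1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer((as.numeric(master_seed) %% m * 48271 + h) %% m)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Scalar fields override [sim_config()] defaults; the `stressors` block, if
#' present, replaces the default stressor list (each entry filled up with the
#' default natural-stressor settings).
#' @param path Path to a YAML (or JSON, parsed by yaml) config file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- formals(sim_config)
  args <- list()
  for (nm in setdiff(names(raw), "stressors")) {
    if (!nm %in% names(defaults)) stop("unknown config field: ", nm)
    args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$stressors)) {
    base <- list(n_planted_dmps = 200L, effect_size = 30, hyper_fraction = 0.5,
                 persistence_prob = 0.5, experiment = "T1")
    args$stressors <- lapply(raw$stressors, function(s) utils::modifyList(base, s))
  }
  do.call(sim_config, args)
}
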