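# Shared fixtures: small simulation configs and hand-built matrices.
# Small genomes need a higher methylated fraction so that enough
# methylated-component sites exist to plant hypomethylated DMPs on.

small_config <- function(n_cpgs = 4000, n_planted = 40L, effect = 30,
                         persistence = 1, seed = 7L, ...) {
  sim_config(
    n_cpgs = n_cpgs, n_genes = 40, baseline_methylated_fraction = 0.03,
    stressors = list(microcystin = list(
      n_planted_dmps = as.integer(n_planted), effect_size = effect,
      hyper_fraction = 0.5, persistence_prob = persistence,
      experiment = "T1")),
    master_seed = seed, ...)
}

# matrix from explicit count matrices
toy_matrix <- function(meth, total, chrom = "chr1") {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(colnames(total))) colnames(total) <-
      paste0("s", seq_len(ncol(total)))
  meth_matrix(data.frame(chrom = chrom, pos = seq_len(nrow(total))),
              meth, total, samples = colnames(total))
}

# annotation with explicit gene/exon coordinates on one chromosome
toy_annotation <- function(gene_start, gene_end,
                           exons = NULL, chrom_len = 10000L,
                           go_map = NULL) {
  ng <- length(gene_start)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)), chrom = "chr1",
                      start = gene_start, end = gene_end, strand = "+")
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                        start = gene_start, end = gene_end)
  ann <- list(genes = genes, exons = exons, go_map = go_map,
              chrom_lengths = c(chr1 = chrom_len))
  class(ann) <- "genome_annotation"
  ann
}
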