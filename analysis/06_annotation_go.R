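#!/usr/bin/env Rscript
# Stage 6: positional and functional annotation of the transgenerational
# DMPs pooled over the natural stressors: nearest genes, gene-body vs
# exon/intron placement against the genome-wide CpG background,
# within-gene clustering, and GO-term enrichment (classic per-term Fisher)
# against the genes carrying tested CpGs.

source(file.path("analysis", "_common.R"))

demo <- load_demo()
ann <- demo$annotation
tg <- unique(unlist(lapply(c("microcystin", "temperature", "zinc"), function(st)
  readLines(file.path(RESULTS, sprintf("transgen_%s.txt", st))))))
cat("annotating", length(tg), "transgenerational DMPs\n")

asn <- assign_nearest_gene(tg, ann)
write_dmp_table(asn, file.path(RESULTS, "transgen_annotation.tsv"))

dist_tab <- genomic_distribution(tg, demo$matrix$key, ann)
write_dmp_table(dist_tab, file.path(RESULTS, "genomic_distribution.tsv"))
print(dist_tab, row.names = FALSE)

clust <- gene_dmp_clustering(asn)
cat(sprintf("genes with >= 2 DMPs: %.0f%%; median within-gene distance: %s bp\n",
            100 * clust$fraction_multi,
            format(clust$median_distance)))

universe <- unique(unlist(lapply(c("microcystin", "temperature", "zinc"),
  function(st) readLines(file.path(RESULTS, sprintf("universe_%s.txt", st))))))
bg_genes <- unique(na.omit(assign_nearest_gene(universe, ann)$gene_id[
  assign_nearest_gene(universe, ann)$distance == 0]))
study_genes <- unique(na.omit(asn$gene_id[asn$distance == 0]))
go <- go_enrichment(intersect(study_genes, bg_genes), bg_genes, ann$go_map,
                    top_n = 10)
write_dmp_table(go, file.path(RESULTS, "go_enrichment_top10.tsv"))
cat("top GO terms (synthetic vocabulary):\n")
print(go, row.names = FALSE)
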