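test_that("nearest-gene assignment honors containment, ties and oracles", {
  ann <- toy_annotation(gene_start = c(100, 399), gene_end = c(199, 498),
                        exons = data.frame(gene_id = c("g01", "g01", "g02"),
                                           chrom = "chr1",
                                           start = c(100, 160, 399),
                                           end = c(129, 199, 498)))
  # inside exon 1 of gene 1
  a1 <- assign_nearest_gene("chr1:110", ann)
  expect_identical(a1$gene_id, "g01")
  expect_identical(a1$distance, 0)
  expect_identical(a1$feature, "exon")
  # inside the gene but between exons
  expect_identical(assign_nearest_gene("chr1:140", ann)$feature, "intron")
  # equidistant (100 bp) between gene 1 end (199) and gene 2 start (399):
  # leftmost gene start wins
  a3 <- assign_nearest_gene("chr1:299", ann)
  expect_identical(a3$distance, 100)
  expect_identical(a3$gene_id, "g01")
  expect_identical(a3$feature, "intergenic")
  # unknown chromosome flagged
  a4 <- assign_nearest_gene("chr9:50", ann)
  expect_true(a4$no_annotation)
  expect_identical(a4$feature, "intergenic")

  # 50 random sites against an all-pairs distance scan
  set.seed(61)
  sites <- paste0("chr1:", sample.int(600, 50))
  asn <- assign_nearest_gene(sites, ann)
  for (i in seq_along(sites)) {
    pos <- as.integer(sub("chr1:", "", sites[i]))
    dists <- pmax(ann$genes$start - pos, pos - ann$genes$end, 0)
    best <- which(dists == min(dists))
    if (length(best) > 1) best <- best[which.min(ann$genes$start[best])]
    expect_identical(asn$gene_id[i], ann$genes$gene_id[best])
    expect_identical(asn$distance[i], as.numeric(min(dists)))
  }
  # input order invariance
  rev_asn <- assign_nearest_gene(rev(sites), ann)
  expect_identical(rev_asn$gene_id, rev(asn$gene_id))
})

test_that("genomic distribution is a partition and recovers planted fractions", {
  ann <- toy_annotation(gene_start = c(100, 400), gene_end = c(199, 499))
  # all DMPs intergenic
  g0 <- genomic_distribution(paste0("chr1:", c(10, 20, 300)),
                             paste0("chr1:", c(10, 20, 300, 150)), ann)
  expect_equal(g0$pct_gene_body[g0$group == "dmp"], 0)
  # annotation without introns: exon share of genic sites 100%
  g1 <- genomic_distribution(paste0("chr1:", c(110, 120, 450)),
                             paste0("chr1:", c(110, 120, 450)), ann)
  expect_equal(g1$pct_exon_of_genic[g1$group == "dmp"], 100)
  expect_equal(g1$pct_exon_of_genic + g1$pct_intron_of_genic,
               c(100, 100))

  # planted genic fraction is recovered within 3 points
  set.seed(62)
  ann2 <- toy_annotation(gene_start = seq(1, 9001, by = 1000),
                         gene_end = seq(500, 9500, by = 1000))
  genic_pos <- unlist(lapply(seq(1, 9001, by = 1000), function(s)
    sample(s:(s + 499), 19)))
  inter_pos <- sample(setdiff(1:9500, unlist(lapply(1:10, function(i)
    (1000 * (i - 1) + 1):(1000 * (i - 1) + 500)))), 10)
  sites <- paste0("chr1:", c(genic_pos, inter_pos))  # 190 genic, 10 not
  g2 <- genomic_distribution(sites, sites, ann2)
  expect_lt(abs(g2$pct_gene_body[1] - 95), 3)
})

test_that("within-gene clustering counts, fractions and distances", {
  mk <- function(pos, gene) data.frame(site = paste0("chr1:", pos),
                                       chrom = "chr1", pos = pos,
                                       gene_id = gene, distance = 0,
                                       feature = "exon",
                                       no_annotation = FALSE)
  # one DMP per gene: no multi-DMP genes, empty distance table
  c1 <- gene_dmp_clustering(mk(c(10, 20, 30), c("g1", "g2", "g3")))
  expect_equal(c1$fraction_multi, 0)
  expect_identical(length(c1$pair_distances), 0L)
  expect_true(is.na(c1$median_distance))

  # one gene with DMPs at 100, 101, 118: consecutive distances {1, 17}
  c2 <- gene_dmp_clustering(mk(c(100, 101, 118), rep("g1", 3)))
  expect_equal(sort(c2$pair_distances), c(1, 17))
  expect_equal(c2$median_distance, 9)

  # sort invariance under permuted input positions
  c3 <- gene_dmp_clustering(mk(c(118, 100, 101), rep("g1", 3)))
  expect_identical(sort(c3$pair_distances), sort(c2$pair_distances))
  expect_equal(c3$median_distance, c2$median_distance)
})

test_that("GO enrichment matches an exact hypergeometric oracle", {
  # study genes = background: every term has p = 1
  gm <- list(g1 = "T1", g2 = "T1", g3 = c("T1", "T2"), g4 = "T2")
  e0 <- go_enrichment(names(gm), names(gm), gm)
  expect_true(all(e0$p_value == 1))

  # the worked 2x2 table: 8 of 10 study genes with the term, 10 of 90
  # background-only genes with it; one-sided tail by hypergeometric sum
  bg <- paste0("g", 1:100)
  term_genes <- c(paste0("g", 1:8), paste0("g", 11:20))  # 18 genes carry T
  study <- paste0("g", c(1:8, 91, 92))                   # 8 carriers of 10
  gm2 <- setNames(lapply(bg, function(g)
    if (g %in% term_genes) "T" else "U"), bg)
  e1 <- go_enrichment(study, bg, gm2)
  K <- 18; N <- 100; ns <- 10
  p_oracle <- sum(dhyper(8:min(K, ns), K, N - K, ns))
  expect_equal(e1$p_value[e1$term == "T"], p_oracle, tolerance = 1e-10)

  # random tables with margins <= 200 agree with phyper to 1e-10
  set.seed(63)
  for (i in 1:20) {
    N <- sample(50:200, 1); K <- sample.int(N, 1); ns <- sample.int(N, 1)
    bgx <- paste0("x", seq_len(N))
    gmx <- setNames(lapply(seq_len(N), function(j)
      if (j <= K) "TT" else "UU"), bgx)
    st <- sample(bgx, ns)
    ex <- go_enrichment(st, bgx, gmx)
    a <- sum(st %in% bgx[seq_len(K)])
    expect_equal(ex$p_value[ex$term == "TT"],
                 phyper(a - 1, K, N - K, ns, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # a term planted on every study gene ranks first
  gm3 <- setNames(lapply(bg, function(g)
    c(if (g %in% study) "PLANT", sample(c("A", "B", "C"), 1))), bg)
  e3 <- go_enrichment(study, bg, gm3)
  expect_identical(e3$term[1], "PLANT")

  expect_error(go_enrichment("zz", bg, gm2), "subset")
})
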