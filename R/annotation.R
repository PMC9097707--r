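## Positional annotation of DMPs (nearest gene, exon/intron/intergenic,
## within-gene clustering) and GO-term enrichment.

.parse_sites <- function(sites) {
  if (is.data.frame(sites)) {
    if (!is.null(sites$site) && is.null(sites$chrom)) sites <- sites$site
    else return(data.frame(site = paste0(sites$chrom, ":", sites$pos),
                           chrom = as.character(sites$chrom),
                           pos = as.integer(sites$pos)))
  }
  parts <- strsplit(as.character(sites), ":", fixed = TRUE)
  data.frame(site = as.character(sites),
             chrom = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)))
}

#' Nearest-gene assignment of CpG sites
#'
#' A site inside a gene gets that gene with distance 0 and feature `exon`
#' (inside any exon of the gene) or `intron`; otherwise the nearest gene by
#' coordinate distance to the closer gene boundary, with feature
#' `intergenic`. Ties are broken by smaller distance, then leftmost gene
#' start, then lexicographic gene_id. Sites on chromosomes absent from the
#' annotation stay intergenic with `NA` distance and are flagged.
#'
#' @param sites Site keys (`"chrom:pos"`), or a data.frame with
#'   chrom/pos or site columns.
#' @param ann A `genome_annotation`.
#' @return data.frame: site, chrom, pos, gene_id, distance, feature,
#'   no_annotation flag.
#' @export
assign_nearest_gene <- function(sites, ann) {
  st <- .parse_sites(sites)
  n <- nrow(st)
  out <- data.frame(st, gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    feature = rep("intergenic", n),
                    no_annotation = rep(FALSE, n))
  if (n == 0 || nrow(ann$genes) == 0) {
    out$no_annotation <- rep(TRUE, n)
    return(out)
  }
  ## candidate genes per site: any containing gene, the left gene with the
  ## largest end, the right gene with the smallest start; pick by
  ## (distance, gene start, gene_id). Built per chromosome so ties are
  ## resolved by the documented rule, not by interval-tree internals.
  for (ch in unique(st$chrom)) {
    si <- which(st$chrom == ch)
    g <- ann$genes[ann$genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    pos <- st$pos[si]
    ## containment
    ir <- IRanges::IRanges(g$start, g$end)
    ov <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), ir)
    cand_q <- S4Vectors::queryHits(ov); cand_g <- S4Vectors::subjectHits(ov)
    ## left neighbors: gene with the largest end <= pos (plus end ties)
    oe <- order(g$end, g$start, g$gene_id)
    ends <- g$end[oe]
    li <- findInterval(pos, ends)
    has_l <- which(li >= 1)
    cand_q <- c(cand_q, has_l); cand_g <- c(cand_g, oe[li[has_l]])
    dup_end <- ends %in% ends[duplicated(ends)]
    for (k in has_l[dup_end[li[has_l]]]) {
      lg <- oe[setdiff(which(ends == ends[li[k]]), li[k])]
      cand_q <- c(cand_q, rep(k, length(lg))); cand_g <- c(cand_g, lg)
    }
    ## right neighbors: gene with the smallest start >= pos (plus start ties)
    os <- order(g$start, g$end, g$gene_id)
    starts <- g$start[os]
    ri <- length(starts) - findInterval(-pos, sort(-starts)) + 1L
    has_r <- which(ri <= length(starts))
    cand_q <- c(cand_q, has_r); cand_g <- c(cand_g, os[ri[has_r]])
    dup_start <- starts %in% starts[duplicated(starts)]
    for (k in has_r[dup_start[ri[has_r]]]) {
      rg <- os[setdiff(which(starts == starts[ri[k]]), ri[k])]
      cand_q <- c(cand_q, rep(k, length(rg))); cand_g <- c(cand_g, rg)
    }
    if (length(cand_q) == 0) next
    cdist <- pmax(g$start[cand_g] - pos[cand_q],
                  pos[cand_q] - g$end[cand_g], 0)
    ord <- order(cand_q, cdist, g$start[cand_g], g$gene_id[cand_g])
    first <- ord[!duplicated(cand_q[ord])]
    out$gene_id[si[cand_q[first]]] <- g$gene_id[cand_g[first]]
    out$distance[si[cand_q[first]]] <- cdist[first]
  }
  out$no_annotation <- is.na(out$gene_id)
  inside <- !is.na(out$distance) & out$distance == 0
  if (any(inside)) {
    egr <- GenomicRanges::GRanges(ann$exons$chrom,
                                  IRanges::IRanges(ann$exons$start, ann$exons$end))
    sgr_in <- GenomicRanges::GRanges(st$chrom[inside],
                                     IRanges::IRanges(st$pos[inside],
                                                      st$pos[inside]))
    ov <- GenomicRanges::findOverlaps(sgr_in, egr)
    in_exon <- logical(sum(inside))
    idx_inside <- which(inside)
    oq <- S4Vectors::queryHits(ov); os <- S4Vectors::subjectHits(ov)
    same_gene <- ann$exons$gene_id[os] == out$gene_id[idx_inside[oq]]
    in_exon[unique(oq[same_gene])] <- TRUE
    out$feature[idx_inside] <- ifelse(in_exon, "exon", "intron")
  }
  out
}

#' Genomic distribution of DMPs versus the CpG background
#'
#' For the DMP list and the genome-wide CpG background: the percentage of
#' sites lying within gene bodies (strict containment), and, of those, the
#' exon versus intron split.
#'
#' @param dmp_sites DMP site keys or data.frame.
#' @param all_sites Background site keys or data.frame (all genome CpGs).
#' @param ann A `genome_annotation`.
#' @return data.frame with rows `dmp` and `background`: n, pct_gene_body,
#'   pct_exon_of_genic, pct_intron_of_genic.
#' @export
genomic_distribution <- function(dmp_sites, all_sites, ann) {
  one <- function(sites) {
    asn <- assign_nearest_gene(sites, ann)
    n <- nrow(asn)
    genic <- !is.na(asn$distance) & asn$distance == 0
    ex <- sum(asn$feature == "exon")
    data.frame(n = n,
               pct_gene_body = if (n) 100 * mean(genic) else NA_real_,
               pct_exon_of_genic = if (sum(genic)) 100 * ex / sum(genic)
                                   else NA_real_,
               pct_intron_of_genic = if (sum(genic))
                 100 * sum(asn$feature == "intron") / sum(genic) else NA_real_)
  }
  out <- rbind(dmp = one(dmp_sites), background = one(all_sites))
  out$group <- rownames(out); rownames(out) <- NULL
  out[, c("group", "n", "pct_gene_body", "pct_exon_of_genic",
          "pct_intron_of_genic")]
}

#' Within-gene DMP clustering
#'
#' Per-gene DMP counts (gene-body assignments only), the fraction of
#' DMP-containing genes with at least two DMPs, and the distances between
#' consecutive sorted DMPs within a gene.
#'
#' @param assignments Output of [assign_nearest_gene()] for the DMPs.
#' @return List: `per_gene` (gene_id, n_dmps), `fraction_multi`,
#'   `pair_distances` (bp, consecutive within genes), `median_distance`.
#' @export
gene_dmp_clustering <- function(assignments) {
  genic <- assignments[!is.na(assignments$distance) &
                         assignments$distance == 0, ]
  if (nrow(genic) == 0)
    return(list(per_gene = data.frame(gene_id = character(), n_dmps = integer()),
                fraction_multi = NA_real_, pair_distances = numeric(0),
                median_distance = NA_real_))
  cnt <- table(genic$gene_id)
  per_gene <- data.frame(gene_id = names(cnt), n_dmps = as.integer(cnt))
  dists <- unlist(lapply(split(genic$pos, genic$gene_id), function(p) {
    if (length(p) < 2) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
  list(per_gene = per_gene,
       fraction_multi = mean(per_gene$n_dmps >= 2),
       pair_distances = dists,
       median_distance = if (length(dists)) stats::median(dists) else NA_real_)
}

#' GO-term enrichment by one-sided Fisher tests
#'
#' Classic per-term Fisher's exact test for enrichment of study genes in
#' each GO term against a gene background, BH-adjusted across terms. The
#' 2x2 table per term is (study with term, study without, background-only
#' with term, background-only without).
#'
#' @param study_genes Character vector, subset of `background_genes`.
#' @param background_genes Character vector of background gene ids.
#' @param go_map Named list gene_id -> GO term ids (must cover background).
#' @param top_n Optionally return only the top rows by p-value.
#' @return data.frame sorted by p-value: term, study_count, background_count,
#'   expected, p_value, q_value.
#' @export
go_enrichment <- function(study_genes, background_genes, go_map, top_n = NULL) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (length(setdiff(study_genes, background_genes)))
    stop("study genes must be a subset of the background")
  gm <- go_map[intersect(names(go_map), background_genes)]
  terms <- sort(unique(unlist(gm, use.names = FALSE)))
  ns <- length(study_genes); nb <- length(background_genes)
  rows <- lapply(terms, function(tm) {
    with_term <- names(gm)[vapply(gm, function(x) tm %in% x, TRUE)]
    K <- length(with_term)
    if (K == 0) return(NULL)
    a <- length(intersect(study_genes, with_term))
    tab <- matrix(c(a, ns - a, K - a, (nb - ns) - (K - a)), 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, study_count = a, background_count = K,
               expected = ns * K / nb, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(), study_count = integer(),
                                      background_count = integer(),
                                      expected = numeric(), p_value = numeric(),
                                      q_value = numeric()))
  out$q_value <- adjust_bh(out$p_value)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
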