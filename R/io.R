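## Standard-format IO: Bismark coverage files, sample sheets, GFF3,
## gene -> GO maps, DMP tables and JSON reports. Coordinates are 1-based
## inclusive everywhere (Bismark and GFF3 conventions).

#' Read a Bismark coverage file
#'
#' Six tab-separated columns: chrom, start (1-based), end, percent
#' methylation, count methylated, count unmethylated. The percent column is
#' ignored and recomputed from the counts. Plain or gzip input.
#'
#' @param path File path (`.gz` handled transparently).
#' @return data.frame with columns chrom, pos, meth, total.
#' @export
read_bismark_coverage <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) == 0) {
    warning("empty coverage file: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6))
    stop("malformed row at line ", which(nfield != 6)[1], " of ", path,
         ": expected 6 tab-separated columns")
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0)
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", path)
  data.frame(chrom = m[, 1], pos = pos, meth = meth, total = meth + unmeth)
}

#' Write Bismark coverage files for a methylation matrix
#'
#' One file per sample, named `<sample_id>.cov[.gz]`, with the standard six
#' columns (start == end for a CpG). Zero-coverage sites are omitted, as
#' Bismark only reports observed cytosines.
#'
#' @param mat A [meth_matrix()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress output files.
#' @return Invisibly, a named vector of file paths.
#' @export
write_bismark_coverage <- function(mat, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(mat$samples))
  names(paths) <- mat$samples
  for (j in seq_along(mat$samples)) {
    keep <- mat$total[, j] > 0
    pct <- ifelse(mat$total[keep, j] > 0,
                  100 * mat$meth[keep, j] / mat$total[keep, j], 0)
    p <- file.path(dir, paste0(mat$samples[j], ".cov", if (gzip) ".gz" else ""))
    con <- if (gzip) gzfile(p, "w") else file(p, "w")
    writeLines(paste(mat$sites$chrom[keep], mat$sites$pos[keep],
                     mat$sites$pos[keep], sprintf("%.6g", pct),
                     mat$meth[keep, j], mat$total[keep, j] - mat$meth[keep, j],
                     sep = "\t"), con)
    close(con)
    paths[j] <- p
  }
  invisible(paths)
}

#' Assemble a methylation matrix from per-sample records
#'
#' @param records Named list (by sample id) of data.frames as returned by
#'   [read_bismark_coverage()].
#' @param sheet Sample sheet; every `sample_id` must have a record.
#' @param site_policy `"union"` (absent sites filled with total 0, the
#'   default) or `"intersection"` (keep sites present in every sample).
#' @return A [meth_matrix()].
#' @export
assemble_matrix <- function(records, sheet, site_policy = c("union", "intersection")) {
  site_policy <- match.arg(site_policy)
  missing <- setdiff(sheet$sample_id, names(records))
  if (length(missing))
    stop("no records for sample(s): ", paste(missing, collapse = ", "))
  records <- records[sheet$sample_id]
  keys <- lapply(records, function(r) paste0(r$chrom, ":", r$pos))
  for (i in seq_along(keys)) if (anyDuplicated(keys[[i]]))
    stop("duplicate (chrom, position) in sample ", names(records)[i])
  all_keys <- if (site_policy == "union") Reduce(union, keys) else
    Reduce(intersect, keys)
  if (length(all_keys) == 0)
    return(meth_matrix(data.frame(chrom = character(), pos = integer()),
                       matrix(0L, 0, length(records)),
                       matrix(0L, 0, length(records)),
                       samples = names(records)))
  parts <- strsplit(all_keys, ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)))
  meth <- matrix(0L, length(all_keys), length(records))
  total <- matrix(0L, length(all_keys), length(records))
  for (j in seq_along(records)) {
    idx <- match(keys[[j]], all_keys)
    keep <- !is.na(idx)
    meth[idx[keep], j] <- records[[j]]$meth[keep]
    total[idx[keep], j] <- records[[j]]$total[keep]
  }
  meth_matrix(sites, meth, total, samples = names(records))
}

#' Read a sample sheet CSV
#'
#' Columns: sample_id, experiment (T1/T2), treatment, generation, clone_line,
#' optionally `file` (coverage-file path).
#' @param path CSV path.
#' @return data.frame.
#' @export
read_samplesheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "experiment", "treatment", "generation", "clone_line")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet misses column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  sheet
}

#' Write a sample sheet CSV
#' @param sheet data.frame.
#' @param path Output path.
#' @export
write_samplesheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genome annotation as GFF3
#'
#' Gene and exon features; exons carry a `Parent` attribute. Output is
#' deterministic (fixed column formatting), so identical annotations give
#' byte-identical files.
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(ann$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(ann$chrom_lengths[[ch]])), con)
  g <- ann$genes
  ord <- order(g$chrom, g$start)
  for (i in ord) {
    writeLines(sprintf("%s\tclonemeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    e <- ann$exons[ann$exons$gene_id == g$gene_id[i], ]
    e <- e[order(e$start), ]
    for (k in seq_len(nrow(e)))
      writeLines(sprintf("%s\tclonemeth\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         e$chrom[k], e$start[k], e$end[k], g$strand[i],
                         g$gene_id[i], k, g$gene_id[i]), con)
  }
  invisible(path)
}

#' Read a GFF3 gene/exon annotation
#'
#' Parses gene and exon features (via rtracklayer) and resolves exons to
#' their parent genes through the `Parent` attribute. Orphan exons are
#' attached to an enclosing gene when one exists, otherwise dropped with a
#' warning.
#' @param path GFF3 path.
#' @param go_map Optional named list gene_id -> GO ids to attach.
#' @return A `genome_annotation`.
#' @export
read_gff3 <- function(path, go_map = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  gg <- gr[ty == "gene"]
  ee <- gr[ty == "exon"]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)))
  parent <- vapply(as.list(ee$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  if (anyNA(parent) && length(ee)) {
    ov <- GenomicRanges::findOverlaps(ee, gg, type = "within", select = "first")
    fix <- is.na(parent) & !is.na(ov)
    parent[fix] <- genes$gene_id[ov[fix]]
    if (any(is.na(parent))) {
      warning(sum(is.na(parent)), " orphan exon(s) dropped")
      ee <- ee[!is.na(parent)]; parent <- parent[!is.na(parent)]
    }
  }
  exons <- data.frame(gene_id = parent,
                      chrom = as.character(GenomicRanges::seqnames(ee)),
                      start = GenomicRanges::start(ee),
                      end = GenomicRanges::end(ee))
  si <- GenomicRanges::seqinfo(gr)
  lens <- GenomeInfoDb::seqlengths(si)
  if (all(is.na(lens)))
    lens <- tapply(c(genes$end, exons$end), c(genes$chrom, exons$chrom), max)
  ann <- list(genes = genes[order(genes$chrom, genes$start), ],
              exons = exons[order(exons$chrom, exons$start), ],
              go_map = go_map,
              chrom_lengths = stats::setNames(as.integer(lens), names(lens)))
  rownames(ann$genes) <- rownames(ann$exons) <- NULL
  class(ann) <- "genome_annotation"
  ann
}

#' Write / read a gene -> GO map as TSV
#'
#' Two columns: gene_id, comma-separated GO term ids.
#' @param go_map Named list gene_id -> character vector of GO ids.
#' @param path TSV path.
#' @return `read_go_map` returns a named list.
#' @export
write_go_map <- function(go_map, path) {
  df <- data.frame(gene_id = names(go_map),
                   go_terms = vapply(go_map, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_go_map
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(df$go_terms, ",", fixed = TRUE), df$gene_id)
}

#' Write a differential-methylation or DMP table as TSV
#'
#' Stable column order; numeric columns written in full precision.
#' @param results data.frame.
#' @param path Output path.
#' @export
write_dmp_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a summary report as JSON
#' @param summary Named list.
#' @param path Output path.
#' @export
write_report <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
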