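#' Methylation count matrix
#'
#' The pipeline's central container: per-CpG, per-sample methylated and total
#' read counts. Sites are kept sorted by (chrom, position) and addressed by a
#' site key `"chrom:position"`. Coordinates are 1-based throughout.
#'
#' @param sites data.frame with columns `chrom` (character) and `pos`
#'   (integer, 1-based).
#' @param meth,total Integer matrices, one row per site and one column per
#'   sample; `0 <= meth <= total` cellwise.
#' @param samples Character vector of sample ids (column names).
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(sites, meth, total, samples = colnames(total)) {
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos))
  meth <- as.matrix(meth); total <- as.matrix(total)
  storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
  if (nrow(sites) != nrow(meth) || nrow(sites) != nrow(total))
    stop("sites and count matrices disagree in length")
  if (!identical(dim(meth), dim(total)))
    stop("meth and total must have identical dimensions")
  if (is.null(samples)) stop("sample names required")
  colnames(meth) <- colnames(total) <- samples
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  meth <- meth[ord, , drop = FALSE]; total <- total[ord, , drop = FALSE]
  key <- if (nrow(sites)) paste0(sites$chrom, ":", sites$pos) else character(0)
  if (anyDuplicated(key)) stop("duplicate (chrom, position) sites")
  rownames(meth) <- rownames(total) <- rownames(sites) <- NULL
  x <- list(sites = sites, meth = meth, total = total,
            samples = as.character(samples), key = key)
  class(x) <- "meth_matrix"
  validate_meth_matrix(x)
  x
}

validate_meth_matrix <- function(x) {
  if (nrow(x$meth) > 0) {
    if (any(x$meth < 0) || any(x$total < 0)) stop("counts must be non-negative")
    if (any(x$meth > x$total)) stop("methylated counts exceed totals")
  }
  if (any(x$sites$pos < 1)) stop("positions must be >= 1")
  invisible(x)
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples (%d chromosome%s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom)),
              if (length(unique(x$sites$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a methylation matrix
#'
#' @param x A `meth_matrix`.
#' @param sites Logical/integer row index or character site keys.
#' @param samples Character sample ids or column index.
#' @return A `meth_matrix` restricted to the selection.
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  ri <- seq_len(nrow(x$sites)); ci <- seq_along(x$samples)
  if (!is.null(sites)) {
    ri <- if (is.character(sites)) match(sites, x$key) else ri[sites]
    if (anyNA(ri)) stop("unknown site key in subset")
  }
  if (!is.null(samples)) {
    ci <- if (is.character(samples)) match(samples, x$samples) else ci[samples]
    if (anyNA(ci)) stop("unknown sample in subset")
  }
  meth_matrix(x$sites[ri, , drop = FALSE],
              x$meth[ri, ci, drop = FALSE],
              x$total[ri, ci, drop = FALSE],
              samples = x$samples[ci])
}

#' Site keys of a methylation matrix
#' @param x A `meth_matrix`.
#' @return Character vector `"chrom:pos"`.
#' @export
site_keys <- function(x) x$key
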