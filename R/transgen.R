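## Combining per-generation DMP sets into transgenerational calls and the
## alternative two-stage confirmation strategy.

.set_sites <- function(x) {
  if (is.data.frame(x)) as.character(x$site) else as.character(x)
}

#' Three-generation Venn partition
#'
#' Exact set algebra on site keys for the F1/F2/F4 DMP sets; no effect-size
#' threshold is applied. The transgenerational set is the triple
#' intersection.
#'
#' @param dmps_f1,dmps_f2,dmps_f4 `dmp_set`s or character site-key vectors.
#' @return A `venn_partition` list: the seven disjoint region site vectors
#'   (`f1_only`, `f2_only`, `f4_only`, `f1f2`, `f1f4`, `f2f4`, `center`),
#'   `counts`, set sizes, and `union_size`.
#' @export
intersect_generations <- function(dmps_f1, dmps_f2, dmps_f4) {
  s1 <- unique(.set_sites(dmps_f1)); s2 <- unique(.set_sites(dmps_f2))
  s4 <- unique(.set_sites(dmps_f4))
  all <- unique(c(s1, s2, s4))
  in1 <- all %in% s1; in2 <- all %in% s2; in4 <- all %in% s4
  regions <- list(
    f1_only = all[in1 & !in2 & !in4],
    f2_only = all[!in1 & in2 & !in4],
    f4_only = all[!in1 & !in2 & in4],
    f1f2 = all[in1 & in2 & !in4],
    f1f4 = all[in1 & !in2 & in4],
    f2f4 = all[!in1 & in2 & in4],
    center = all[in1 & in2 & in4])
  out <- c(regions,
           list(counts = vapply(regions, length, 1L),
                sizes = c(F1 = length(s1), F2 = length(s2), F4 = length(s4)),
                union_size = length(all)))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition:", paste(names(x$counts), x$counts, collapse = ", "),
      "\n  |F1|,|F2|,|F4| =", paste(x$sizes, collapse = ", "),
      " union =", x$union_size, "\n")
  invisible(x)
}

#' Persistence fraction of F1 DMPs
#'
#' Percentage of the reference generation's DMPs that lie in the
#' three-generation intersection, `100 * |center| / |F1|`, reported to one
#' decimal place (the convention used to report, e.g., 130/225 = 57.8%).
#'
#' @param partition A `venn_partition`.
#' @param relative_to Reference set, `"F1"` by default.
#' @return Percentage rounded to one decimal.
#' @export
persistence_fraction <- function(partition, relative_to = "F1") {
  denom <- partition$sizes[[relative_to]]
  if (denom == 0) stop("reference set is empty")
  round(100 * length(partition$center) / denom, 1)
}

#' Direction consistency of transgenerational DMPs
#'
#' For every center (transgenerational) site, tabulates the sign of the
#' methylation difference in each generation and flags sites whose
#' hypo/hyper direction is not identical across F1, F2 and F4.
#'
#' @param partition A `venn_partition`.
#' @param results Named list of per-generation `dm_result`s (F1, F2, F4).
#' @return data.frame (site, dir_F1, dir_F2, dir_F4, consistent) with the
#'   summary fraction in attribute `fraction_consistent`.
#' @export
check_sign_consistency <- function(partition, results) {
  sites <- partition$center
  if (length(sites) == 0) {
    out <- data.frame(site = character(0))
    for (g in names(results)) out[[paste0("dir_", g)]] <- character(0)
    out$consistent <- logical(0)
    attr(out, "fraction_consistent") <- NA_real_
    return(out)
  }
  dirs <- sapply(names(results), function(g) {
    r <- results[[g]]
    md <- r$meth_diff[match(sites, r$site)]
    ifelse(md > 0, "hyper", ifelse(md < 0, "hypo", "flat"))
  })
  dirs <- matrix(dirs, nrow = length(sites),
                 dimnames = list(NULL, names(results)))
  consistent <- apply(dirs, 1, function(d) length(unique(d)) == 1)
  out <- data.frame(site = sites, dirs, consistent = consistent)
  names(out)[2:(1 + length(results))] <- paste0("dir_", names(results))
  attr(out, "fraction_consistent") <-
    if (length(sites)) mean(consistent) else NA_real_
  out
}

#' Paired F1/F4 effect sizes for transgenerational DMPs
#'
#' @param res_f1,res_f4 `dm_result`s for F1 and F4.
#' @param center Character vector of transgenerational site keys.
#' @return data.frame (site, meth_diff_F1, meth_diff_F4) with attributes
#'   `correlation` (Pearson) and `mean_abs_change`.
#' @export
effect_size_pairs <- function(res_f1, res_f4, center) {
  d1 <- res_f1$meth_diff[match(center, res_f1$site)]
  d4 <- res_f4$meth_diff[match(center, res_f4$site)]
  out <- data.frame(site = center, meth_diff_F1 = d1, meth_diff_F4 = d4)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "correlation") <- if (nrow(out) >= 3 &&
                                  stats::sd(out$meth_diff_F1) > 0 &&
                                  stats::sd(out$meth_diff_F4) > 0)
    stats::cor(out$meth_diff_F1, out$meth_diff_F4) else NA_real_
  attr(out, "mean_abs_change") <- if (nrow(out))
    mean(abs(out$meth_diff_F4 - out$meth_diff_F1)) else NA_real_
  out
}

#' Alternative two-stage transgenerational calling
#'
#' Stage 1 screens for candidates in F1 with a lenient FDR using only the
#' F1 controls (3 cases vs 3 controls); stage 2 retests the candidates
#' within F2 and within F4 (3 vs 3) and keeps sites with unadjusted
#' p <= `p2` in both and the same direction as in F1. This avoids reusing
#' one control pool across the three tests.
#'
#' @param mat A [meth_matrix()].
#' @param design A [comparison_design()].
#' @param fdr1 Stage-1 q-value cutoff (lenient, default 20% FDR).
#' @param p2 Stage-2 unadjusted p-value cutoff.
#' @param method `"wald"` (default) or `"logistic"`.
#' @param min_total,sd_min,d0 As in [run_generation_tests()].
#' @return A `dmp_set` of confirmed transgenerational sites (directions from
#'   F1), with stage bookkeeping in attribute `stages`.
#' @export
alternative_two_stage <- function(mat, design, fdr1 = 0.20, p2 = 0.05,
                                  method = c("wald", "logistic"),
                                  min_total = 5, sd_min = 0.5, d0 = 20) {
  method <- match.arg(method)
  gens <- design$generations
  ctrl <- design$controls_by_generation
  test33 <- function(m, g) {
    samples <- c(design$cases[[g]], ctrl[[g]])
    mg <- filter_variability(m, samples, sd_min = sd_min)
    if (method == "wald")
      betabinom_wald_test(mg, design$cases[[g]], ctrl[[g]], d0 = d0)
    else
      logistic_regression_test(mg, design$cases[[g]], ctrl[[g]])
  }
  mm <- filter_min_coverage(mat, design, min_total = min_total)
  if (nrow(mm$sites) > 0)
    mm <- normalize_median_coverage(mm, design_samples(design))
  r1 <- test33(mm, gens[1])
  cand <- r1[r1$qvalue <= fdr1 & r1$meth_diff != 0, ]
  if (nrow(cand) == 0) {
    out <- data.frame(site = character(), direction = character(),
                      meth_diff = numeric(), qvalue = numeric())
    class(out) <- c("dmp_set", "data.frame")
    attr(out, "stages") <- list(stage1 = 0L, stage2 = c(0L, 0L))
    return(out)
  }
  keep <- rep(TRUE, nrow(cand))
  stage2_n <- integer(0)
  for (g in gens[-1]) {
    rg <- test33(mm, g)
    m <- match(cand$site, rg$site)
    ok <- !is.na(m) & rg$pvalue[m] <= p2 &
      sign(rg$meth_diff[m]) == sign(cand$meth_diff)
    keep <- keep & ok
    stage2_n <- c(stage2_n, sum(ok))
  }
  out <- data.frame(site = cand$site[keep],
                    direction = ifelse(cand$meth_diff[keep] > 0, "hyper", "hypo"),
                    meth_diff = cand$meth_diff[keep],
                    qvalue = cand$qvalue[keep])
  rownames(out) <- NULL
  class(out) <- c("dmp_set", "data.frame")
  attr(out, "stages") <- list(stage1 = nrow(cand), stage2 = stage2_n)
  out
}

#' Concordance between the primary and alternative strategies
#'
#' @param primary,alternative `dmp_set`s or site-key vectors over the same
#'   universe.
#' @return Percentage `100 * |primary cap alternative| / |primary|`; 0 with a
#'   warning when the primary set is empty.
#' @export
strategy_concordance <- function(primary, alternative) {
  p <- unique(.set_sites(primary)); a <- unique(.set_sites(alternative))
  if (length(p) == 0) {
    warning("primary DMP set is empty; concordance undefined, returning 0")
    return(0)
  }
  100 * length(intersect(p, a)) / length(p)
}

#' Cross-stressor overlap of transgenerational DMP sets
#'
#' @param sets Named list (>= 2) of `dmp_set`s or site-key vectors.
#' @return List with `pairwise` (data.frame of all pairs and intersection
#'   sizes) and `higher_order` (k-way intersection sizes for k = 3..K).
#' @export
cross_stressor_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two stressor sets")
  keys <- lapply(sets, .set_sites)
  nms <- names(keys)
  pairs <- utils::combn(nms, 2)
  pairwise <- data.frame(
    stressor1 = pairs[1, ], stressor2 = pairs[2, ],
    overlap = apply(pairs, 2, function(p)
      length(intersect(keys[[p[1]]], keys[[p[2]]]))))
  higher <- list()
  for (k in seq_len(length(keys))[-(1:2)]) {
    combs <- utils::combn(nms, k, simplify = FALSE)
    higher[[paste0(k, "way")]] <- data.frame(
      sets = vapply(combs, paste, "", collapse = "+"),
      overlap = vapply(combs, function(cc)
        length(Reduce(intersect, keys[cc])), 1L))
  }
  list(pairwise = pairwise, higher_order = higher)
}
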