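## The two permutation machines: whole-analysis sample-label shuffling and
## CpG-set overlap significance by resampling from the tested universe.

#' Permute case/control and generation labels
#'
#' Uniformly reassigns the (case/control, generation) cell labels over the
#' samples of one comparison while preserving the design shape (default 3
#' case samples per generation and 3 controls per generation), so every
#' permuted analysis is well-defined. The permuted control pool again pools
#' all permuted controls across generations.
#'
#' @param design A [comparison_design()].
#' @return A permuted `comparison_design` of identical shape.
#' @export
permute_labels <- function(design) {
  ids <- c(unlist(design$cases, use.names = FALSE),
           unlist(design$controls_by_generation, use.names = FALSE))
  shuffled <- sample(ids)
  sizes_case <- vapply(design$cases, length, 1L)
  sizes_ctrl <- vapply(design$controls_by_generation, length, 1L)
  at <- 0L
  cases <- list(); ctrls <- list()
  for (g in design$generations) {
    cases[[g]] <- shuffled[at + seq_len(sizes_case[[g]])]
    at <- at + sizes_case[[g]]
  }
  for (g in design$generations) {
    ctrls[[g]] <- shuffled[at + seq_len(sizes_ctrl[[g]])]
    at <- at + sizes_ctrl[[g]]
  }
  out <- design
  out$cases <- cases
  out$controls_by_generation <- ctrls
  out$control_pool <- unlist(ctrls, use.names = FALSE)
  out
}

#' Label-permutation null for the full analysis
#'
#' Repeats the complete per-generation 3-vs-9 analysis (filters, dispersion
#' shrinkage, Wald or logistic test, BH, DMP calling, three-generation
#' intersection) under `n_perm` random relabelings, collecting the pooled
#' null p-value distribution (for Q-Q comparison with the observed run) and
#' the number of transgenerational DMPs per permutation.
#'
#' @param mat A [meth_matrix()].
#' @param design A [comparison_design()].
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @param ... Passed to [run_generation_tests()].
#' @return List: `null_pvalues` (list of pooled p-value vectors, one per
#'   permutation), `n_transgen` (integer per permutation), `failed`
#'   (indices of failed permutations).
#' @export
permutation_null_run <- function(mat, design, n_perm = 100, seed = 1, ...) {
  set.seed(seed)
  null_p <- vector("list", n_perm)
  n_tg <- integer(n_perm)
  failed <- integer(0)
  for (b in seq_len(n_perm)) {
    pd <- permute_labels(design)
    res <- tryCatch(run_generation_tests(mat, pd, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, b)
      n_tg[b] <- NA_integer_
      next
    }
    null_p[[b]] <- unlist(lapply(res$results, `[[`, "pvalue"),
                          use.names = FALSE)
    part <- intersect_generations(res$dmps[[1]], res$dmps[[2]], res$dmps[[3]])
    n_tg[b] <- length(part$center)
  }
  list(null_pvalues = null_p, n_transgen = n_tg, failed = failed)
}

#' Overlap permutation test for k DMP sets
#'
#' Significance of the k-way intersection of the observed per-generation DMP
#' sets, against draws of equal-sized site sets sampled uniformly without
#' replacement from the universe of tested CpGs. The p-value uses the
#' add-one rule `p = (1 + #{null >= observed}) / (1 + n_perm)`, so it is
#' never exactly zero.
#'
#' @param sets List of observed site-key sets (or `dmp_set`s), each a subset
#'   of `universe`.
#' @param universe Character vector of all tested CpG site keys.
#' @param n_perm Number of resampling draws.
#' @param seed Integer seed.
#' @return List: `observed` intersection size, `null` vector of null
#'   intersection sizes, `p_value`, `null_mean`, `null_sd`.
#' @export
overlap_permutation_test <- function(sets, universe, n_perm = 1000, seed = 1) {
  keys <- lapply(sets, .set_sites)
  universe <- unique(as.character(universe))
  for (k in keys) if (length(setdiff(k, universe)))
    stop("observed set contains sites outside the tested universe")
  sizes <- vapply(keys, length, 1L)
  if (any(sizes > length(universe)))
    stop("observed set larger than the universe")
  observed <- length(Reduce(intersect, keys))
  set.seed(seed)
  null <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    draw <- lapply(sizes, function(s) sample(universe, s))
    null[b] <- length(Reduce(intersect, draw))
  }
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       null_mean = mean(null), null_sd = stats::sd(null))
}

#' Pairwise cross-stressor overlap significance
#'
#' Applies the overlap resampling machinery to every pair of
#' transgenerational DMP sets.
#'
#' @param sets Named list of per-stressor site-key sets (or `dmp_set`s).
#' @param universe Tested-CpG site keys.
#' @param n_perm,seed As in [overlap_permutation_test()].
#' @return data.frame: stressor1, stressor2, observed overlap, null mean,
#'   p_value.
#' @export
cross_stressor_overlap_test <- function(sets, universe, n_perm = 1000, seed = 1) {
  if (length(sets) < 2) stop("need at least two stressor sets")
  nms <- names(sets)
  pairs <- utils::combn(nms, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- overlap_permutation_test(sets[c(a, b)], universe, n_perm = n_perm,
                                  seed = seed + i)
    data.frame(stressor1 = a, stressor2 = b, observed = r$observed,
               null_mean = r$null_mean, p_value = r$p_value)
  })
  do.call(rbind, rows)
}
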