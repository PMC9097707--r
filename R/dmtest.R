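## Beta-binomial Wald testing with empirical-Bayes dispersion shrinkage,
## the logistic-regression alternative, and BH-based DMP calling.

#' Method-of-moments beta-binomial dispersion estimates
#'
#' Per site, the overdispersion phi of the beta-binomial model
#' `Var(k) = n p (1-p) (1 + (n-1) phi)` is estimated from the Pearson
#' residual sum over both groups around the group-pooled proportions,
#' with a degrees-of-freedom correction for the estimated group means:
#' `phi = (X * N/(N-G) - N) / sum(n_i - 1)` where `X` is the Pearson sum,
#' `N` the number of informative observations and `G` the number of groups
#' contributing. Estimates are clamped to `[1e-6, 0.99]`.
#'
#' @param meth,total Count matrices (sites x samples).
#' @param case,control Column indices of the two groups.
#' @return data.frame: `phi_raw` (NA where inestimable), `df` (residual
#'   degrees of freedom), `p_pool` (all-sample pooled proportion).
#' @export
estimate_dispersion <- function(meth, total, case, control) {
  groups <- list(case, control)
  nr <- nrow(meth)
  X <- numeric(nr); Nv <- integer(nr); G <- integer(nr); den <- numeric(nr)
  for (g in groups) {
    if (length(g) == 0) next
    k <- meth[, g, drop = FALSE]; n <- total[, g, drop = FALSE]
    p <- rowSums(k) / pmax(rowSums(n), 1)
    ok <- n > 0 & p > 0 & p < 1
    r <- (k - n * p)^2 / (n * p * (1 - p))
    r[!ok] <- 0
    X <- X + rowSums(r)
    cnt <- rowSums(ok)
    Nv <- Nv + cnt
    G <- G + as.integer(cnt > 0)
    nm1 <- (n - 1) * ok
    den <- den + rowSums(nm1)
  }
  df <- pmax(Nv - G, 0L)
  phi <- rep(NA_real_, nr)
  est <- df > 0 & den > 0
  phi[est] <- (X[est] * Nv[est] / df[est] - Nv[est]) / den[est]
  phi[est] <- pmin(pmax(phi[est], 1e-6), 0.99)
  all_idx <- c(case, control)
  p_pool <- rowSums(meth[, all_idx, drop = FALSE]) /
    pmax(rowSums(total[, all_idx, drop = FALSE]), 1)
  data.frame(phi_raw = phi, df = df, p_pool = p_pool)
}

#' Empirical-Bayes shrinkage of dispersion estimates
#'
#' Fits a log-normal prior to the raw log-dispersions of
#' dispersion-identifiable sites (pooled methylation within
#' `informative_range`, raw estimate available) and pulls every site's
#' estimate toward the prior mean: `phi* = exp(w log phi + (1-w) mu0)` with
#' `w = d/(d + d0)`. Sites without a raw estimate receive the prior mean.
#' With fewer than 50 informative sites a fixed fallback prior
#' `mu0 = log(0.01)` is used (with a warning).
#'
#' Shrinkage is robust to dispersion outliers: sites whose raw
#' log-dispersion lies more than `outlier_z` spread units above the prior
#' mean keep their raw estimate. Without this guard, a site with genuinely
#' extreme between-replicate variability (e.g. group labels cutting across
#' a bimodal methylation pattern, as happens under label permutation) would
#' have its variance understated by an order of magnitude and produce
#' spuriously small p-values.
#'
#' @param disp data.frame from [estimate_dispersion()].
#' @param d0 Prior strength in residual-df units.
#' @param informative_range Pooled-proportion window in which dispersion is
#'   considered identifiable.
#' @param outlier_z Number of log-scale spread units above the prior mean
#'   beyond which a raw estimate is left unshrunk.
#' @return Numeric vector `phi_star`; prior parameters in attributes
#'   `mu0`, `tau0`.
#' @export
shrink_dispersion <- function(disp, d0 = 20, informative_range = c(0.05, 0.95),
                              outlier_z = 2) {
  inform <- !is.na(disp$phi_raw) &
    disp$p_pool >= informative_range[1] & disp$p_pool <= informative_range[2]
  if (sum(inform) >= 50) {
    ## moment-matched prior mean: raw log-dispersions are noisy and
    ## right-skewed, so the mean of logs underestimates the typical phi and
    ## makes the Wald test anti-conservative
    mu0 <- log(mean(disp$phi_raw[inform]))
    tau0 <- stats::var(log(disp$phi_raw[inform]))
  } else {
    warning("fewer than 50 informative sites for the dispersion prior; ",
            "using fixed prior mu0 = log(0.01)")
    mu0 <- log(0.01); tau0 <- NA_real_
  }
  w <- disp$df / (disp$df + d0)
  spread <- if (!is.na(tau0) && tau0 > 0) sqrt(tau0) else 1
  lph_all <- log(disp$phi_raw)
  w[!is.na(lph_all) & lph_all > mu0 + outlier_z * spread] <- 1
  phi_star <- ifelse(is.na(disp$phi_raw), exp(mu0),
                     exp(w * log(disp$phi_raw) + (1 - w) * mu0))
  phi_star <- pmin(pmax(phi_star, 1e-6), 0.99)
  attr(phi_star, "mu0") <- mu0
  attr(phi_star, "tau0") <- tau0
  phi_star
}

#' Beta-binomial Wald test
#'
#' Group proportions are read-pooled within group,
#' `p_g = sum(meth) / sum(total)`, with variance
#' `Var(p_g) = sum_i n_i p_g (1-p_g) (1 + (n_i - 1) phi*) / (sum_i n_i)^2`.
#' The Wald statistic `z = (p1 - p0) / sqrt(Var1 + Var0)` gets a two-sided
#' normal p-value; sites where both groups are degenerate at 0 or 1
#' (`Var1 + Var0 = 0`) are assigned `z = 0, p = 1` so downstream set algebra
#' stays total. Sites where a group has zero total reads are dropped and
#' recorded in the `skipped` attribute.
#'
#' @param mat A (filtered) [meth_matrix()].
#' @param case,control Sample ids of the two groups.
#' @param phi_star Per-site shrunk dispersions (recycled if length 1); if
#'   `NULL`, estimated and shrunk internally with defaults.
#' @param d0 Prior strength passed to [shrink_dispersion()] when `phi_star`
#'   is `NULL`.
#' @return A `dm_result` data.frame: site, chrom, pos, p_case, p_control,
#'   meth_diff (percentage points), phi_star, z, pvalue, qvalue (BH within
#'   this test).
#' @export
betabinom_wald_test <- function(mat, case, control, phi_star = NULL, d0 = 20) {
  ci <- match(case, mat$samples); oi <- match(control, mat$samples)
  if (anyNA(ci) || anyNA(oi)) stop("unknown sample id in test groups")
  if (length(ci) == 0 || length(oi) == 0) stop("empty test group")
  if (is.null(phi_star)) {
    disp <- estimate_dispersion(mat$meth, mat$total, ci, oi)
    phi_star <- shrink_dispersion(disp, d0 = d0)
  }
  phi_star <- rep_len(phi_star, nrow(mat$sites))
  n1 <- mat$total[, ci, drop = FALSE]; k1 <- mat$meth[, ci, drop = FALSE]
  n0 <- mat$total[, oi, drop = FALSE]; k0 <- mat$meth[, oi, drop = FALSE]
  N1 <- rowSums(n1); N0 <- rowSums(n0)
  skipped <- N1 == 0 | N0 == 0
  p1 <- rowSums(k1) / pmax(N1, 1); p0 <- rowSums(k0) / pmax(N0, 1)
  v1 <- rowSums(n1 * (1 + (n1 - 1) * phi_star)) * p1 * (1 - p1) / pmax(N1, 1)^2
  v0 <- rowSums(n0 * (1 + (n0 - 1) * phi_star)) * p0 * (1 - p0) / pmax(N0, 1)^2
  v <- v1 + v0
  z <- ifelse(v > 0, (p1 - p0) / sqrt(v), 0)
  p <- ifelse(v > 0, 2 * stats::pnorm(-abs(z)), 1)
  res <- data.frame(site = mat$key, chrom = mat$sites$chrom, pos = mat$sites$pos,
                    p_case = p1, p_control = p0, meth_diff = 100 * (p1 - p0),
                    phi_star = as.numeric(phi_star), z = z, pvalue = p)
  res <- res[!skipped, , drop = FALSE]
  rownames(res) <- NULL
  res$qvalue <- adjust_bh(res$pvalue)
  attr(res, "skipped") <- mat$key[skipped]
  class(res) <- c("dm_result", "data.frame")
  res
}

## penalized IRLS for a per-site binomial GLM on a group indicator;
## the ridge on the slope regularizes complete separation.
.logistic_site <- function(k, n, g, ridge = 1e-6, max_iter = 50) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; g <- g[keep]
  if (length(k) == 0 || all(g == g[1])) return(c(NA, NA))
  beta <- c(0, 0)
  X <- cbind(1, g)
  P <- diag(c(0, ridge))
  for (it in seq_len(max_iter)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    W <- n * mu * (1 - mu)
    grad <- crossprod(X, k - n * mu) - P %*% beta
    H <- crossprod(X, X * as.numeric(W)) + P
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(c(NA, NA))
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  if (max(abs(step)) > 1e-6 || any(!is.finite(beta))) return(c(NA, NA))
  mu <- as.numeric(1 / (1 + exp(-X %*% beta)))
  ll <- function(m) sum(k * log(pmax(m, 1e-12)) +
                          (n - k) * log(pmax(1 - m, 1e-12)))
  p0 <- sum(k) / sum(n)
  lrt <- 2 * (ll(mu) - ll(rep(p0, length(k))))
  c(max(lrt, 0), beta[2])
}

#' Per-site logistic-regression test
#'
#' Binomial regression of methylated/total on a case/control indicator with
#' a likelihood-ratio p-value against the intercept-only model.
#' Complete separation is regularized by a ridge penalty on the group
#' coefficient. Non-converging sites get `pvalue = NA` and are listed in the
#' `failed` attribute.
#'
#' @inheritParams betabinom_wald_test
#' @param ridge Ridge penalty on the group coefficient.
#' @return A `dm_result` data.frame (columns as for
#'   [betabinom_wald_test()], with `lrt` in place of `z`).
#' @export
logistic_regression_test <- function(mat, case, control, ridge = 1e-6) {
  ci <- match(case, mat$samples); oi <- match(control, mat$samples)
  if (anyNA(ci) || anyNA(oi)) stop("unknown sample id in test groups")
  idx <- c(ci, oi)
  g <- rep(c(1, 0), c(length(ci), length(oi)))
  nr <- nrow(mat$sites)
  lrt <- numeric(nr)
  for (i in seq_len(nr)) {
    out <- .logistic_site(mat$meth[i, idx], mat$total[i, idx], g, ridge)
    lrt[i] <- out[1]
  }
  p1 <- rowSums(mat$meth[, ci, drop = FALSE]) /
    pmax(rowSums(mat$total[, ci, drop = FALSE]), 1)
  p0 <- rowSums(mat$meth[, oi, drop = FALSE]) /
    pmax(rowSums(mat$total[, oi, drop = FALSE]), 1)
  p <- ifelse(is.na(lrt), NA, stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  res <- data.frame(site = mat$key, chrom = mat$sites$chrom, pos = mat$sites$pos,
                    p_case = p1, p_control = p0, meth_diff = 100 * (p1 - p0),
                    lrt = lrt, pvalue = p)
  failed <- res$site[is.na(p)]
  res <- res[!is.na(p), , drop = FALSE]
  rownames(res) <- NULL
  res$qvalue <- adjust_bh(res$pvalue)
  attr(res, "failed") <- failed
  class(res) <- c("dm_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values (via [stats::p.adjust()]); adjustment is always per
#' test (per generation, per stressor), never pooled across tests.
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values, same length.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated positions
#'
#' @param dmres A `dm_result`.
#' @param fdr q-value cutoff.
#' @param generation Optional generation label attached to the set.
#' @return A `dmp_set` data.frame: site, direction ("hyper"/"hypo"),
#'   meth_diff, qvalue.
#' @export
call_dmps <- function(dmres, fdr = 0.05, generation = NULL) {
  sel <- dmres$qvalue <= fdr & dmres$meth_diff != 0
  out <- data.frame(site = dmres$site[sel],
                    direction = ifelse(dmres$meth_diff[sel] > 0, "hyper", "hypo"),
                    meth_diff = dmres$meth_diff[sel],
                    qvalue = dmres$qvalue[sel])
  if (!is.null(generation)) out$generation <- rep(generation, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("dmp_set", "data.frame")
  out
}

#' Run the per-generation differential methylation analysis
#'
#' The full test path for one stressor: minimum-coverage filter over all
#' comparison samples, median-coverage normalization, then per generation a
#' variability filter and the 3-vs-9 test (cases of that generation against
#' the pooled control samples), BH-adjusted within each generation.
#'
#' @param mat A [meth_matrix()] containing all design samples.
#' @param design A [comparison_design()].
#' @param min_total,sd_min Filter thresholds.
#' @param normalize Apply median-coverage normalization.
#' @param fdr q-value cutoff for DMP calling.
#' @param method `"wald"` or `"logistic"`.
#' @param d0 Dispersion prior strength (Wald method).
#' @return List with `results` (per-generation `dm_result`), `dmps`
#'   (per-generation `dmp_set`), `tested` (per-generation site keys) and
#'   `universe` (sites tested in every generation).
#' @export
run_generation_tests <- function(mat, design, min_total = 5, sd_min = 0.5,
                                 normalize = TRUE, fdr = 0.05,
                                 method = c("wald", "logistic"), d0 = 20) {
  method <- match.arg(method)
  mm <- filter_min_coverage(mat, design, min_total = min_total)
  if (normalize && nrow(mm$sites) > 0)
    mm <- normalize_median_coverage(mm, design_samples(design))
  results <- list(); dmps <- list(); tested <- list()
  for (g in design$generations) {
    case <- design$cases[[g]]
    comp_samples <- c(case, design$control_pool)
    mg <- if (nrow(mm$sites) > 0)
      filter_variability(mm, comp_samples, sd_min = sd_min) else mm
    res <- if (method == "wald")
      betabinom_wald_test(mg, case, design$control_pool, d0 = d0)
    else
      logistic_regression_test(mg, case, design$control_pool)
    results[[g]] <- res
    dmps[[g]] <- call_dmps(res, fdr = fdr, generation = g)
    tested[[g]] <- res$site
  }
  list(results = results, dmps = dmps, tested = tested,
       universe = Reduce(intersect, tested))
}
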