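test_that("dispersion estimation recovers the no-overdispersion limit and fixed points", {
  set.seed(31)
  # binomial data (phi = 0): median raw estimate sits at the lower clamp,
  # shrunk values are pulled towards the prior
  n <- matrix(rpois(2000 * 12, 30), 2000, 12)
  m <- rbeta(2000, 8, 2)
  k <- matrix(rbinom(length(n), n, rep(m, 12)), 2000, 12)
  disp <- estimate_dispersion(k, n, 1:3, 4:12)
  expect_identical(median(disp$phi_raw, na.rm = TRUE), 1e-6)
  ps <- shrink_dispersion(disp)
  mu0 <- attr(ps, "mu0")
  expect_true(all(abs(log(ps) - mu0) <= abs(log(pmax(disp$phi_raw, 1e-6)) - mu0) + 1e-9,
                  na.rm = TRUE))

  # all sites sharing one raw phi: the prior mean equals the shared value,
  # so shrinkage is a fixed point for any prior strength
  d2 <- data.frame(phi_raw = rep(0.07, 100), df = 10, p_pool = 0.5)
  for (d0 in c(1, 20, 500))
    expect_equal(unname(as.numeric(shrink_dispersion(d2, d0 = d0))),
                 rep(0.07, 100), tolerance = 1e-12)
})

test_that("dispersion recovery: phi = 0.1, six samples, coverage 20", {
  set.seed(32)
  n <- matrix(rpois(5000 * 6, 20), 5000, 6)
  m <- rep(0.5, 5000)
  k <- matrix(0L, 5000, 6)
  for (j in 1:6) k[, j] <- rbetabinom(n[, j], m, 0.1)
  disp <- estimate_dispersion(k, n, 1:6, integer(0))
  ps <- shrink_dispersion(disp)
  expect_gt(mean(ps), 0.05)
  expect_lt(mean(ps), 0.2)
})

test_that("Wald test matches the two-proportion z closed form at phi = 0", {
  # identical counts in both groups: diff 0, p = 1
  mat0 <- toy_matrix(matrix(3L, 5, 6), matrix(10L, 5, 6))
  r0 <- betabinom_wald_test(mat0, paste0("s", 1:3), paste0("s", 4:6),
                            phi_star = 0)
  expect_equal(r0$meth_diff, rep(0, 5))
  expect_equal(r0$pvalue, rep(1, 5))

  # pooled 30/100 vs 10/100 against the closed-form two-proportion statistic
  mat <- toy_matrix(cbind(c(15L), c(15L), c(4L), c(6L)),
                    cbind(c(50L), c(50L), c(40L), c(60L)))
  r <- betabinom_wald_test(mat, c("s1", "s2"), c("s3", "s4"), phi_star = 0)
  p1 <- 0.3; p0 <- 0.1
  z_oracle <- (p1 - p0) / sqrt(p1 * (1 - p1) / 100 + p0 * (1 - p0) / 100)
  expect_equal(r$z, z_oracle, tolerance = 1e-10)
  expect_equal(r$pvalue, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-10)

  # degenerate variance (both groups all-zero) gives z = 0, p = 1
  matd <- toy_matrix(matrix(0L, 2, 4), matrix(8L, 2, 4))
  rd <- betabinom_wald_test(matd, c("s1", "s2"), c("s3", "s4"), phi_star = 0.1)
  expect_equal(rd$z, c(0, 0))
  expect_equal(rd$pvalue, c(1, 1))

  # a group with zero total coverage is skipped and recorded
  nz <- matrix(10L, 2, 4); nz[2, 1:2] <- 0L
  rz <- betabinom_wald_test(toy_matrix(matrix(0L, 2, 4), nz),
                            c("s1", "s2"), c("s3", "s4"), phi_star = 0)
  expect_identical(nrow(rz), 1L)
  expect_identical(attr(rz, "skipped"), "chr1:2")
})

test_that("a 40-point effect at coverage 10 in 3v9 is detected reliably", {
  set.seed(33)
  hits <- vapply(1:200, function(i) {
    n <- pmax(matrix(rpois(12, 10), 1, 12), 1L)
    k <- matrix(rbinom(12, n, rep(c(0.6, 0.2), c(3, 9))), 1, 12)
    mat <- toy_matrix(k, n)
    r <- betabinom_wald_test(mat, paste0("s", 1:3), paste0("s", 4:12),
                             phi_star = 0)
    r$pvalue < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("logistic LRT matches a direct two-binomial likelihood computation", {
  mat0 <- toy_matrix(matrix(4L, 3, 4), matrix(9L, 3, 4))
  r0 <- logistic_regression_test(mat0, c("s1", "s2"), c("s3", "s4"))
  expect_equal(r0$lrt, rep(0, 3), tolerance = 1e-8)
  expect_equal(r0$pvalue, rep(1, 3), tolerance = 1e-8)

  mat <- toy_matrix(cbind(30L, 10L), cbind(100L, 100L))
  r <- logistic_regression_test(mat, "s1", "s2")
  ll <- function(k, n, p) k * log(p) + (n - k) * log(1 - p)
  lrt_oracle <- 2 * (ll(30, 100, 0.3) + ll(10, 100, 0.1) -
                       ll(30, 100, 0.2) - ll(10, 100, 0.2))
  expect_equal(r$lrt, lrt_oracle, tolerance = 1e-6)
  expect_equal(r$pvalue, pchisq(lrt_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("Wald and logistic p-values are rank-concordant on simulated data", {
  # a methylation-rich simulation so that the tested universe carries real
  # signal structure rather than pure noise ranks
  cfg <- sim_config(n_cpgs = 3000, n_genes = 40,
                    baseline_methylated_fraction = 0.12, coverage_mean = 12,
                    stressors = list(microcystin = list(
                      n_planted_dmps = 150L, effect_size = 40,
                      hyper_fraction = 0.5, persistence_prob = 1,
                      experiment = "T1")),
                    master_seed = 13L)
  sim <- simulate_experiment(cfg)
  d <- comparison_design(sim$sheet, "microcystin")
  gw <- suppressWarnings(run_generation_tests(sim$matrix, d, method = "wald"))
  gl <- suppressWarnings(run_generation_tests(sim$matrix, d, method = "logistic"))
  rw <- gw$results$F1; rl <- gl$results$F1
  common <- intersect(rw$site, rl$site)
  rho <- cor(rw$pvalue[match(common, rw$site)],
             rl$pvalue[match(common, rl$site)], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("BH adjustment equals an independent step-up implementation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_identical(adjust_bh(numeric(0)), numeric(0))

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(34)
  p <- runif(1000)^1.5
  expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
})

test_that("DMP calling respects the cutoff and direction signs", {
  res <- data.frame(site = paste0("chr1:", 1:4),
                    meth_diff = c(10, -5, 3, 0),
                    qvalue = c(0.01, 0.04, 0.2, 0.001))
  dmps <- call_dmps(res, fdr = 0.05, generation = "F1")
  expect_identical(dmps$site, c("chr1:1", "chr1:2"))
  expect_identical(dmps$direction, c("hyper", "hypo"))
  expect_identical(unique(dmps$generation), "F1")
  expect_identical(nrow(call_dmps(res, fdr = 0)), 0L)
})

test_that("type-I error is near nominal for a well-replicated design", {
  # the Wald p-value is asymptotic, so calibration is checked in a
  # replication-rich regime (20 vs 20, deep coverage)
  set.seed(35)
  ns <- 40; nsite <- 3000
  n <- matrix(rpois(nsite * ns, 100), nsite, ns)
  m <- rbeta(nsite, 8, 2)
  k <- matrix(0L, nsite, ns)
  for (j in seq_len(ns)) k[, j] <- rbetabinom(n[, j], m, 0.1)
  mat <- toy_matrix(k, n)
  r <- betabinom_wald_test(mat, paste0("s", 1:20), paste0("s", 21:40))
  for (alpha in c(0.05, 0.01)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / nsite)
    expect_lt(abs(mean(r$pvalue < alpha) - alpha), tol + 1e-12)
  }
})

test_that("false-discovery proportion is controlled with planted signal", {
  # small-scale companion of the full-scale acceptance check
  set.seed(36)
  fdps <- vapply(1:3, function(i) {
    cfg <- small_config(n_cpgs = 6000, n_planted = 80L, persistence = 0.5,
                        seed = 100L + i)
    sim <- simulate_experiment(cfg)
    d <- comparison_design(sim$sheet, "microcystin")
    gt <- suppressWarnings(run_generation_tests(sim$matrix, d, fdr = 0.05))
    called <- unlist(lapply(gt$dmps, `[[`, "site"), use.names = FALSE)
    if (length(called)) mean(!called %in% sim$truth$site) else 0
  }, 0)
  mc_se <- sd(fdps) / sqrt(length(fdps))
  expect_lte(mean(fdps), 0.05 + 3 * mc_se)
})
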