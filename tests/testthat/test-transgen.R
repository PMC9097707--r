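test_that("Venn partition matches exhaustive membership enumeration", {
  # three identical sets
  s <- paste0("chr1:", 1:5)
  p <- intersect_generations(s, s, s)
  expect_identical(length(p$center), 5L)
  expect_identical(sum(p$counts), 5L)
  expect_true(all(p$counts[names(p$counts) != "center"] == 0))

  # pairwise disjoint sets
  p2 <- intersect_generations(paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:3))
  expect_identical(length(p2$center), 0L)
  expect_identical(p2$union_size, 9L)

  # random toy sets against a bitmask oracle
  set.seed(41)
  for (rep in 1:5) {
    univ <- paste0("chr1:", 1:40)
    s1 <- sample(univ, 15); s2 <- sample(univ, 12); s4 <- sample(univ, 18)
    p3 <- intersect_generations(s1, s2, s4)
    mask <- cbind(univ %in% s1, univ %in% s2, univ %in% s4)
    oracle <- table(factor(mask %*% c(1, 2, 4), levels = 0:7))
    expect_identical(unname(p3$counts["f1_only"]), as.integer(oracle["1"]))
    expect_identical(unname(p3$counts["f2_only"]), as.integer(oracle["2"]))
    expect_identical(unname(p3$counts["f1f2"]), as.integer(oracle["3"]))
    expect_identical(unname(p3$counts["f4_only"]), as.integer(oracle["4"]))
    expect_identical(unname(p3$counts["f1f4"]), as.integer(oracle["5"]))
    expect_identical(unname(p3$counts["f2f4"]), as.integer(oracle["6"]))
    expect_identical(unname(p3$counts["center"]), as.integer(oracle["7"]))
    # region sizes sum to the union
    expect_identical(sum(p3$counts), length(union(union(s1, s2), s4)))
    # order invariance of the center under permuted inputs
    p4 <- intersect_generations(s1, s4, s2)
    expect_setequal(p4$center, p3$center)
  }
})

test_that("persistence fraction reproduces the published worked examples", {
  mk <- function(n_f1, n_center) {
    center <- paste0("c", seq_len(n_center))
    extra <- if (n_f1 > n_center) paste0("x", seq_len(n_f1 - n_center))
    intersect_generations(c(center, extra), c(center, "y1"), c(center, "z1"))
  }
  expect_identical(persistence_fraction(mk(225, 130)), 57.8)
  expect_identical(persistence_fraction(mk(2231, 26)), 1.2)
  p <- mk(50, 50)
  expect_identical(persistence_fraction(p), 100)
  # scale-free: duplicating every site under fresh keys leaves it unchanged
  big <- intersect_generations(
    c(paste0("c", 1:130), paste0("x", 1:95), paste0("C", 1:130), paste0("X", 1:95)),
    c(paste0("c", 1:130), paste0("C", 1:130), "y1"),
    c(paste0("c", 1:130), paste0("C", 1:130), "z1"))
  expect_identical(persistence_fraction(big), 57.8)
})

test_that("sign consistency flags direction flips across generations", {
  res <- function(diffs) data.frame(site = names(diffs), meth_diff = diffs)
  results <- list(
    F1 = res(c(a = 10, b = 20, c = -5)),
    F2 = res(c(a = 12, b = -15, c = -8)),
    F4 = res(c(a = 9, b = 18, c = -4)))
  part <- intersect_generations(c("a", "b", "c"), c("a", "b", "c"),
                                c("a", "b", "c"))
  tab <- check_sign_consistency(part, results)
  expect_identical(tab$consistent[match(c("a", "b", "c"), tab$site)],
                   c(TRUE, FALSE, TRUE))
  expect_equal(attr(tab, "fraction_consistent"), 2 / 3)
})

test_that("effect-size pairing handles identity and empty cases", {
  r <- data.frame(site = c("a", "b", "c"), meth_diff = c(10, -20, 35))
  pairs <- effect_size_pairs(r, r, c("a", "b", "c"))
  expect_equal(attr(pairs, "correlation"), 1)
  expect_equal(pairs$meth_diff_F1, pairs$meth_diff_F4)
  empty <- effect_size_pairs(r, r, character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("strategy concordance is plain overlap arithmetic", {
  expect_equal(strategy_concordance(c("a", "b"), c("a", "b")), 100)
  expect_equal(strategy_concordance(c("a", "b"), c("c", "d")), 0)
  expect_equal(strategy_concordance(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 75)
  expect_warning(z <- strategy_concordance(character(0), "a"), "empty")
  expect_equal(z, 0)
})

test_that("cross-stressor overlap tables match exhaustive enumeration", {
  sets <- list(A = paste0("s", 1:5), B = paste0("s", 3:8), C = paste0("s", 10:12))
  ov <- cross_stressor_overlap(sets)
  expect_identical(ov$pairwise$overlap[ov$pairwise$stressor1 == "A" &
                                         ov$pairwise$stressor2 == "B"], 3L)
  expect_identical(ov$pairwise$overlap[ov$pairwise$stressor2 == "C"], c(0L, 0L))
  expect_identical(ov$higher_order[["3way"]]$overlap, 0L)
  # identical sets: pairwise overlap = set size; disjoint: zero
  ov2 <- cross_stressor_overlap(list(A = paste0("s", 1:4), B = paste0("s", 1:4)))
  expect_identical(ov2$pairwise$overlap, 4L)
})

test_that("the two-stage strategy confirms planted transgenerational DMPs", {
  cfg <- small_config(n_cpgs = 4000, n_planted = 50L, persistence = 1,
                      seed = 19L)
  sim <- simulate_experiment(cfg)
  d <- comparison_design(sim$sheet, "microcystin")

  alt <- suppressWarnings(alternative_two_stage(sim$matrix, d))
  gt <- suppressWarnings(run_generation_tests(sim$matrix, d))
  part <- intersect_generations(gt$dmps$F1, gt$dmps$F2, gt$dmps$F4)
  # substantial overlap with the primary strategy on strong planted signal
  if (length(part$center) > 0) {
    conc <- strategy_concordance(part$center, alt$site)
    expect_gte(conc, 25)
  }
  # confirmed sites are predominantly planted truth
  if (nrow(alt) > 0)
    expect_gte(mean(alt$site %in% sim$truth$site), 0.8)

  # boundary: fully permissive thresholds return every stage-1 site whose
  # sign persists through both later generations
  alt_all <- suppressWarnings(alternative_two_stage(sim$matrix, d, fdr1 = 1, p2 = 1))
  expect_gte(nrow(alt_all), nrow(alt))
  # no candidates at an impossible stage-1 threshold
  alt_none <- suppressWarnings(alternative_two_stage(sim$matrix, d, fdr1 = 0))
  expect_identical(nrow(alt_none), 0L)
})
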