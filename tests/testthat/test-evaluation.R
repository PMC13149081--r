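# Metrics and patient-level statistics against independent oracles.

test_that("dice/iou/accuracy follow the set formulas", {
  a <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3) > 0
  b <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3) > 0
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 2 * 2 / (3 + 3))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(iou(a, b), 2 / 4)
  expect_equal(dice(a & FALSE, b & FALSE), 1)  # both-empty convention
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shape")

  # random small masks: dice/iou vs direct-formula enumeration; iou <= dice
  set.seed(7)
  for (i in 1:25) {
    x <- matrix(runif(30) > 0.5, 5, 6)
    y <- matrix(runif(30) > 0.5, 5, 6)
    inter <- sum(x & y)
    expect_equal(dice(x, y),
                 if (sum(x) + sum(y) == 0) 1 else 2 * inter / (sum(x) + sum(y)))
    expect_equal(iou(x, y),
                 if (sum(x | y) == 0) 1 else inter / sum(x | y))
    expect_lte(iou(x, y), dice(x, y) + 1e-12)
  }
})

test_that("AUC equals the normalized Mann-Whitney count with half ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "classes")
  set.seed(8)
  for (i in 1:20) {
    s <- round(runif(12), 1)  # forces ties
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(auc(s, y), mean(pairs))
    expect_equal(auc(s, y) + auc(-s, y), 1)
  }
})

test_that("stratified bootstrap CI is seeded, degenerate-safe, and calibrated", {
  expect_equal(unname(bootstrap_ci(rep(0.7, 10), B = 100, seed = 2)),
               c(0.7, 0.7, 0.7))
  v <- rnorm(50, 10, 2)
  ci1 <- bootstrap_ci(v, B = 500, seed = 5)
  ci2 <- bootstrap_ci(v, B = 500, seed = 5)
  expect_identical(ci1, ci2)
  # agreement with the normal-theory interval for the mean
  nt <- mean(v) + c(-1.96, 1.96) * sd(v) / sqrt(50)
  expect_lt(abs(ci1[["low"]] - nt[1]), 0.5)
  expect_lt(abs(ci1[["high"]] - nt[2]), 0.5)
  # stratified resampling keeps strata
  strat <- rep(c("a", "b"), each = 25)
  ci3 <- bootstrap_ci(v, strata = strat, B = 200, seed = 1)
  expect_lt(ci3[["low"]], ci3[["high"]])
  expect_error(bootstrap_ci(v, strata = c("a", rep("b", 49)), B = 10),
               "stratum")

  # coverage of the 95% interval for a Gaussian mean (Monte-Carlo check)
  set.seed(11)
  cover <- mean(vapply(1:400, function(i) {
    x <- rnorm(30)
    ci <- bootstrap_ci(x, B = 300, seed = i)
    ci[["low"]] <= 0 && 0 <= ci[["high"]]
  }, logical(1)))
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.985)
})

test_that("paired Wilcoxon: exact DP equals full sign-flip enumeration", {
  r <- paired_wilcoxon(1:6 + 0.5, 1:6 - 0.5)  # 6 equal positive differences
  expect_equal(r$p, 2 / 64)
  expect_equal(r$method, "exact")

  same <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)

  set.seed(9)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)   # rounding forces ties and zeros
    if (all(a == b)) next
    got <- paired_wilcoxon(a, b)
    expect_equal(got$p, wilcoxon_enumeration(a, b), tolerance = 1e-12,
                 label = sprintf("draw %d", i))
  }
  # distinct differences match the reference implementation too
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(paired_wilcoxon(a, b)$p, ref, tolerance = 1e-12)
  }
  # large-sample normal mode
  set.seed(10)
  a <- rnorm(40) + 0.6
  b <- rnorm(40)
  big <- paired_wilcoxon(a, b)
  expect_equal(big$method, "normal")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(big$p, ref, tolerance = 1e-9)
  expect_gt(big$delta, 0)
  expect_lt(big$delta_ci[["low"]], big$delta_ci[["high"]])
})

test_that("Holm step-down matches the hand rule and p.adjust", {
  expect_equal(holm_bonferroni(0.04), 0.04)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
  set.seed(12)
  for (i in 1:30) {
    p <- runif(sample(1:8, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_bonferroni(p[perm]), adj[perm])
  }
})

test_that("coefficient of variation uses the n-1 SD as a percentage", {
  expect_equal(cov_percent(c(5, 5, 5)), 0)
  expect_equal(cov_percent(c(80, 90, 100)), 100 * 10 / 90)
  x <- runif(6, 1, 2)
  expect_equal(cov_percent(3 * x), cov_percent(x))
  expect_error(cov_percent(c(-1, 1)), "zero mean")
})

test_that("evaluate_cohort summarizes votes, P_mean, AUC and exclusions", {
  res <- data.frame(patient_id = sprintf("P%d", 1:8),
                    truth = c(1, 1, 1, 0, 0, 0, 1, 0),
                    n_roi = c(rep(50L, 7), 0L),
                    p_mean = c(0.9, 0.8, 0.4, 0.2, 0.1, 0.3, 0.7, NA),
                    vote = c(1L, 1L, 0L, 0L, 0L, 0L, 1L, NA),
                    dice = rep(NA_real_, 8),
                    status = c(rep("ok", 7), "empty_mask"))
  ev <- evaluate_cohort(res, B = 200, seed = 3)
  expect_equal(ev$excluded, 1L)
  expect_equal(ev$n, 7L)
  expect_equal(unname(ev$accuracy), 6 / 7)
  p_true <- c(0.9, 0.8, 0.4, 0.8, 0.9, 0.7, 0.7)
  expect_equal(ev$p_mean, mean(p_true))
  expect_equal(ev$auc, auc(res$p_mean[1:7], res$truth[1:7]))
})
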