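# Statistical harness: ROC/AUC, DeLong, Youden, confusion, Mann-Whitney,
# ANOVA, subgroups.

test_that("roc_auc matches hand-computed examples and curve contract", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)

  # 3 of 4 positive-negative pairs won
  r <- roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)

  expect_equal(unname(r$curve$fpr[1]), 0)
  expect_equal(unname(r$curve$tpr[1]), 0)
  expect_equal(unname(r$curve$fpr[nrow(r$curve)]), 1)
  expect_equal(unname(r$curve$tpr[nrow(r$curve)]), 1)

  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc equals the brute-force pair-counting oracle (with ties)", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding => ties
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("CI construction reproduces the published interval arithmetic", {
  ci <- ci95_from_auc_se(0.774, 0.033)
  expect_equal(round(ci[["lower"]], 3), 0.709)
  # upper bound computes to 0.839 (the published table prints 0.840; rounding
  # discrepancy documented, not asserted)
  expect_equal(round(ci[["upper"]], 3), 0.839)
  expect_equal(ci95_from_auc_se(0.99, 0.05)[["upper"]], 1)  # clipped
})

test_that("DeLong SE agrees with a stratified bootstrap within 15%", {
  set.seed(7)
  n <- 300
  labels <- rbinom(n, 1, 0.5)
  scores <- rnorm(n, mean = 0.8 * labels)
  r <- roc_auc(scores, labels)
  fast_auc <- function(s, y) {
    rk <- rank(s)
    (mean(rk[y == 1]) - (sum(y) + 1) / 2) / sum(y == 0)
  }
  ip <- which(labels == 1); ineg <- which(labels == 0)
  boot <- replicate(2000, {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    fast_auc(scores[idx], labels[idx])
  })
  expect_lt(abs(r$se - sd(boot)) / sd(boot), 0.15)
})

test_that("DeLong paired test: identity, power and degenerate handling", {
  set.seed(11)
  labels <- rbinom(80, 1, 0.5)
  s <- runif(80)
  expect_equal(delong_paired_test(s, s, labels)$p.value, 1)

  # power: AUC gap ~0.15 detected in >= 90% of 200 replicates
  hits <- 0L
  for (rep in 1:200) {
    y <- c(rep(1, 150), rep(0, 150))
    a <- c(rnorm(150, 1.45), rnorm(150, 0))   # AUC ~0.85
    b <- 0.55 * a + sqrt(1 - 0.55^2) * rnorm(300)  # correlated, AUC ~0.70
    p <- delong_paired_test(a, b, y)$p.value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("youden_cutoff equals exhaustive search and handles edge cases", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    got <- youden_cutoff(scores, labels)
    best <- youden_best_j(scores, labels)
    expect_equal(got$j, best, tolerance = 1e-12)
    # the returned threshold achieves the optimum
    expect_equal(youden_j_at(scores, labels, got$threshold), best,
                 tolerance = 1e-12)
  }
  # perfect separation: midpoint between the classes, J = 1
  yd <- youden_cutoff(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(yd$threshold, 0.55)
  expect_equal(yd$j, 1)
  expect_false(yd$anti_predictive)
  # anti-predictive scores are flagged
  yd2 <- youden_cutoff(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1))
  expect_true(yd2$anti_predictive)
})

test_that("confusion statistics: published counts, identities, edge cases", {
  cs <- confusion_from_counts(tp = 72, fn = 27, fp = 27, tn = 69)
  expect_equal(round(cs$sensitivity, 3), 0.727)
  expect_equal(round(cs$specificity, 3), 0.719)
  expect_equal(round(cs$ppv, 3), 0.727)
  expect_equal(round(cs$npv, 3), 0.719)
  # the four published counts sum to 195 (the printed grand total of 197 is
  # inconsistent with its own cells); accuracy follows the counts
  expect_equal(cs$accuracy, 141 / 195)

  cs1 <- confusion_from_counts(1, 1, 1, 1)
  expect_equal(unlist(cs1[c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")]),
               c(sensitivity = 0.5, specificity = 0.5, ppv = 0.5, npv = 0.5,
                 accuracy = 0.5))

  set.seed(31)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  for (thr in c(-1, quantile(scores, c(0.2, 0.5, 0.9)), 2)) {
    cs <- confusion_stats(scores, labels, thr)
    expect_equal(cs$tp + cs$fn, sum(labels == 1))
    expect_equal(cs$tn + cs$fp, sum(labels == 0))
    expect_equal(cs$sensitivity, cs$tp / (cs$tp + cs$fn))
    expect_equal(cs$specificity, cs$tn / (cs$tn + cs$fp))
    expect_equal(cs$accuracy, (cs$tp + cs$tn) / 60)
  }
  cs_hi <- confusion_stats(scores, labels, max(scores) + 1)
  expect_equal(cs_hi$sensitivity, 0)
  expect_equal(cs_hi$specificity, 1)
})

test_that("mann_whitney: exact enumeration, ties, and normal approximation", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1)   # 2/20 arrangements as extreme
  expect_equal(mw$method, "exact")

  expect_equal(mann_whitney(c(2, 5, 9), c(2, 5, 9))$p.value, 1)

  set.seed(41)
  a <- rnorm(100, 1); b <- rnorm(100)
  expect_lt(mann_whitney(a, b)$p.value, 1e-6)

  # normal approximation matches the base implementation without continuity
  # correction (ties handled by the same midrank correction)
  x <- round(rnorm(40), 1); y <- round(rnorm(35, 0.3), 1)
  expect_equal(mann_whitney(x, y)$p.value,
               suppressWarnings(
                 wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value,
               tolerance = 1e-10)
})

test_that("two_way_anova: degenerate grids, additive effect, null calibration", {
  grid0 <- expand.grid(l2 = c(0.01, 0.02), augment = c(1, 10), rep = 1:2)
  grid0$auc <- 0.7
  res <- two_way_anova(grid0)
  expect_equal(res$p_l2, 1)
  expect_equal(res$p_augment, 1)

  grid1 <- grid0
  grid1$auc <- 0.6 + 0.1 * (grid1$augment == 10)  # pure additive, no noise
  res1 <- two_way_anova(grid1)
  expect_equal(res1$p_augment, 0)
  expect_equal(res1$p_l2, 1)

  expect_error(two_way_anova(grid0[-1, ]), "unbalanced")

  set.seed(51)
  rej <- replicate(1000, {
    g <- expand.grid(l2 = 1:2, augment = 1:2, rep = 1:2)
    g$auc <- rnorm(8)
    two_way_anova(g)$p_augment < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("subgroup_auc: degenerate bands and band/global consistency", {
  set.seed(61)
  n <- 600
  ages <- runif(n, 25, 34)   # everyone in the first SART band
  labels <- rbinom(n, 1, 0.5)
  scores <- labels + rnorm(n)
  glob <- roc_auc(scores, labels)
  sg <- subgroup_auc(scores, labels, ages)
  expect_equal(sg[["<35"]]$auc, glob$auc)
  expect_true(isTRUE(sg[["38-40"]]$undefined))

  # uniform signal: per-band AUC within 3 SE of the global AUC
  ages2 <- sample(c(30, 36, 39, 41.5, 44), n, replace = TRUE)
  sg2 <- subgroup_auc(scores, labels, ages2)
  for (b in sg2) {
    if (isTRUE(b$undefined)) next
    expect_lt(abs(b$auc - glob$auc), 3 * max(b$se, 1e-6))
  }
})
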