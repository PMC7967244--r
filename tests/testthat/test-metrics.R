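test_that("clinical indexes match hand-computed values", {
  ## TP = 40, FN = 10, FP = 5, TN = 45
  cm <- matrix(c(40, 5, 10, 45), 2, 2,
               dimnames = list(c("MI", "HC"), c("MI", "HC")))
  m <- clinical_indexes(cm, positive = "MI")
  expect_equal(m$acc, 85)
  expect_equal(m$sen, 80)
  expect_equal(m$spe, 90)
  expect_equal(m$f1, 100 * 80 / 95)   # 2*40 / (2*40 + 5 + 10) = 84.21...
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(40, 45, 5, 10))
})

test_that("clinical indexes reorder by the positive-class name", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2,
               dimnames = list(c("HC", "MI"), c("HC", "MI")))
  m <- clinical_indexes(cm, positive = "MI")
  expect_equal(m$sen, 80)
  expect_equal(m$spe, 90)
})

test_that("zero denominators give NA, never an error", {
  cm <- matrix(c(0, 5, 0, 45), 2, 2,
               dimnames = list(c("MI", "HC"), c("MI", "HC")))
  m <- clinical_indexes(cm)
  expect_true(is.na(m$sen))           # no true positives or false negatives
  expect_false(is.na(m$spe))
  expect_error(clinical_indexes(matrix(0, 3, 3)), "2 x 2")
})

test_that("multiclass accuracy is trace over total", {
  cm <- diag(6) * 10
  expect_equal(multiclass_accuracy(cm), 100)
  expect_equal(multiclass_accuracy(matrix(1, 6, 6)), 100 / 6)
  off <- matrix(0, 3, 3); off[cbind(1:3, c(2, 3, 1))] <- 5
  expect_equal(multiclass_accuracy(off), 0)
  expect_error(multiclass_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("AUC equals the rank statistic in known cases", {
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve_auc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
  expect_equal(roc_curve_auc(c(0.5, 0.5, 0.5, 0.5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  ## one discordant pair of four: 3/4
  expect_equal(roc_curve_auc(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_curve_auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("AUC equals U / (n_pos * n_neg) on random data", {
  set.seed(42)
  for (i in 1:10) {
    scores <- runif(30)
    labels <- runif(30) < 0.5
    if (!any(labels) || all(labels)) next
    auc <- roc_curve_auc(scores, labels)$auc
    u <- mann_whitney_u(scores[labels], scores[!labels])$u
    expect_equal(auc, u / (sum(labels) * sum(!labels)))
  }
})

test_that("ROC curve is a valid monotone step path ending at (1, 1)", {
  set.seed(7)
  r <- roc_curve_auc(runif(50), runif(50) < 0.4)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC agrees with pROC on random data", {
  set.seed(9)
  scores <- runif(60)
  labels <- runif(60) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(roc_curve_auc(scores, labels)$auc, ref)
})

test_that("Mann-Whitney U matches hand-worked extremes", {
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$u, 0)                 # complete separation, a below b
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 * 1 / choose(6, 3))   # two-sided: 2/20 = 0.1
  r2 <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$u, 9)                # n*m - 0 by symmetry
  expect_equal(r2$p, r$p)
})

test_that("exact p-values match brute-force enumeration (no ties)", {
  set.seed(11)
  for (sizes in list(c(3, 3), c(4, 5), c(5, 2), c(6, 6), c(7, 4))) {
    a <- rnorm(sizes[1]); b <- rnorm(sizes[2])
    got <- mann_whitney_u(a, b)
    ref <- brute_force_u_p(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$u, ref$u)
    expect_equal(got$p, ref$p)
  }
})

test_that("exact p-values match wilcox.test (no ties)", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(6)
    got <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
})

test_that("normal approximation matches wilcox.test with ties", {
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  b <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal")
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("large samples switch to the normal approximation", {
  set.seed(17)
  a <- rnorm(25); b <- rnorm(25)
  got <- mann_whitney_u(a, b)
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("identical samples give p = 1", {
  x <- c(5, 5, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$u, 4.5)              # all midranks: n*m/2
  expect_equal(r$p, 1)
  expect_equal(r$stars, "ns")
})

test_that("one-sided alternatives are consistent", {
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  less <- mann_whitney_u(a, b, alternative = "less")
  greater <- mann_whitney_u(a, b, alternative = "greater")
  expect_lt(less$p, 0.05)
  expect_equal(greater$p, 1)
  expect_equal(less$p,
               stats::wilcox.test(a, b, alternative = "less", exact = TRUE)$p.value)
})

test_that("significance stars follow the conventional cut points", {
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.05), "ns")
  expect_equal(significance_stars(0.9), "ns")
  expect_true(is.na(significance_stars(NA)))
})

test_that("u_null_frequencies sums to C(n+m, n) and is symmetric", {
  for (nm in list(c(2, 1), c(3, 3), c(5, 4), c(8, 8))) {
    f <- ecgmi:::u_null_frequencies(nm[1], nm[2])
    expect_equal(sum(f), choose(sum(nm), nm[1]))
    expect_equal(f, rev(f))           # null distribution of U is symmetric
    expect_equal(length(f), nm[1] * nm[2] + 1)
  }
  expect_equal(ecgmi:::u_null_frequencies(2, 1), c(1, 1, 1))
})

test_that("compare_models: a model against itself is never significant", {
  tab <- data.frame(acc = c(80, 82, 84, 86, 88),
                    sen = c(75, 78, 80, 82, 85),
                    spe = c(85, 86, 88, 90, 91),
                    f1 = c(78, 80, 82, 84, 86),
                    auc = c(0.8, 0.82, 0.84, 0.86, 0.88))
  cmp <- compare_models(tab, tab, task = "detection")
  expect_equal(nrow(cmp), 5)
  expect_true(all(cmp$p == 1))
  expect_true(all(cmp$stars == "ns"))
  expect_equal(cmp$mean_a, cmp$mean_b)
})

test_that("compare_models flags disjoint accuracy distributions", {
  a <- data.frame(acc = seq(90, 95, length.out = 15))
  b <- data.frame(acc = seq(60, 65, length.out = 15))
  cmp <- compare_models(a, b, task = "locating")
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$index, "acc")
  expect_lt(cmp$p, 0.001)
  expect_equal(cmp$stars, "***")
  expect_error(compare_models(a, data.frame(acc = 1:3), task = "locating"),
               "repeat counts differ")
})
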