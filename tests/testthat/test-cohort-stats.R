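test_that("rank-sum test uses the exact distribution for tiny groups", {
  # all C(4,2) = 6 assignments of ranks; observed split is the most extreme
  # on one side -> two-sided p = 2 * (1/6)
  expect_equal(wilcoxonRankSum(c(1, 2), c(10, 20)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "each group")
})

test_that("large-sample rank-sum p agrees with a permutation estimate", {
  set.seed(51)
  x <- rnorm(50); y <- rnorm(50, 0.4)
  p <- wilcoxonRankSum(x, y)
  pooled <- c(x, y)
  stat <- function(ix) sum(rank(pooled)[ix])
  obs <- sum(rank(pooled)[1:50])
  mu <- 50 * 101 / 2
  nperm <- 20000
  perm <- replicate(nperm, stat(sample.int(100, 50)))
  pperm <- mean(abs(perm - mu) >= abs(obs - mu) - 1e-9)
  se <- sqrt(pperm * (1 - pperm) / nperm)
  expect_lt(abs(p - pperm), 5 * se + 1e-4)
})

test_that("BH q-values match the brute-force step-up formula", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.123), 0.123)
  expect_equal(bhFdr(rep(1, 7)), rep(1, 7))
  set.seed(52)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney AUC equals the trapezoidal ROC area", {
  set.seed(53)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    vals <- if (i %% 2) rnorm(n) else sample(1:6, n, TRUE)  # with ties
    isPos <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(isPos) || all(isPos)) next
    expect_equal(mbglioma:::.aucMW(vals, isPos), trapezoidAuc(vals, isPos),
                 tolerance = 1e-12)
  }
})

test_that("ROC analysis finds the separating threshold and orientation", {
  r <- rocAnalysis(c(1, 2, 3, 4), c("HGG", "HGG", "metastasis", "metastasis"))
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 2); expect_lt(r$threshold, 3)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_identical(r$direction, "greater")
  # reversed direction is auto-oriented
  r2 <- rocAnalysis(c(4, 3, 2, 1), c("HGG", "HGG", "metastasis", "metastasis"))
  expect_equal(r2$auc, 1)
  expect_identical(r2$direction, "less")
  expect_equal(r2$sensitivity + r2$specificity, 2)
  rc <- rocAnalysis(rep(5, 8), rep(c("HGG", "metastasis"), 4))
  expect_equal(rc$auc, 0.5)
  expect_error(rocAnalysis(1:4, rep("HGG", 4)), "both classes")
})

test_that("the reported threshold maximizes sensitivity + specificity", {
  set.seed(54)
  for (i in 1:15) {
    vals <- round(rnorm(40), 1)
    labs <- ifelse(rnorm(40, vals) > 0.4, "metastasis", "HGG")
    if (length(unique(labs)) < 2) next
    r <- rocAnalysis(vals, labs)
    isPos <- labs == "metastasis"
    v <- if (r$direction == "greater") vals else -vals
    sweep <- vapply(sort(unique(c(v - 1e-6, v + 1e-6))), function(t)
      mean(v[isPos] > t) + mean(v[!isPos] <= t), 0)
    expect_equal(r$sensitivity + r$specificity, max(sweep),
                 tolerance = 1e-12)
    expect_gte(r$auc, 0.5)
  }
})

test_that("threshold odds ratios equal the cross-product ratio", {
  # 2x2 [[10,5],[5,10]]: OR = (10*10)/(5*5) = 4
  vals <- c(rep(0, 15), rep(1, 15))
  labs <- c(rep("HGG", 10), rep("metastasis", 5),
            rep("HGG", 5), rep("metastasis", 10))
  r <- thresholdOddsRatio(vals, labs, 0.5, "greater")
  expect_equal(unname(r$or), 4, tolerance = 1e-6)
  expect_false(r$corrected)
  # [[7,1],[2,7]]: OR = 49/2
  vals2 <- c(rep(0, 8), rep(1, 9))
  labs2 <- c(rep("HGG", 7), "metastasis", rep("HGG", 2), rep("metastasis", 7))
  r2 <- thresholdOddsRatio(vals2, labs2, 0.5, "greater")
  expect_equal(unname(r2$or), 24.5, tolerance = 1e-6)
  # independence -> OR 1
  vals3 <- rep(c(0, 1), each = 10)
  labs3 <- rep(rep(c("HGG", "metastasis"), each = 5), 2)
  expect_equal(unname(thresholdOddsRatio(vals3, labs3, 0.5, "greater")$or), 1,
               tolerance = 1e-9)
  # zero cell -> Haldane-Anscombe correction, flagged
  vals4 <- c(1, 1, 1, 0, 0, 0)
  labs4 <- c(rep("metastasis", 3), rep("HGG", 3))
  r4 <- thresholdOddsRatio(vals4, labs4, 0.5, "greater")
  expect_true(r4$corrected)
  expect_equal(unname(r4$or), (3.5 * 3.5) / (0.5 * 0.5))
  expect_error(thresholdOddsRatio(vals4, labs4, 5, "greater"), "degenerate")
})

.syntheticFeatureTable <- function(n1 = 40, n2 = 25, shift = 0, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  tab <- data.frame(id = sprintf("s%03d", 1:n),
                    label = rep(c("HGG", "metastasis"), c(n1, n2)))
  for (nm in featureNames()) tab[[nm]] <- rnorm(n)
  tab$K_enh_median <- tab$K_enh_median +
    shift * (tab$label == "metastasis")
  tab
}

test_that("an injected group shift is recovered as significant after FDR", {
  for (seed in 1:3) {
    tab <- .syntheticFeatureTable(shift = 1.6, seed = seed)
    res <- compareGroups(tab)
    expect_lt(res$univariate$q[res$univariate$feature == "K_enh_median"],
              0.05)
  }
})

test_that("label permutation keeps the FDR near its nominal level", {
  set.seed(55)
  fracs <- vapply(1:12, function(i) {
    tab <- .syntheticFeatureTable(shift = 0, seed = 100 + i)
    res <- compareGroups(tab)
    mean(res$univariate$significant, na.rm = TRUE)
  }, 0)
  expect_lte(mean(fracs), 0.05)
})

test_that("absent markers are skipped identically to dropped rows", {
  tab <- .syntheticFeatureTable(seed = 9)
  tab$f_nonenh_median[1:10] <- NA
  res <- compareGroups(tab)
  row <- res$univariate[res$univariate$feature == "f_nonenh_median", ]
  x <- tab$f_nonenh_median[tab$label == "HGG"]
  y <- tab$f_nonenh_median[tab$label == "metastasis"]
  expect_equal(row$p, wilcoxonRankSum(x[!is.na(x)], y[!is.na(y)]))
  expect_identical(row$n_neg, sum(!is.na(x)))
  # a feature absent in an entire group is marked not computable
  tab$D_edema_sd[tab$label == "metastasis"] <- NA
  res2 <- compareGroups(tab)
  expect_true(is.na(res2$univariate$p[
    res2$univariate$feature == "D_edema_sd"]))
})

test_that("own AUC agrees with the reference ROC implementation", {
  set.seed(56)
  vals <- rnorm(60); labs <- ifelse(rnorm(60, vals) > 0, "metastasis", "HGG")
  r <- rocAnalysis(vals, labs)
  ref <- pROC::roc(labs == "metastasis", vals, quiet = TRUE,
                   direction = if (r$direction == "greater") "<" else ">")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})
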