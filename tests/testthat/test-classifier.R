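.toyTable <- function(n = 30, seed = 61, sep = 3) {
  set.seed(seed)
  lab <- rep(c("HGG", "metastasis"), length.out = n)
  tab <- data.frame(id = sprintf("s%02d", 1:n), label = lab)
  tab$K_enh_median <- rnorm(n) + sep * (lab == "metastasis")
  tab$D_enh_median <- rnorm(n)
  tab$vol_nonenh <- rnorm(n)
  tab
}

test_that("zero-imputation replaces markers and keeps them recoverable", {
  tab <- .toyTable()
  tab$K_enh_median[2] <- NA; tab$vol_nonenh[c(1, 5)] <- NA
  imp <- imputeMissingZero(tab)
  expect_false(anyNA(imp$K_enh_median))
  expect_equal(imp$K_enh_median[2], 0)
  mask <- attr(imp, "imputed")
  expect_identical(unname(which(mask[, "vol_nonenh"])), c(1L, 5L))
  # fully observed table is unchanged
  full <- .toyTable()
  imp2 <- imputeMissingZero(full)
  expect_equal(imp2$K_enh_median, full$K_enh_median)
})

test_that("LASSO keeps an informative feature and rejects pure noise", {
  nSeeds <- 20
  good <- 0
  for (s in 1:nSeeds) {
    set.seed(700 + s)
    n <- 80
    lab <- rep(c("HGG", "metastasis"), each = n / 2)
    tab <- data.frame(id = sprintf("s%02d", 1:n), label = lab)
    tab$f_enh_median <- (lab == "metastasis") + rnorm(n, 0, 0.6)
    noiseNames <- setdiff(featureNames(), "f_enh_median")[1:50]
    for (nm in noiseNames) tab[[nm]] <- rnorm(n)
    sel <- lassoSelect(tab, nFolds = 10, seed = s)
    hit <- "f_enh_median" %in% sel$selected
    fp <- length(setdiff(sel$selected, "f_enh_median"))
    if (hit && fp <= 2) good <- good + 1
  }
  expect_gte(good / nSeeds, 0.9)
})

test_that("LASSO selection is seed-deterministic and guards its inputs", {
  tab <- .toyTable(n = 40)
  s1 <- lassoSelect(tab, nFolds = 5, seed = 3)
  s2 <- lassoSelect(tab, nFolds = 5, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_true("K_enh_median" %in% s1$selected)
  const <- tab
  const$K_enh_median <- 1; const$D_enh_median <- 0; const$vol_nonenh <- 2
  expect_identical(lassoSelect(const, nFolds = 5, seed = 1)$selected,
                   character(0))
  expect_error(lassoSelect(tab[1:4, ], nFolds = 10, seed = 1),
               "fewer subjects than folds")
  tabNA <- tab; tabNA$vol_nonenh[1] <- NA
  expect_error(lassoSelect(tabNA, nFolds = 5, seed = 1), "imputed")
})

test_that("a perfectly separating feature gives a depth-1 tree", {
  tab <- .toyTable(n = 40, sep = 10)
  model <- fitDecisionTree(tab, features = c("K_enh_median", "D_enh_median"),
                           minsplit = 10)
  expect_equal(sum(!model@nodes$leaf), 1)
  expect_identical(model@nodes$var[!model@nodes$leaf], "K_enh_median")
  ev <- evaluateTree(model, tab)
  expect_equal(ev$accuracy, 1)
})

test_that("uninformative data with large minsplit gives a majority leaf", {
  tab <- .toyTable(n = 20, sep = 0)
  model <- fitDecisionTree(tab, minsplit = 50,
                           features = c("K_enh_median", "D_enh_median"))
  expect_equal(nrow(model@nodes), 1)
  expect_true(model@nodes$leaf[1])
  pred <- predictTree(model, tab)
  expect_equal(length(unique(pred$class)), 1)
  # single-class input: a trivial single-leaf tree, not an error
  one <- .toyTable(n = 10)
  one$label <- "HGG"
  m1 <- fitDecisionTree(one, features = "K_enh_median")
  expect_equal(nrow(m1@nodes), 1)
  expect_identical(predictTree(m1, one)$class, rep("HGG", 10))
})

test_that("recursive split search learns a two-feature interaction", {
  set.seed(62)
  # three tight corner clusters, 25 points each; the positive class needs
  # BOTH features high, so a correct tree is exactly depth 2
  centers <- rbind(c(0, 1), c(1, 0), c(1, 1))
  lab <- rep(c("HGG", "HGG", "metastasis"), each = 25)
  xy <- centers[rep(1:3, each = 25), ] +
    matrix(rnorm(150, 0, 0.05), 75)
  tab <- data.frame(id = sprintf("s%03d", 1:75), label = lab,
                    K_enh_median = xy[, 1], vol_nonenh = xy[, 2])
  model <- fitDecisionTree(tab, features = c("K_enh_median", "vol_nonenh"),
                           minsplit = 25, cp = 1e-4)
  ev <- evaluateTree(model, tab)
  expect_equal(ev$accuracy, 1)
  depth <- max(floor(log2(model@nodes$id[model@nodes$leaf])))
  expect_equal(depth, 2)
  # both features appear on the path to the positive leaf
  expect_setequal(unique(na.omit(model@nodes$var)),
                  c("K_enh_median", "vol_nonenh"))
})

test_that("tree descent matches a hand-built two-node model", {
  nodes <- data.frame(
    id = c(1L, 2L, 3L, 6L, 7L),
    var = c("K_enh_median", NA, "vol_nonenh", NA, NA),
    threshold = c(0.5, NA, 2, NA, NA),
    leftIfLess = c(TRUE, NA, TRUE, NA, NA),
    pred = c("HGG", "HGG", "metastasis", "HGG", "metastasis"),
    probPositive = c(0.4, 0.1, 0.8, 0.3, 0.9),
    n = c(10L, 5L, 5L, 2L, 3L), frac = c(1, 0.5, 0.5, 0.2, 0.3),
    leaf = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  model <- new("TreeModel", nodes = nodes,
               classes = c("HGG", "metastasis"))
  tab <- data.frame(K_enh_median = c(0.2, 0.9, 0.9),
                    vol_nonenh = c(5, 1, 3))
  pred <- predictTree(model, tab)
  # manual descent: (0.2 -> node 2 HGG), (0.9, 1 -> node 6 HGG),
  # (0.9, 3 -> node 7 metastasis)
  expect_identical(pred$class, c("HGG", "HGG", "metastasis"))
  expect_identical(pred$leaf, c(2L, 6L, 7L))
  expect_error(predictTree(model, tab[, 1, drop = FALSE]),
               "unknown feature")
})

test_that("own descent reproduces the reference CART predictions", {
  tab <- .toyTable(n = 60, seed = 63, sep = 1.2)
  model <- fitDecisionTree(tab, minsplit = 10, cp = 0.005,
                           features = c("K_enh_median", "D_enh_median",
                                        "vol_nonenh"))
  df <- tab[, c("K_enh_median", "D_enh_median", "vol_nonenh")]
  df$.y <- factor(tab$label, c("HGG", "metastasis"))
  ref <- rpart::rpart(.y ~ ., df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = 10, cp = 0.005, xval = 0,
                        maxsurrogate = 0, maxcompete = 0))
  expect_identical(predictTree(model, tab)$class,
                   unname(as.character(predict(ref, df, type = "class"))))
})

test_that("JSON serialization round-trips a TreeModel", {
  tab <- .toyTable(n = 40, seed = 64, sep = 1.5)
  model <- fitDecisionTree(tab, minsplit = 10,
                           features = c("K_enh_median", "vol_nonenh"))
  path <- withr::local_tempfile(fileext = ".json")
  writeTreeModel(model, path)
  model2 <- readTreeModel(path)
  expect_identical(predictTree(model2, tab), predictTree(model, tab))
  expect_equal(model2@nodes$threshold, model@nodes$threshold)
})

test_that("increasing the pruning parameter never grows the tree", {
  tab <- .toyTable(n = 80, seed = 65, sep = 1)
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2), function(cp)
    nrow(fitDecisionTree(tab, cp = cp, minsplit = 10,
                         features = c("K_enh_median", "D_enh_median",
                                      "vol_nonenh"))@nodes), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("leaf occupancy agrees with recounting through predict", {
  tab <- .toyTable(n = 60, seed = 66, sep = 1.2)
  model <- fitDecisionTree(tab, minsplit = 10,
                           features = c("K_enh_median", "vol_nonenh"))
  pred <- predictTree(model, tab)
  leaves <- model@nodes[model@nodes$leaf, ]
  counts <- table(factor(pred$leaf, leaves$id))
  expect_equal(as.numeric(counts), leaves$n)
  expect_equal(sum(leaves$frac), 1)
})

test_that("confusion statistics reproduce the printed validation matrix", {
  # predicted x reference, metastasis positive:
  # predicted HGG: 7 HGG, 1 metastasis; predicted metastasis: 2 HGG, 7 meta
  m <- matrix(c(7, 2, 1, 7), 2)
  cs <- confusionStats(m)
  expect_equal(round(cs$sensitivity, 3), 0.875)
  expect_equal(round(cs$specificity, 3), 0.778)
  expect_equal(cs$n, 17)
  expect_equal(cs$accuracy, 14 / 17)
  perfect <- confusionStats(matrix(c(9, 0, 0, 8), 2))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  noPos <- confusionStats(matrix(c(5, 5, 0, 0), 2))
  expect_true(is.na(noPos$sensitivity))
  expect_false(is.na(noPos$specificity))
  expect_error(confusionStats(matrix(c(1, -1, 0, 2), 2)), "non-negative")
})
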