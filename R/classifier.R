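#' Replace absent-tissue markers by zero
#'
#' L1-regularized regression needs a fully numeric matrix, so absent-tissue
#' NA markers are replaced by 0.  The imputation mask is retained as an
#' attribute for audit so the original pattern stays recoverable.
#'
#' @param table feature table with NA markers.
#' @return the table with every feature NA set to 0 and attribute
#'   \code{imputed} (logical matrix of the former NA pattern).
#' @export
imputeMissingZero <- function(table) {
  feats <- intersect(featureNames(), names(table))
  mask <- is.na(as.matrix(table[, feats]))
  for (nm in feats) table[[nm]][is.na(table[[nm]])] <- 0
  attr(table, "imputed") <- mask
  table
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression of the positive class on the
#' standardized, zero-imputed features; the penalty is chosen by seeded
#' k-fold cross-validated deviance with the 1-SE rule.  Features with
#' nonzero coefficients at the chosen penalty are returned.
#'
#' @param table zero-imputed feature table.
#' @param labels group labels (default the table's label column).
#' @param nFolds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @param positive the positive class.
#' @return list: \code{selected} (feature names), \code{lambda} (chosen
#'   penalty), \code{path} data.frame (lambda, mean CV deviance, nonzero
#'   count).
#' @export
lassoSelect <- function(table, labels = table$label, nFolds = 10, seed = 1,
                        positive = "metastasis") {
  feats <- intersect(featureNames(), names(table))
  x <- as.matrix(table[, feats])
  if (anyNA(x)) stop("table must be zero-imputed first (NA present)")
  y <- as.integer(labels == positive)
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (nrow(x) < nFolds) stop("fewer subjects than folds")
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (!any(keep))
    return(list(selected = character(), lambda = NA_real_,
                path = data.frame()))
  x <- x[, keep, drop = FALSE]
  foldid <- .withSeed(seed, sample(rep(seq_len(nFolds),
                                       length.out = nrow(x))))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = TRUE, foldid = foldid)
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  sel <- rownames(co)[co[, 1] != 0]
  sel <- setdiff(sel, "(Intercept)")
  list(selected = sel, lambda = cv$lambda.1se,
       path = data.frame(lambda = cv$lambda, cv_deviance = cv$cvm,
                         nonzero = cv$nzero))
}

#' Published differentiation-tree feature subset
#'
#' The four features of the published glioma-versus-metastasis decision
#' tree: 95th and 5th percentiles of enhancing-tissue diffusion kurtosis,
#' non-enhancing tissue volume, and the histogram kurtosis of the edema
#' pseudo-diffusion coefficient.  Offered as a fixed alternative to
#' data-driven LASSO selection.
#'
#' @return character vector of 4 feature names.
#' @export
publishedTreeFeatures <- function() {
  c("K_enh_p95", "vol_nonenh", "Dstar_edema_kurt", "K_enh_p5")
}

#' CART model container
#'
#' Binary classification tree in a flat, JSON-serializable node table.
#' Internal nodes carry (feature, threshold, direction); leaves carry the
#' predicted class, the class proportion, and the fraction of training
#' subjects reaching them (so sibling-leaf fractions sum over each layer).
#'
#' @slot nodes data.frame with columns id, var, threshold, leftIfLess,
#'   pred, probPositive, n, frac, leaf.
#' @slot classes character length-2, (negative, positive).
#' @export
setClass("TreeModel",
  representation(nodes = "data.frame", classes = "character"))

setMethod("show", "TreeModel", function(object) {
  cat("TreeModel:", sum(object@nodes$leaf), "leaves,",
      sum(!object@nodes$leaf), "splits; classes:",
      paste(object@classes, collapse = " / "), "\n")
  .printTreeNode(object, 1L, "")
})

.printTreeNode <- function(model, id, indent) {
  nd <- model@nodes[model@nodes$id == id, ]
  if (!nrow(nd)) return(invisible())
  if (nd$leaf) {
    cat(sprintf("%s* %s  (%.2f positive, %.0f%% of patients)\n", indent,
                nd$pred, nd$probPositive, 100 * nd$frac))
  } else {
    cat(sprintf("%s%s %s %.4g\n", indent, nd$var,
                if (nd$leftIfLess) "<" else ">=", nd$threshold))
    .printTreeNode(model, 2L * id, paste0(indent, "  "))
    cat(sprintf("%s%s %s %.4g\n", indent, nd$var,
                if (nd$leftIfLess) ">=" else "<", nd$threshold))
    .printTreeNode(model, 2L * id + 1L, paste0(indent, "  "))
  }
  invisible()
}

#' Fit a CART decision tree
#'
#' Classification tree with Gini impurity, exhaustive split search,
#' minimum-node-size stopping and cost-complexity pruning (rpart engine,
#' the conventional CART implementation; defaults minsplit 20, cp 0.01).
#' Single-class input yields a single-leaf tree, not an error.
#'
#' @param table feature table restricted (by you or by LASSO) to candidate
#'   features; zero-imputed.
#' @param labels class labels (default table$label).
#' @param features candidate feature names (default: all present features).
#' @param minsplit minimum node size eligible for splitting.
#' @param cp cost-complexity pruning parameter.
#' @param positive the positive class.
#' @return A \linkS4class{TreeModel}.
#' @export
fitDecisionTree <- function(table, labels = table$label,
                            features = intersect(featureNames(),
                                                 names(table)),
                            minsplit = 20, cp = 0.01,
                            positive = "metastasis") {
  stopifnot(length(features) >= 1)
  neg <- setdiff(unique(labels), positive)
  if (length(neg) > 1) stop("labels must contain exactly two classes")
  classes <- c(if (length(neg)) neg else "HGG", positive)
  df <- table[, features, drop = FALSE]
  if (anyNA(df)) stop("table must be zero-imputed first (NA present)")
  y <- factor(ifelse(labels == positive, positive, classes[1]),
              levels = classes)
  if (length(unique(y)) < 2 || length(y) < 2) {
    prob <- mean(y == positive)
    nodes <- data.frame(id = 1L, var = NA_character_,
                        threshold = NA_real_, leftIfLess = NA,
                        pred = if (prob >= 0.5) positive else classes[1],
                        probPositive = prob, n = length(y), frac = 1,
                        leaf = TRUE, stringsAsFactors = FALSE)
    return(new("TreeModel", nodes = nodes, classes = classes))
  }
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = minsplit, cp = cp, xval = 0,
                        maxsurrogate = 0, maxcompete = 0))
  .treeFromRpart(fit, classes)
}

.treeFromRpart <- function(fit, classes) {
  fr <- fit$frame
  ids <- as.integer(rownames(fr))
  posCol <- which(attr(fit, "ylevels") == classes[2])
  nclass <- length(attr(fit, "ylevels"))
  probPos <- fr$yval2[, 1 + nclass + posCol]
  splitRow <- 1L
  nodes <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    isLeaf <- fr$var[i] == "<leaf>"
    var <- thr <- NA
    leftLess <- NA
    if (!isLeaf) {
      sp <- fit$splits[splitRow, ]
      var <- as.character(fr$var[i])
      thr <- unname(sp["index"])
      leftLess <- sp["ncat"] < 0
      splitRow <- splitRow + 1L + fr$ncompete[i] + fr$nsurrogate[i]
    }
    nodes[[i]] <- data.frame(
      id = ids[i], var = if (is.na(leftLess)) NA_character_ else var,
      threshold = as.numeric(thr), leftIfLess = as.logical(leftLess),
      pred = attr(fit, "ylevels")[fr$yval[i]],
      probPositive = probPos[i], n = fr$n[i], frac = fr$n[i] / fr$n[1],
      leaf = isLeaf, stringsAsFactors = FALSE)
  }
  new("TreeModel", nodes = do.call(rbind, nodes), classes = classes)
}

#' Predict classes with a TreeModel
#'
#' Deterministic descent from the root; records each subject's leaf for
#' explainability.
#'
#' @param model a \linkS4class{TreeModel}.
#' @param table feature table containing every feature the tree uses
#'   (zero-imputed).
#' @return data.frame with columns class and leaf (node id).
#' @export
predictTree <- function(model, table) {
  used <- stats::na.omit(unique(model@nodes$var))
  missing <- setdiff(used, names(table))
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  nd <- model@nodes
  rownames(nd) <- as.character(nd$id)
  descend <- function(row) {
    id <- 1L
    repeat {
      node <- nd[as.character(id), ]
      if (node$leaf) return(c(node$pred, id))
      v <- row[[node$var]]
      goLeft <- if (node$leftIfLess) v < node$threshold
                else v >= node$threshold
      id <- if (goLeft) 2L * id else 2L * id + 1L
    }
  }
  res <- t(vapply(seq_len(nrow(table)),
                  function(i) descend(table[i, , drop = FALSE]),
                  character(2)))
  data.frame(class = res[, 1], leaf = as.integer(res[, 2]),
             stringsAsFactors = FALSE)
}

#' Serialize / load a TreeModel as JSON
#'
#' @param model a \linkS4class{TreeModel}.
#' @param path JSON file path.
#' @export
writeTreeModel <- function(model, path) {
  jsonlite::write_json(list(classes = model@classes, nodes = model@nodes),
                       path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTreeModel
#' @export
readTreeModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  nodes <- obj$nodes
  nodes$var <- as.character(nodes$var)
  nodes$threshold <- as.numeric(nodes$threshold)
  new("TreeModel", nodes = nodes, classes = obj$classes)
}

#' Confusion-matrix statistics
#'
#' Rows of the matrix are predicted classes (negative, positive) and
#' columns the reference classes in the same order; metastasis is the
#' positive class throughout.  The AUC of a binary predictor is reported
#' as (sensitivity + specificity)/2, qualified as such.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return list: matrix, sensitivity, specificity, accuracy, auc
#'   (binary-predictor), n.  Rates are NA when a reference class has no
#'   cases.
#' @export
confusionStats <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == 2) || any(m < 0) || any(m != round(m)))
    stop("need a 2x2 matrix of non-negative integer counts")
  tp <- m[2, 2]; fn <- m[1, 2]; tn <- m[1, 1]; fp <- m[2, 1]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(matrix = m, sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / sum(m),
       auc = if (is.na(sens) || is.na(spec)) NA_real_
             else (sens + spec) / 2,
       auc_type = "binary-predictor", n = sum(m))
}

#' Evaluate a TreeModel on labelled data
#'
#' @param model a \linkS4class{TreeModel}.
#' @param table zero-imputed labelled feature table.
#' @param labels reference labels (default table$label).
#' @return \code{\link{confusionStats}} output plus the predictions.
#' @export
evaluateTree <- function(model, table, labels = table$label) {
  pred <- predictTree(model, table)
  cls <- model@classes
  m <- table(factor(pred$class, cls), factor(labels, cls))
  out <- confusionStats(unclass(m))
  out$predictions <- pred
  out
}
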