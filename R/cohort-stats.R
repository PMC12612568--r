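#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the smaller group has at most 10
#' observations and there are no ties; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("each group needs at least one value")
  exact <- min(length(x), length(y)) <= 10 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate q-values with monotonicity enforcement;
#' order-preserving.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values, same order as the input.
#' @export
bhFdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Mann-Whitney AUC of `values` for predicting labels == positive,
# in the "higher value => positive" orientation (ties count 1/2)
.aucMW <- function(values, isPos) {
  r <- rank(values)
  np <- sum(isPos); nn <- sum(!isPos)
  (sum(r[isPos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC threshold analysis of one feature
#'
#' Empirical ROC over all cut midpoints; AUC by the Mann-Whitney identity
#' with a DeLong 95% CI; the optimal threshold maximizes sensitivity +
#' specificity (Youden), with ties broken toward the threshold with higher
#' specificity.  The direction is auto-oriented so AUC >= 0.5 and recorded:
#' "greater" means values above the threshold predict the positive class.
#' NA entries (absent tissue) are skipped.
#'
#' @param values numeric feature vector.
#' @param labels group labels, same length.
#' @param positive the positive class (default "metastasis").
#' @return list: auc, auc_ci (DeLong 95%), threshold, sensitivity,
#'   specificity, direction, n_pos, n_neg, plus odds ratio fields (or,
#'   or_ci, or_p) at the optimal threshold.
#' @export
rocAnalysis <- function(values, labels, positive = "metastasis") {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  isPos <- labels == positive
  if (!any(isPos) || all(isPos)) stop("both classes must be present")
  auc <- .aucMW(values, isPos)
  direction <- if (auc >= 0.5) "greater" else "less"
  if (auc < 0.5) auc <- 1 - auc
  v <- if (direction == "greater") values else -values
  u <- sort(unique(v))
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cuts, function(t) mean(v[isPos] > t), 0)
  spec <- vapply(cuts, function(t) mean(v[!isPos] <= t), 0)
  ord <- order(sens + spec, spec, decreasing = TRUE)
  bestIdx <- ord[1]
  thr <- cuts[bestIdx]
  if (direction == "less") thr <- -thr
  ci <- tryCatch(suppressWarnings({
    r <- pROC::roc(response = factor(isPos, levels = c(FALSE, TRUE)),
                   predictor = values, quiet = TRUE,
                   direction = if (direction == "greater") "<" else ">")
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))
  orRes <- tryCatch(
    thresholdOddsRatio(values, labels, thr, direction, positive),
    error = function(e) list(or = NA_real_, ci = c(NA_real_, NA_real_),
                             p = NA_real_, corrected = NA))
  list(auc = auc, auc_ci = ci, threshold = thr,
       sensitivity = sens[bestIdx], specificity = spec[bestIdx],
       direction = direction, n_pos = sum(isPos), n_neg = sum(!isPos),
       or = orRes$or, or_ci = orRes$ci, or_p = orRes$p)
}

#' Threshold-based odds ratio from univariate logistic regression
#'
#' Dichotomizes the feature at the threshold (in the stated direction) and
#' fits a univariate logistic regression of the positive class on the
#' indicator: OR = exp(coefficient) with a Wald 95% CI.  When the 2x2
#' table has a zero cell, the Haldane-Anscombe 0.5 correction is applied
#' to the equivalent table and flagged.
#'
#' @param values numeric feature vector.
#' @param labels group labels.
#' @param threshold cut value.
#' @param direction "greater": indicator is value > threshold; "less":
#'   value < threshold.
#' @param positive the positive class.
#' @return list: or, ci (length 2), p, corrected flag.
#' @export
thresholdOddsRatio <- function(values, labels, threshold,
                               direction = c("greater", "less"),
                               positive = "metastasis") {
  direction <- match.arg(direction)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  ind <- if (direction == "greater") values > threshold
         else values < threshold
  if (all(ind) || all(!ind))
    stop("degenerate dichotomization: all values on one side")
  y <- as.integer(labels == positive)
  tab <- table(factor(ind, c(FALSE, TRUE)), factor(y, c(0, 1)))
  if (any(tab == 0)) {
    t2 <- tab + 0.5
    logor <- log(t2[2, 2] * t2[1, 1] / (t2[1, 2] * t2[2, 1]))
    se <- sqrt(sum(1 / t2))
    list(or = exp(logor),
         ci = exp(logor + c(-1, 1) * qnorm(0.975) * se),
         p = 2 * pnorm(-abs(logor / se)), corrected = TRUE)
  } else {
    fit <- stats::glm(y ~ ind, family = stats::binomial())
    co <- summary(fit)$coefficients["indTRUE", ]
    list(or = exp(co["Estimate"]),
         ci = exp(co["Estimate"] + c(-1, 1) * qnorm(0.975) *
                  co["Std. Error"]),
         p = unname(co["Pr(>|z|)"]), corrected = FALSE)
  }
}

.featureTissue <- function(nm) {
  parts <- strsplit(nm, "_")[[1]]
  if (parts[1] == "vol") parts[2] else parts[2]
}

#' Univariate group comparison of all features
#'
#' For each of the 135 features: absent (NA) entries are skipped, groups
#' are compared by the Wilcoxon rank-sum test, q-values are
#' Benjamini-Hochberg adjusted over all testable features as one family,
#' and ROC threshold analysis plus the threshold odds ratio are computed.
#' Features absent in an entire group are marked not computable.  The ROC
#' table is sorted within each tissue by sensitivity + specificity, the
#' way the most discriminative parameters per tissue are usually listed.
#'
#' @param table feature table (id, label, 135 feature columns).
#' @param positive the positive class (default "metastasis").
#' @return list: \code{univariate} data.frame (feature, n per group,
#'   medians and IQRs per group, p, q, significant) and \code{roc}
#'   data.frame (feature, tissue, threshold, direction, auc + CI,
#'   sensitivity, specificity, or + CI, or_p).
#' @export
compareGroups <- function(table, positive = "metastasis") {
  feats <- intersect(featureNames(), names(table))
  labs <- table$label
  groups <- unique(labs)
  if (length(groups) != 2) stop("both groups must be present")
  neg <- setdiff(groups, positive)
  uni <- lapply(feats, function(nm) {
    xs <- table[[nm]][labs == neg]
    ys <- table[[nm]][labs == positive]
    xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
    row <- data.frame(feature = nm, n_neg = length(xs), n_pos = length(ys),
                      median_neg = NA_real_, q25_neg = NA_real_,
                      q75_neg = NA_real_, median_pos = NA_real_,
                      q25_pos = NA_real_, q75_pos = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    if (length(xs)) {
      q <- stats::quantile(xs, c(0.25, 0.5, 0.75))
      row[c("q25_neg", "median_neg", "q75_neg")] <- q
    }
    if (length(ys)) {
      q <- stats::quantile(ys, c(0.25, 0.5, 0.75))
      row[c("q25_pos", "median_pos", "q75_pos")] <- q
    }
    if (length(xs) && length(ys)) row$p <- wilcoxonRankSum(xs, ys)
    row
  })
  uni <- do.call(rbind, uni)
  uni$q <- NA_real_
  testable <- !is.na(uni$p)
  uni$q[testable] <- bhFdr(uni$p[testable])
  uni$significant <- !is.na(uni$q) & uni$q < 0.05
  roc <- lapply(feats, function(nm) {
    vals <- table[[nm]]
    ok <- is.finite(vals)
    if (length(unique(labs[ok])) != 2 || length(unique(vals[ok])) < 2)
      return(NULL)
    r <- rocAnalysis(vals, labs, positive)
    data.frame(feature = nm, tissue = .featureTissue(nm),
               threshold = r$threshold, direction = r$direction,
               auc = r$auc, auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               or = r$or, or_lo = r$or_ci[1], or_hi = r$or_ci[2],
               or_p = r$or_p, stringsAsFactors = FALSE)
  })
  roc <- do.call(rbind, roc)
  if (!is.null(roc)) {
    roc <- roc[order(roc$tissue,
                     -(roc$sensitivity + roc$specificity)), ]
    rownames(roc) <- NULL
  }
  list(univariate = uni, roc = roc)
}
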