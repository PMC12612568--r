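#' Dice similarity coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|).  Two empty masks are defined as perfectly
#' agreeing (1.0) with attribute \code{bothEmpty = TRUE}.
#'
#' @param a,b logical (or 0/1) arrays on one grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(structure(1, bothEmpty = TRUE))
  2 * sum(a & b) / denom
}

# directed mean nearest-neighbor distance between voxel-center point sets,
# chunked to bound memory
.directedAvg <- function(A, B) {
  step <- max(1L, floor(2e6 / nrow(B)))
  mins <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = step)) {
    i <- s:min(s + step - 1, nrow(A))
    d2 <- outer(rowSums(A[i, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[i, , drop = FALSE] %*% t(B)
    mins[i] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  mean(mins)
}

#' Average Hausdorff distance between two masks
#'
#' The maximum of the two directed average distances,
#' d(A,B) = mean over a in A of min over b in B of ||a - b||, computed on
#' voxel centers in physical millimeters (the convention of the standard
#' segmentation-evaluation tooling).  The symmetric-mean variant
#' (|A|,|B|-weighted mean of both directed sums) is available via
#' \code{variant = "mean"}.
#'
#' @param a,b non-empty masks on one grid.
#' @param voxelDims numeric length-3 voxel size (mm).
#' @param variant "max" (default) or "mean".
#' @return distance in mm.
#' @export
averageHausdorff <- function(a, b, voxelDims, variant = c("max", "mean")) {
  variant <- match.arg(variant)
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  if (!any(a != 0) || !any(b != 0))
    stop("average Hausdorff distance is undefined for an empty mask")
  coord <- function(m) {
    idx <- which(m != 0, arr.ind = TRUE)
    sweep(idx, 2, voxelDims, "*")
  }
  A <- coord(a); B <- coord(b)
  dab <- .directedAvg(A, B)
  dba <- .directedAvg(B, A)
  if (variant == "max") max(dab, dba)
  else (nrow(A) * dab + nrow(B) * dba) / (nrow(A) + nrow(B))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from the
#' two-way ANOVA mean squares of two raters' paired ratings, with the
#' F-based 95% confidence interval and p-value.
#'
#' @param ratingsA,ratingsB numeric vectors, paired by subject, length >= 3.
#' @param conf confidence level (default 0.95).
#' @return list: icc, ci (lower, upper), p, and the ANOVA mean squares.
#'   icc is NA (undefined) when the between-subject variance is zero.
#' @export
icc <- function(ratingsA, ratingsB, conf = 0.95) {
  if (length(ratingsA) != length(ratingsB))
    stop("ratings must be paired (equal length)")
  n <- length(ratingsA)
  if (n < 3) stop("need at least 3 paired subjects")
  x <- cbind(ratingsA, ratingsB)
  k <- 2
  rowM <- rowMeans(x); colM <- colMeans(x); gm <- mean(x)
  SSr <- k * sum((rowM - gm)^2)
  SSc <- n * sum((colM - gm)^2)
  SSe <- sum((x - outer(rowM, rep(1, k)) -
              outer(rep(1, n), colM) + gm)^2)
  MSr <- SSr / (n - 1)
  MSc <- SSc / (k - 1)
  MSe <- SSe / ((n - 1) * (k - 1))
  if (MSr <= .Machine$double.eps * max(1, abs(gm)))
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                MSr = MSr, MSc = MSc, MSe = MSe))
  coeff <- (MSr - MSe) / (MSr + (k - 1) * MSe + k / n * (MSc - MSe))
  alpha <- 1 - conf
  Fvalue <- MSr / MSe
  p <- stats::pf(Fvalue, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  aC <- k * coeff / (n * (1 - coeff))
  bC <- 1 + k * coeff * (n - 1) / (n * (1 - coeff))
  v <- (aC * MSc + bC * MSe)^2 /
    ((aC * MSc)^2 / (k - 1) + (bC * MSe)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lb <- n * (MSr - FL * MSe) /
    (FL * (k * MSc + (k * n - k - n) * MSe) + n * MSr)
  ub <- n * (FU * MSr - MSe) /
    (k * MSc + (k * n - k - n) * MSe + n * FU * MSr)
  list(icc = coeff, ci = c(lb, ub), p = p, MSr = MSr, MSc = MSc, MSe = MSe)
}

#' Inter-rater agreement report
#'
#' Per-tissue Dice and average Hausdorff distance between two raters'
#' masks, and per-feature ICC(2,1) between two raters' feature tables.
#'
#' @param masksA,masksB lists of \linkS4class{TissueMasks} (same subjects,
#'   same order).
#' @param featuresA,featuresB feature tables from the two raters (matched
#'   by row).
#' @return list: \code{masks} data.frame (subject, tissue, dice, ahd) and
#'   \code{features} data.frame (feature, icc, lower, upper, p, n).
#' @export
agreementReport <- function(masksA = NULL, masksB = NULL,
                            featuresA = NULL, featuresB = NULL) {
  maskDf <- NULL
  if (!is.null(masksA)) {
    stopifnot(length(masksA) == length(masksB))
    rows <- list()
    for (i in seq_along(masksA)) {
      for (tis in TISSUES) {
        ma <- tissueMask(masksA[[i]], tis)
        mb <- tissueMask(masksB[[i]], tis)
        ahd <- if (any(ma) && any(mb))
          averageHausdorff(ma, mb, masksA[[i]]@voxelDims) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, tissue = tis, dice = as.numeric(dice(ma, mb)),
          ahd = ahd)
      }
    }
    maskDf <- do.call(rbind, rows)
  }
  featDf <- NULL
  if (!is.null(featuresA)) {
    feats <- intersect(intersect(featureNames(), names(featuresA)),
                       names(featuresB))
    rows <- lapply(feats, function(nm) {
      a <- featuresA[[nm]]; b <- featuresB[[nm]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3)
        return(data.frame(feature = nm, icc = NA_real_, lower = NA_real_,
                          upper = NA_real_, p = NA_real_, n = sum(ok)))
      r <- icc(a[ok], b[ok])
      data.frame(feature = nm, icc = r$icc, lower = r$ci[1],
                 upper = r$ci[2], p = r$p, n = sum(ok))
    })
    featDf <- do.call(rbind, rows)
  }
  list(masks = maskDf, features = featDf)
}
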