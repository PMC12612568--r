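#' Default IVIM/kurtosis fitting options
#'
#' Bounds bracket reported tumor and brain values with margin; the
#' separation factor keeps the pseudo-diffusion compartment identifiably
#' faster than tissue diffusion.  The start grid is deterministic (no RNG in
#' fitting), so maps are bit-reproducible.
#'
#' @param dBounds bounds on D (mm^2/s).
#' @param dstarBounds bounds on D* (mm^2/s).
#' @param separation minimum D*/D ratio.
#' @param gridN per-axis size of the coarse log-spaced start grid.
#' @param nStarts number of grid starts refined by Nelder-Mead.
#' @param maxit Nelder-Mead iteration cap.
#' @param smoothingSigma Gaussian sigma (voxels) applied to each b-volume
#'   before the kurtosis fit only.
#' @param kBounds bounds enforced on diffusion kurtosis K.
#' @param method "varpro" (one-step variable projection, default) or
#'   "two-step" (high-b monoexponential first; comparison only).
#' @param bThreshold b-value (s/mm^2) above which the two-step mode treats
#'   the decay as monoexponential.
#' @return list of options for \code{\link{fitIvimVoxel}} /
#'   \code{\link{fitMaps}}.
#' @export
fitOptions <- function(dBounds = c(1e-6, 4e-3), dstarBounds = c(1e-3, 0.5),
                       separation = 3, gridN = 60, nStarts = 2, maxit = 100,
                       smoothingSigma = 5, kBounds = c(0, 3),
                       method = c("varpro", "two-step"), bThreshold = 200) {
  list(dBounds = dBounds, dstarBounds = dstarBounds, separation = separation,
       gridN = as.integer(gridN), nStarts = as.integer(nStarts),
       maxit = as.integer(maxit), smoothingSigma = smoothingSigma,
       kBounds = kBounds, method = match.arg(method),
       bThreshold = bThreshold)
}

# matrix interface: Y is nb x nvox, returns 7 x nvox (f, D, Dstar, S0,
# resid, valid, degenerate)
.fitIvimMat <- function(Y, b, opt) {
  if (opt$method == "two-step") {
    return(apply(Y, 2, .fitIvimTwoStep, b = b, opt = opt))
  }
  .cpp_fit_ivim(Y, b, opt$dBounds[1], opt$dBounds[2],
                opt$dstarBounds[1], opt$dstarBounds[2], opt$separation,
                opt$gridN, opt$nStarts, opt$maxit)
}

.fitIvimTwoStep <- function(y, b, opt) {
  out <- c(0, 0, 0, 0, 0, 0, 0)
  hi <- b >= opt$bThreshold
  if (any(y <= 0) || sum(hi) < 2) return(out)
  cf <- stats::lm.fit(cbind(1, -b[hi]), log(y[hi]))$coefficients
  D <- min(max(cf[2], opt$dBounds[1]), opt$dBounds[2])
  s0d <- exp(cf[1])                       # (1-f) * S0
  s0 <- y[b == 0][1]
  f <- min(max(1 - s0d / s0, 0), 1)
  rss <- function(ds) {
    th <- cbind(exp(-b * ds), exp(-b * D))
    sum(stats::lm.fit(th, y)$residuals^2)
  }
  o <- stats::optimize(rss, lower = max(opt$dstarBounds[1], opt$separation * D),
                       upper = opt$dstarBounds[2])
  c(f, D, o$minimum, s0, sqrt(o$objective), 1, as.numeric(f <= 1e-3))
}

#' Fit the IVIM model to a single voxel by variable projection
#'
#' Separable nonlinear least squares: for candidate decay rates (D*, D) the
#' model is linear in the non-negative amplitudes (S0 f, S0 (1-f)), solved
#' in closed form; the outer bounded 2D problem is solved by a deterministic
#' multi-start (coarse log grid + Nelder-Mead refinement) with the
#' constraint D* >= separation * D.
#'
#' @param signal signal vector over the scheme (b=0 first).
#' @param scheme a \linkS4class{BValueScheme}.
#' @param options see \code{\link{fitOptions}}.
#' @return list with S0, f, Dstar, D (mm^2/s), residual (norm), valid
#'   (FALSE for unusable voxels, e.g. all-zero signal) and degenerate
#'   (TRUE when f is at a boundary so D* is unidentifiable).
#' @export
fitIvimVoxel <- function(signal, scheme, options = fitOptions()) {
  if (length(signal) != length(scheme@bvalues))
    stop("signal length must equal scheme length")
  r <- .fitIvimMat(matrix(signal, ncol = 1), scheme@bvalues, options)
  list(S0 = r[4, 1], f = r[1, 1], Dstar = r[3, 1], D = r[2, 1],
       residual = r[5, 1], valid = r[6, 1] == 1, degenerate = r[7, 1] == 1)
}

# matrix kurtosis fit: Y nb x nvox positive signals; returns 6 x nvox
# (S0, Dk, K, resid, valid, clipped)
.fitKurtosisMat <- function(Y, b, opt) {
  nv <- ncol(Y)
  out <- matrix(0, 6, nv)
  ok <- colSums(Y <= 0 | !is.finite(Y)) == 0
  if (any(ok)) {
    X <- cbind(1, b, b^2)
    L <- log(Y[, ok, drop = FALSE])
    cf <- qr.solve(X, L)                       # least squares, shared design
    c0 <- cf[1, ]; c1 <- cf[2, ]; c2 <- cf[3, ]
    dk <- -c1
    decaying <- c1 < 0
    K <- ifelse(decaying, 6 * c2 / c1^2, NA_real_)
    clipped <- decaying & (K < opt$kBounds[1] | K > opt$kBounds[2])
    Kc <- pmin(pmax(K, opt$kBounds[1]), opt$kBounds[2])
    res <- sqrt(colSums((L - X %*% cf)^2))
    idx <- which(ok)
    # constrained refit of (S0, D) with K fixed at its bound
    for (j in which(clipped)) {
      kb <- Kc[j]
      l <- L[, j]
      rssD <- function(d) {
        m <- -b * d + b^2 * d^2 * kb / 6
        sum((l - m - mean(l - m))^2)
      }
      o <- stats::optimize(rssD, lower = 1e-6, upper = 5e-3)
      dk[j] <- o$minimum
      m <- -b * dk[j] + b^2 * dk[j]^2 * kb / 6
      c0[j] <- mean(l - m)
      res[j] <- sqrt(o$objective)
    }
    out[1, idx] <- exp(c0)
    out[2, idx] <- pmax(dk, 0)
    out[3, idx] <- Kc
    out[4, idx] <- res
    out[5, idx] <- as.numeric(decaying)
    out[6, idx] <- as.numeric(clipped)
    out[3, idx[!decaying]] <- 0
  }
  out
}

#' Fit the kurtosis model to a single voxel in the log domain
#'
#' Fits ln S(b) = c0 + c1 b + c2 b^2 by unweighted least squares over all
#' b-values, then maps D = -c1 and K = 6 c2 / c1^2.  K is clipped to the
#' fitting bounds (default [0, 3]); when clipping occurs, S0 and D are
#' refit with K held at the bound and the clip is flagged.
#'
#' @param signal positive signal vector over the scheme.
#' @param scheme a \linkS4class{BValueScheme} with >= 3 distinct b-values.
#' @param options see \code{\link{fitOptions}}.
#' @return list with S0, D (mm^2/s), K, residual (log-domain norm), valid,
#'   clipped.
#' @export
fitKurtosisVoxel <- function(signal, scheme, options = fitOptions()) {
  if (length(signal) != length(scheme@bvalues))
    stop("signal length must equal scheme length")
  if (length(unique(scheme@bvalues)) < 3)
    stop("kurtosis fit needs at least 3 distinct b-values")
  r <- .fitKurtosisMat(matrix(signal, ncol = 1), scheme@bvalues, options)
  list(S0 = r[1, 1], D = r[2, 1], K = r[3, 1], residual = r[4, 1],
       valid = r[5, 1] == 1, clipped = r[6, 1] == 1)
}

#' Fit voxelwise parameter maps for a DWI series
#'
#' The IVIM variable-projection fit runs on the unsmoothed signals; the
#' kurtosis fit runs on signals Gaussian-smoothed spatially per b-volume
#' (default sigma 5 voxels).  The D map kept for downstream statistics is
#' the IVIM D.  The validity mask marks voxels where both fits succeeded.
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param mask logical 3D array of voxels to fit (default: the series'
#'   brain mask).  Must contain at least one voxel.
#' @param options see \code{\link{fitOptions}}.
#' @return A \linkS4class{ParameterMaps}.
#' @export
fitMaps <- function(dwi, mask = dwi@brainMask, options = fitOptions()) {
  gridShape <- dim(dwi@signal)[1:3]
  if (!identical(dim(mask), gridShape))
    stop("mask must match the DWI spatial grid")
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  nb <- length(dwi@scheme@bvalues)
  flat <- matrix(dwi@signal, prod(gridShape), nb)
  Y <- t(flat[idx, , drop = FALSE])
  iv <- .fitIvimMat(Y, dwi@scheme@bvalues, options)
  sm <- dwi@signal
  if (options$smoothingSigma > 0)
    for (j in seq_len(nb))
      sm[, , , j] <- gaussianSmooth3d(dwi@signal[, , , j],
                                      options$smoothingSigma)
  Ys <- t(matrix(sm, prod(gridShape), nb)[idx, , drop = FALSE])
  ku <- .fitKurtosisMat(Ys, dwi@scheme@bvalues, options)
  mkMap <- function(vals) {
    m <- array(NA_real_, gridShape)
    m[idx] <- vals
    m
  }
  valid <- array(FALSE, gridShape)
  valid[idx] <- iv[6, ] == 1 & ku[5, ] == 1
  new("ParameterMaps",
      f = mkMap(iv[1, ]), D = mkMap(iv[2, ]), Dstar = mkMap(iv[3, ]),
      K = mkMap(ku[3, ]), S0 = mkMap(iv[4, ]),
      residual = mkMap(sqrt(iv[5, ]^2 + ku[4, ]^2)),
      valid = valid, voxelDims = dwi@voxelDims)
}

setMethod("show", "ParameterMaps", function(object) {
  cat("ParameterMaps:", paste(dim(object@f), collapse = "x"), "grid,",
      sum(object@valid), "valid voxels\n")
})

#' @describeIn fitMaps validity mask accessor
#' @param x a ParameterMaps.
#' @export
validMask <- function(x) x@valid

#' Extract one parameter volume from ParameterMaps
#'
#' @param x a \linkS4class{ParameterMaps}.
#' @param param one of "f", "D", "Dstar", "K", "S0", "residual".
#' @return numeric 3D array (NA outside the fitted set).
#' @export
parameterMap <- function(x, param = c("f", "D", "Dstar", "K", "S0",
                                      "residual")) {
  slot(x, match.arg(param))
}
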