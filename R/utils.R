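#' Separable 3D Gaussian smoothing
#'
#' Normalized Gaussian convolution along each axis (edge effects handled by
#' renormalizing the kernel mass inside the grid), as used to pre-smooth
#' per-b volumes before the kurtosis-model fit.
#'
#' @param x numeric 3D array.
#' @param sigma kernel standard deviation in voxels (scalar or length 3);
#'   0 returns \code{x} unchanged.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3)
  sigma <- rep_len(sigma, 3L)
  if (all(sigma <= 0)) return(x)
  smoothMat <- function(n, s) {
    if (s <= 0) return(diag(n))
    idx <- seq_len(n)
    M <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * s^2)))
    M / rowSums(M)
  }
  d <- dim(x)
  M1 <- smoothMat(d[1], sigma[1])
  M2 <- smoothMat(d[2], sigma[2])
  M3 <- smoothMat(d[3], sigma[3])
  # contract each axis in turn
  y <- array(M1 %*% matrix(x, d[1]), d)
  y <- aperm(array(M2 %*% matrix(aperm(y, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  y <- aperm(array(M3 %*% matrix(aperm(y, c(3, 1, 2)), d[3]),
                   c(d[3], d[1], d[2])), c(2, 3, 1))
  y
}

# voxel-center coordinates (mm) for a grid, one row per voxel in array order
.voxelCoords <- function(gridShape, voxelDims) {
  ax <- lapply(1:3, function(k) (seq_len(gridShape[k]) - 0.5) * voxelDims[k])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
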