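# Independent oracles and small fixture builders used across the suite.

# Rician magnitude signal with per-b averaging, written independently of the
# phantom module (direct transcription of the noise model).
riceAveraged <- function(clean, nav, sd) {
  vapply(seq_along(clean), function(j) {
    mean(sqrt((clean[j] + rnorm(nav[j], 0, sd))^2 +
              rnorm(nav[j], 0, sd)^2))
  }, 0)
}

# brute-force variable-projection residual on a (Dstar, D) log grid;
# independent R implementation of the separable NNLS objective
gridSearchIvim <- function(y, b, n = 50, dBounds = c(1e-6, 4e-3),
                           dstarBounds = c(1e-3, 0.5), sep = 3) {
  ldg <- seq(log(dBounds[1]), log(dBounds[2]), length.out = n)
  lsg <- seq(log(dstarBounds[1]), log(dstarBounds[2]), length.out = n)
  best <- list(rss = Inf)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (lsg[j] < ldg[i] + log(sep)) next
      e1 <- exp(-b * exp(lsg[j])); e2 <- exp(-b * exp(ldg[i]))
      A <- cbind(e1, e2)
      th <- tryCatch(qr.solve(A, y), error = function(e) c(-1, -1))
      if (any(th < 0)) {
        t2 <- max(sum(e2 * y) / sum(e2 * e2), 0)
        r2 <- sum((y - t2 * e2)^2)
        t1 <- max(sum(e1 * y) / sum(e1 * e1), 0)
        r1 <- sum((y - t1 * e1)^2)
        if (r2 <= r1) { th <- c(0, t2); rss <- r2 }
        else { th <- c(t1, 0); rss <- r1 }
      } else rss <- sum((y - A %*% th)^2)
      if (rss < best$rss)
        best <- list(rss = rss, D = exp(ldg[i]), Dstar = exp(lsg[j]),
                     f = th[1] / max(th[1] + th[2], 1e-300))
    }
  }
  best
}

# brute-force Benjamini-Hochberg: q_i = min over tail of p_(j) * m / j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    q[i] <- min(vapply(r:m, function(j) p[o[j]] * m / j, 0), 1)
  }
  q
}

# trapezoidal area under the empirical ROC curve
trapezoidAuc <- function(values, isPos) {
  cuts <- c(-Inf, sort(unique(values)), Inf)
  sens <- vapply(cuts, function(t) mean(values[isPos] > t), 0)
  fpr <- vapply(cuts, function(t) mean(values[!isPos] > t), 0)
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
}

# build a DWISeries directly from voxelwise parameter arrays and a forward
# model ("ivim", "kurtosis" or "joint"), bypassing the phantom module
makeSeries <- function(gridShape, scheme, S0, f, Dstar, D, K,
                       model = "joint", voxelDims = c(2, 2, 2)) {
  expand <- function(x) if (length(x) == 1) array(x, gridShape) else x
  f <- expand(f); Dstar <- expand(Dstar); D <- expand(D); K <- expand(K)
  S0 <- expand(S0)
  b <- bValues(scheme)
  sig <- array(0, c(gridShape, length(b)))
  for (j in seq_along(b)) {
    sig[, , , j] <- switch(model,
      ivim = S0 * (f * exp(-b[j] * Dstar) + (1 - f) * exp(-b[j] * D)),
      kurtosis = S0 * exp(-b[j] * D + b[j]^2 * D^2 * K / 6),
      joint = S0 * (f * exp(-b[j] * Dstar) +
                    (1 - f) * exp(-b[j] * D + b[j]^2 * D^2 * K / 6)))
  }
  new("DWISeries", signal = sig, scheme = scheme,
      voxelDims = voxelDims, brainMask = array(TRUE, gridShape),
      truth = list())
}

# a SubjectTruth with explicit anchors, bypassing calibration sampling
makeTruth <- function(group = "HGG", f = c(0.2, 0.25, 0.2),
                      D = c(774.5e-6, 932e-6, 950e-6),
                      Dstar = c(5975.5e-6, 4798e-6, 5053e-6),
                      K = c(0.76, 0.65, 0.63),
                      volumes = c(12, 8, 40),
                      presence = c(TRUE, TRUE, TRUE), jitterSd = 0.1) {
  tissues <- c("enhancing", "non_enhancing", "edema")
  anchors <- cbind(f = f, D = D, Dstar = Dstar, K = K)
  rownames(anchors) <- tissues
  new("SubjectTruth", group = group, anchors = anchors,
      volumes = setNames(volumes, tissues),
      presence = setNames(presence, tissues), jitterSd = jitterSd)
}

# cube mask helper: side^3 voxels centered in the grid
cubeMask <- function(gridShape, side, center = round(gridShape / 2)) {
  m <- array(FALSE, gridShape)
  h <- floor(side / 2)
  lo <- center - h
  idx <- lapply(1:3, function(k) lo[k] + seq_len(side) - 1)
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

# run the full analysis chain on one simulated two-cohort replicate;
# returns q-values of the generator-separated features and the held-out
# confusion statistics
runEndToEnd <- function(seed, nHgg = 67, nMeta = 30, nHggV = 9, nMetaV = 8,
                        gridShape = c(20, 20, 20), voxelDims = c(6, 6, 6),
                        snr = 40) {
  opt <- fitOptions(smoothingSigma = 1)
  ext <- function(co) buildFeatureTable(lapply(co$subjects, function(s) {
    lesion <- s$masks@enhancing | s$masks@nonEnhancing | s$masks@edema
    mp <- fitMaps(s$dwi, lesion, opt)
    suppressWarnings(extractFeatures(mp, s$masks, s$id, s$label))
  }))
  train <- generateCohort(nHgg, nMeta, masterSeed = seed, snr = snr,
                          gridShape = gridShape, voxelDims = voxelDims)
  valid <- generateCohort(nHggV, nMetaV, masterSeed = seed + 500000L,
                          snr = snr, gridShape = gridShape,
                          voxelDims = voxelDims)
  tabT <- ext(train); tabV <- ext(valid)
  u <- compareGroups(tabT)$univariate
  qs <- vapply(c("K_enh_median", "D_enh_median", "f_edema_median"),
               function(nm) u$q[u$feature == nm], 0)
  tabTi <- imputeMissingZero(tabT)
  sel <- lassoSelect(tabTi, nFolds = 10, seed = seed)
  feats <- if (length(sel$selected)) sel$selected else publishedTreeFeatures()
  model <- fitDecisionTree(tabTi, features = feats)
  ev <- evaluateTree(model, imputeMissingZero(tabV))
  list(q = qs, sensitivity = ev$sensitivity, specificity = ev$specificity,
       nSelected = length(sel$selected),
       nSignificant = sum(u$significant, na.rm = TRUE))
}
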