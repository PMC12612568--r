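## Synthetic phantom cohorts: subject anchors, lesion geometry, noisy
## multi-b signals.  Anchor distributions are matched to a calibration by
## median and IQR: log-normal for D, D*, volumes (positive, right-skewed),
## logit-normal for f, truncated normal for K.

.IQR_Z <- 2 * qnorm(0.75)  # 25th..75th percentile span in SD units

# physiologic truncation applied to sampled anchors, in the units the
# anchors are drawn in (D, Dstar in 1e-6 mm^2/s; volume in mL)
.PHYS_BOUNDS <- list(f = c(0.01, 0.95), D = c(50, 4000),
                     Dstar = c(1000, 1e5), K = c(0.01, 3),
                     volume = c(0.05, 200))

.sampleAnchor <- function(param, med, q25, q75) {
  b <- .PHYS_BOUNDS[[param]]
  x <- switch(param,
    f = plogis(rnorm(1, qlogis(med),
                     (qlogis(q75) - qlogis(q25)) / .IQR_Z)),
    K = rnorm(1, med, (q75 - q25) / .IQR_Z),
    {
      sdlog <- if (q25 > 0) log(q75 / q25) / .IQR_Z
               else log(q75 / med) / qnorm(0.75)
      exp(rnorm(1, log(med), sdlog))
    })
  min(max(x, b[1]), b[2])
}

#' Draw per-subject ground-truth tissue anchors
#'
#' Samples, for one synthetic subject, scalar per-tissue anchors of f, D,
#' D* and K plus target tissue volumes from distributions whose median and
#' interquartile range match the group calibration, truncated to physiologic
#' bounds.  Enhancing tumor and edema are always present; the non-enhancing
#' compartment is absent with the calibrated group-specific probability.
#'
#' @param group "HGG" or "metastasis".
#' @param calibration a \linkS4class{GroupCalibration}.
#' @param seed integer seed (NULL: use current RNG state).
#' @param jitterSd relative SD of within-tissue voxelwise jitter (stored on
#'   the subject; applied by \code{\link{synthesizeDwi}}).
#' @return A \linkS4class{SubjectTruth}.
#' @export
sampleSubjectParams <- function(group, calibration, seed = NULL,
                                jitterSd = 0.1) {
  if (!group %in% c("HGG", "metastasis"))
    stop("unknown group label: ", group)
  validObject(calibration)
  .withSeed(seed, {
    presence <- c(enhancing = TRUE, non_enhancing = TRUE, edema = TRUE)
    ap <- calibration@absenceProb
    presence["non_enhancing"] <-
      runif(1) >= (if ("non_enhancing" %in% names(ap)) ap[["non_enhancing"]] else 0)
    anchors <- matrix(NA_real_, 3, 4, dimnames = list(TISSUES, DIFF_PARAMS))
    for (tis in TISSUES) {
      for (par in DIFF_PARAMS) {
        row <- calibration@params[calibration@params$tissue == tis &
                                  calibration@params$param == par, ]
        scale <- if (par %in% c("D", "Dstar")) 1e-6 else 1
        anchors[tis, par] <-
          .sampleAnchor(par, row$median, row$q25, row$q75) * scale
      }
      # keep the fast compartment clearly faster than tissue diffusion
      anchors[tis, "Dstar"] <- max(anchors[tis, "Dstar"], 3 * anchors[tis, "D"])
    }
    volumes <- c(enhancing = NA_real_, non_enhancing = NA_real_,
                 edema = NA_real_)
    for (tis in TISSUES) {
      row <- calibration@volumes[calibration@volumes$tissue == tis, ]
      volumes[tis] <- if (presence[tis])
        .sampleAnchor("volume", max(row$median, 0.1), row$q25, row$q75) else 0
    }
    new("SubjectTruth", group = group, anchors = anchors,
        volumes = volumes, presence = presence, jitterSd = jitterSd)
  })
}

setMethod("show", "SubjectTruth", function(object) {
  cat("SubjectTruth [", object@group, "], tissues present:",
      paste(TISSUES[object@presence], collapse = ", "), "\n")
  a <- object@anchors
  a[, c("D", "Dstar")] <- a[, c("D", "Dstar")] * 1e6
  print(round(cbind(a, volume_mL = object@volumes), 3))
})

#' Build concentric deformed-ellipsoid lesion masks
#'
#' Places a randomly oriented, randomly deformed ellipsoidal lesion at the
#' grid center: a non-enhancing core inside an enhancing shell inside an
#' edema rim.  Compartment voxel counts match the subject's target volumes
#' exactly (nearest whole voxel); the compartments are nested level sets of
#' one deformed radial field, hence pairwise disjoint with connected union.
#'
#' @param truth a \linkS4class{SubjectTruth}.
#' @param gridShape integer length-3 grid dimensions.
#' @param voxelDims numeric length-3 voxel size (mm).
#' @param seed integer seed (NULL: current RNG state).
#' @return A \linkS4class{TissueMasks}.
#' @export
buildLesionGeometry <- function(truth, gridShape = c(64, 64, 64),
                                voxelDims = c(2, 2, 2), seed = NULL) {
  gridShape <- as.integer(gridShape)
  voxvol <- prod(voxelDims)
  counts <- vapply(TISSUES, function(tis) {
    if (!truth@presence[[tis]]) 0L
    else max(1L, as.integer(round(truth@volumes[[tis]] * 1000 / voxvol)))
  }, integer(1))
  nTot <- sum(counts)
  if (nTot > prod(gridShape))
    stop("requested volume exceeds grid capacity (", nTot, " voxels needed)")
  .withSeed(seed, {
    fov <- gridShape * voxelDims
    center <- fov / 2 + runif(3, -1, 1) * voxelDims
    co <- sweep(.voxelCoords(gridShape, voxelDims), 2, center)
    # random orientation and axis ratios
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    axes <- exp(rnorm(3, 0, 0.2))
    axes <- axes / prod(axes)^(1/3)
    z <- co %*% R
    r <- sqrt((z[, 1] / axes[1])^2 + (z[, 2] / axes[2])^2 +
              (z[, 3] / axes[3])^2)
    # smooth direction-dependent deformation (random quadratic form on the
    # unit sphere), bounded away from collapsing the radius
    E <- matrix(rnorm(9, 0, 0.1), 3); E <- (E + t(E)) / 2
    u <- z / pmax(r, 1e-9)
    pert <- rowSums((u %*% E) * u)
    r <- r * pmax(1 + pert, 0.6)
    ord <- order(r)
    sel <- ord[seq_len(nTot)]
    # reject lesions clipped by the grid boundary
    idx <- arrayInd(sel, gridShape)
    if (nTot > 0 && (any(idx == 1L) ||
        any(sweep(idx, 2, gridShape) == 0L)))
      stop("requested volume exceeds grid capacity (lesion touches boundary)")
    mk <- function(which) {
      m <- array(FALSE, gridShape)
      m[which] <- TRUE
      m
    }
    n1 <- counts[["non_enhancing"]]
    n2 <- n1 + counts[["enhancing"]]
    new("TissueMasks",
        nonEnhancing = mk(sel[seq_len(n1)]),
        enhancing = mk(sel[seq(n1 + 1L, length.out = counts[["enhancing"]])]),
        edema = mk(sel[seq(n2 + 1L, length.out = counts[["edema"]])]),
        voxelDims = as.numeric(voxelDims),
        provenance = "synthetic concentric deformed ellipsoids")
  })
}

#' Synthesize a noisy multi-b DWI series for one subject
#'
#' Per voxel the ground truth is the tissue anchor times a multiplicative
#' log-normal jitter field; the noiseless signal follows the joint forward
#' model \deqn{S(b) = S0 [ f e^{-b D^*} + (1-f) e^{-b D + b^2 D^2 K / 6} ]}
#' so that a single voxel is consistent with both the IVIM and the kurtosis
#' analysis.  Noise is Rician: the magnitude of complex Gaussian noise with
#' sd = S0ref/snr, drawn independently per signal average, and the stored
#' signal is the mean of the per-average magnitudes (magnitude-domain
#' averaging, as on the scanner, so the high-b noise floor is reproduced).
#' Ground-truth parameter volumes are retained in the result's \code{truth}.
#'
#' @param truth a \linkS4class{SubjectTruth}.
#' @param masks a \linkS4class{TissueMasks} from \code{buildLesionGeometry}.
#' @param scheme a \linkS4class{BValueScheme}.
#' @param snr signal-to-noise ratio at b=0 per single average
#'   (\code{Inf} for noiseless).
#' @param backgroundParams named numeric (f, D, Dstar, K; mm^2/s) for
#'   normal-appearing brain outside the lesion.
#' @param seed integer seed (NULL: current RNG state).
#' @param s0 b=0 signal level inside the brain.
#' @param jitterCorrelationSigma optional Gaussian sigma (voxels) used to
#'   spatially correlate the log-jitter field; 0 = independent voxels.
#' @return A \linkS4class{DWISeries} with ground-truth maps in \code{truth}.
#' @export
synthesizeDwi <- function(truth, masks, scheme = paperBScheme(), snr = 40,
                          backgroundParams = c(f = 0.08, D = 800e-6,
                                               Dstar = 5000e-6, K = 0.7),
                          seed = NULL, s0 = 1000,
                          jitterCorrelationSigma = 0) {
  stopifnot(is(truth, "SubjectTruth"), is(masks, "TissueMasks"))
  if (!(snr > 0)) stop("snr must be positive (Inf for noiseless)")
  gridShape <- dim(masks@enhancing)
  nv <- prod(gridShape)
  fov <- gridShape * masks@voxelDims
  co <- sweep(.voxelCoords(gridShape, masks@voxelDims), 2, fov / 2)
  brain <- matrix(
    (co[, 1] / (0.45 * fov[1]))^2 + (co[, 2] / (0.45 * fov[2]))^2 +
    (co[, 3] / (0.45 * fov[3]))^2 <= 1, nrow = nv)
  lesion <- as.vector(masks@enhancing | masks@nonEnhancing | masks@edema)
  brain <- array(brain | lesion, gridShape)
  .withSeed(seed, {
    maps <- list()
    for (par in DIFF_PARAMS) {
      m <- array(0, gridShape)
      m[brain] <- backgroundParams[[par]]
      for (tis in TISSUES) {
        msk <- slot(masks, c(enhancing = "enhancing",
                             non_enhancing = "nonEnhancing",
                             edema = "edema")[[tis]])
        if (any(msk)) m[msk] <- truth@anchors[tis, par]
      }
      if (truth@jitterSd > 0) {
        sdlog <- sqrt(log(1 + truth@jitterSd^2))
        lj <- array(rnorm(nv, 0, sdlog), gridShape)
        if (jitterCorrelationSigma > 0) {
          lj <- gaussianSmooth3d(lj, jitterCorrelationSigma)
          lj <- lj * sdlog / max(sd(as.vector(lj)), 1e-12)
        }
        m <- m * exp(lj)
      }
      maps[[par]] <- m
    }
    maps$f <- pmin(maps$f, 0.95)
    maps$K <- pmin(maps$K, 3)
    maps$Dstar <- pmax(maps$Dstar, 1.5 * maps$D)
    for (par in DIFF_PARAMS) maps[[par]][!brain] <- 0
    S0map <- array(0, gridShape)
    S0map[brain] <- s0
    maps$S0 <- S0map
    b <- scheme@bvalues
    nb <- length(b)
    sig <- array(0, c(gridShape, nb))
    fv <- as.vector(maps$f); Dv <- as.vector(maps$D)
    Sv <- as.vector(maps$Dstar); Kv <- as.vector(maps$K)
    S0v <- as.vector(S0map)
    noiseSd <- if (is.finite(snr)) s0 / snr else 0
    for (j in seq_len(nb)) {
      clean <- S0v * (fv * exp(-b[j] * Sv) +
                      (1 - fv) * exp(-b[j] * Dv + b[j]^2 * Dv^2 * Kv / 6))
      if (noiseSd > 0) {
        nav <- scheme@nAverages[j]
        acc <- numeric(nv)
        for (a in seq_len(nav))
          acc <- acc + sqrt((clean + rnorm(nv, 0, noiseSd))^2 +
                            rnorm(nv, 0, noiseSd)^2)
        clean <- acc / nav
      }
      sig[, , , j] <- clean
    }
    new("DWISeries", signal = sig, scheme = scheme,
        voxelDims = masks@voxelDims, brainMask = brain, truth = maps)
  })
}

setMethod("show", "DWISeries", function(object) {
  d <- dim(object@signal)
  cat("DWISeries:", paste(d[1:3], collapse = "x"), "grid,",
      d[4], "b-values, voxels",
      paste(object@voxelDims, collapse = "x"), "mm\n")
})

#' Generate a two-group synthetic cohort
#'
#' Draws \code{nHgg + nMeta} subjects (anchors, lesion geometry, noisy DWI)
#' with per-subject seeds derived deterministically from \code{masterSeed}.
#' A subject whose sampled lesion does not fit the grid is redrawn from a
#' fresh derived seed (physiologic truncation of extreme volumes).
#'
#' @param nHgg,nMeta group sizes (>= 1).
#' @param calibration named list with GroupCalibration entries "HGG" and
#'   "metastasis".
#' @param scheme a \linkS4class{BValueScheme}.
#' @param snr per-average b=0 signal-to-noise ratio.
#' @param masterSeed integer master seed.
#' @param gridShape,voxelDims phantom grid geometry.
#' @param jitterSd relative SD of within-tissue jitter.
#' @return list with \code{subjects} (each: id, label, seed, dwi, masks,
#'   truth), \code{manifest} data.frame, and \code{summary} data.frame of
#'   per-group median anchors (audit of calibration recovery).
#' @export
generateCohort <- function(nHgg, nMeta,
                           calibration = list(
                             HGG = defaultCalibration("HGG"),
                             metastasis = defaultCalibration("metastasis")),
                           scheme = paperBScheme(), snr = 40, masterSeed = 1,
                           gridShape = c(24, 24, 24), voxelDims = c(5, 5, 5),
                           jitterSd = 0.1) {
  if (nHgg < 1 || nMeta < 1) stop("need at least one subject per group")
  n <- nHgg + nMeta
  labels <- rep(c("HGG", "metastasis"), c(nHgg, nMeta))
  seeds <- .withSeed(masterSeed, sample.int(2^31 - 2, n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- seeds[i]
    for (try in 1:25) {
      truth <- sampleSubjectParams(labels[i], calibration[[labels[i]]],
                                   seed = sd_i, jitterSd = jitterSd)
      masks <- tryCatch(
        buildLesionGeometry(truth, gridShape, voxelDims, seed = sd_i + 1L),
        error = function(e) NULL)
      if (!is.null(masks)) break
      sd_i <- (sd_i + 7919L) %% (2^31 - 2) + 1
    }
    if (is.null(masks)) stop("could not fit subject ", i, " on the grid")
    dwi <- synthesizeDwi(truth, masks, scheme, snr, seed = sd_i + 2L)
    subjects[[i]] <- list(id = sprintf("subj%03d", i), label = labels[i],
                          seed = sd_i, truth = truth, masks = masks,
                          dwi = dwi)
  }
  manifest <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    label = labels,
    seed = vapply(subjects, function(s) as.numeric(s$seed), 0),
    enhancing = vapply(subjects, function(s) s$truth@presence[["enhancing"]], TRUE),
    non_enhancing = vapply(subjects, function(s) s$truth@presence[["non_enhancing"]], TRUE),
    edema = vapply(subjects, function(s) s$truth@presence[["edema"]], TRUE))
  anchorRows <- do.call(rbind, lapply(subjects, function(s) {
    a <- s$truth@anchors
    data.frame(label = s$label, tissue = rep(rownames(a), ncol(a)),
               param = rep(colnames(a), each = nrow(a)),
               value = as.vector(a))
  }))
  summary <- aggregate(value ~ label + tissue + param, anchorRows, median)
  names(summary)[names(summary) == "value"] <- "median_anchor"
  list(subjects = subjects, manifest = manifest, summary = summary)
}
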