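#' @useDynLib mbglioma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

TISSUES <- c("enhancing", "non_enhancing", "edema")
DIFF_PARAMS <- c("f", "D", "Dstar", "K")

#' Multi-b acquisition scheme
#'
#' Ordered diffusion weightings (b-values, s/mm^2) together with the number
#' of signal averages acquired at each b.  The scheme is shared by the
#' phantom simulator and the model fitters.
#'
#' @slot bvalues numeric, strictly increasing, first value 0 (s/mm^2).
#' @slot nAverages integer, number of magnitude averages per b (>= 1).
#' @export
setClass("BValueScheme",
  representation(bvalues = "numeric", nAverages = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@bvalues) != length(object@nAverages))
      msg <- c(msg, "bvalues and nAverages must have equal length")
    if (length(object@bvalues) < 1L || object@bvalues[1] != 0)
      msg <- c(msg, "first b-value must be 0")
    if (any(diff(object@bvalues) <= 0))
      msg <- c(msg, "b-values must be strictly increasing")
    if (any(object@nAverages < 1L))
      msg <- c(msg, "nAverages must all be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Two-group calibration of tissue parameter distributions
#'
#' Per tissue compartment (enhancing, non-enhancing, edema) and per diffusion
#' parameter (f, D, Dstar, K), the median and interquartile range of the
#' subject-level tissue median, plus per-tissue volume median/IQR (mL) and
#' the probability that a compartment is absent.  D and Dstar are stored in
#' 1e-6 mm^2/s, matching how such cohort tables are printed.
#'
#' @slot params data.frame with columns tissue, param, median, q25, q75.
#' @slot volumes data.frame with columns tissue, median, q25, q75 (mL).
#' @slot absenceProb named numeric, per-tissue probability of absence.
#' @export
setClass("GroupCalibration",
  representation(params = "data.frame", volumes = "data.frame",
                 absenceProb = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- object@params
    need <- c("tissue", "param", "median", "q25", "q75")
    if (!all(need %in% names(p)))
      return("params must have columns tissue, param, median, q25, q75")
    if (!all(c("tissue", "median", "q25", "q75") %in% names(object@volumes)))
      return("volumes must have columns tissue, median, q25, q75")
    if (any(p$median < p$q25 - 1e-12 | p$median > p$q75 + 1e-12))
      msg <- c(msg, "every parameter median must lie within its IQR")
    fp <- p[p$param == "f", ]
    if (any(fp$median <= 0 | fp$median >= 1))
      msg <- c(msg, "f medians must lie in (0,1)")
    for (tis in unique(p$tissue)) {
      dmed <- p$median[p$tissue == tis & p$param == "D"]
      smed <- p$median[p$tissue == tis & p$param == "Dstar"]
      if (length(dmed) && length(smed) && smed <= dmed)
        msg <- c(msg, sprintf("Dstar median must exceed D median (%s)", tis))
    }
    if (any(object@absenceProb < 0 | object@absenceProb > 1))
      msg <- c(msg, "absence probabilities must lie in [0,1]")
    v <- object@volumes
    if (any(v$median < v$q25 - 1e-12 | v$median > v$q75 + 1e-12))
      msg <- c(msg, "every volume median must lie within its IQR")
    if (length(msg)) msg else TRUE
  })

#' Ground-truth description of one synthetic subject
#'
#' @slot group "HGG" or "metastasis".
#' @slot anchors matrix (tissue x parameter) of scalar tissue anchors;
#'   f dimensionless, D and Dstar in mm^2/s, K dimensionless.
#' @slot volumes named numeric, per-tissue target volume (mL).
#' @slot presence named logical, tissue-presence flags.
#' @slot jitterSd relative SD of the multiplicative within-tissue jitter.
#' @export
setClass("SubjectTruth",
  representation(group = "character", anchors = "matrix",
                 volumes = "numeric", presence = "logical",
                 jitterSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@group %in% c("HGG", "metastasis"))
      msg <- c(msg, "group must be 'HGG' or 'metastasis'")
    if (!identical(rownames(object@anchors), TISSUES) ||
        !identical(colnames(object@anchors), DIFF_PARAMS))
      msg <- c(msg, "anchors must be a tissue x parameter matrix")
    else {
      for (tis in TISSUES) {
        if (!object@presence[[tis]]) next
        a <- object@anchors[tis, ]
        if (a["f"] < 0 || a["f"] > 1) msg <- c(msg, "f outside [0,1]")
        if (a["D"] <= 0 || a["D"] > 4e-3)
          msg <- c(msg, "D outside (0, 4e-3] mm^2/s")
        if (a["Dstar"] <= a["D"] || a["Dstar"] > 0.1)
          msg <- c(msg, "Dstar outside (D, 0.1] mm^2/s")
        if (a["K"] < 0 || a["K"] > 3) msg <- c(msg, "K outside [0,3]")
        if (object@volumes[[tis]] <= 0)
          msg <- c(msg, "present tissues must have positive volume")
      }
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' Disjoint tissue compartment masks
#'
#' Binary volumes for enhancing tumor, non-enhancing (necrotic/cystic) tumor
#' and edema on a shared grid.  Any mask may be empty (absent compartment);
#' the three are pairwise disjoint.
#'
#' @slot enhancing,nonEnhancing,edema logical 3D arrays.
#' @slot voxelDims numeric length-3, voxel size in mm.
#' @slot provenance character note on how the masks were derived.
#' @export
setClass("TissueMasks",
  representation(enhancing = "array", nonEnhancing = "array",
                 edema = "array", voxelDims = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@enhancing)
    if (length(d) != 3) msg <- c(msg, "masks must be 3D arrays")
    if (!identical(d, dim(object@nonEnhancing)) ||
        !identical(d, dim(object@edema)))
      msg <- c(msg, "masks must share one grid")
    if (length(object@voxelDims) != 3 || any(object@voxelDims <= 0))
      msg <- c(msg, "voxelDims must be 3 positive numbers (mm)")
    if (!length(msg)) {
      if (any(object@enhancing & object@nonEnhancing) ||
          any(object@enhancing & object@edema) ||
          any(object@nonEnhancing & object@edema))
        msg <- c(msg, "tissue masks must be pairwise disjoint")
    }
    if (length(msg)) msg else TRUE
  })

#' 4D diffusion-weighted series
#'
#' @slot signal 4D array (x, y, z, b) of non-negative signal.
#' @slot scheme the \linkS4class{BValueScheme} of the fourth axis.
#' @slot voxelDims numeric length-3 voxel size (mm).
#' @slot brainMask logical 3D array (all TRUE when unknown).
#' @slot truth list of ground-truth parameter volumes (empty for real data).
#' @export
setClass("DWISeries",
  representation(signal = "array", scheme = "BValueScheme",
                 voxelDims = "numeric", brainMask = "array",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@signal)
    if (length(d) != 4) return("signal must be a 4D array")
    if (d[4] != length(object@scheme@bvalues))
      msg <- c(msg, "fourth axis must match the b-value scheme length")
    if (any(object@signal < 0)) msg <- c(msg, "signals must be >= 0")
    if (length(object@voxelDims) != 3 || any(object@voxelDims <= 0))
      msg <- c(msg, "voxelDims must be 3 positive numbers (mm)")
    if (!identical(dim(object@brainMask), d[1:3]))
      msg <- c(msg, "brainMask must match the spatial grid")
    if (length(msg)) msg else TRUE
  })

#' Voxelwise parameter maps from the two diffusion models
#'
#' IVIM perfusion fraction f, diffusion coefficient D, pseudo-diffusion
#' coefficient Dstar (all from the variable-projection IVIM fit, mm^2/s for
#' the diffusivities) and diffusion kurtosis K (log-domain kurtosis-model
#' fit), with S0, a residual-norm fit-quality volume and a validity mask.
#'
#' @slot f,D,Dstar,K,S0,residual numeric 3D arrays on the DWI grid.
#' @slot valid logical 3D array, TRUE where both fits succeeded.
#' @slot voxelDims numeric length-3 voxel size (mm).
#' @export
setClass("ParameterMaps",
  representation(f = "array", D = "array", Dstar = "array", K = "array",
                 S0 = "array", residual = "array", valid = "array",
                 voxelDims = "numeric"),
  validity = function(object) {
    d <- dim(object@f)
    msg <- character()
    if (length(d) != 3) return("maps must be 3D arrays")
    for (nm in c("D", "Dstar", "K", "S0", "residual", "valid"))
      if (!identical(dim(slot(object, nm)), d))
        msg <- c(msg, sprintf("map '%s' must match the grid of f", nm))
    if (!length(msg) && any(!is.finite(object@f[object@valid])))
      msg <- c(msg, "values inside the validity mask must be finite")
    if (length(msg)) msg else TRUE
  })
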