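#' Derive disjoint tissue masks from nested segmentations
#'
#' Segmentation protocols for contrast-enhancing brain lesions typically
#' produce three nested masks: enhancing tumor, tumor core (enhancing plus
#' necrotic/cystic tissue) and whole pathology (core plus edema).  The
#' non-enhancing mask is the core minus the enhancing mask; the edema mask
#' is the whole-pathology mask minus the core.  The three outputs partition
#' the whole-pathology mask and are verified pairwise disjoint.
#'
#' Small containment violations (registration slack) up to
#' \code{tolerance} of the child mask's voxels are clipped into the parent
#' with a warning; larger violations are rejected with a voxel-count
#' report.
#'
#' @param enhancing,core,whole logical 3D arrays on one grid.
#' @param voxelDims numeric length-3 voxel size (mm).
#' @param tolerance maximum tolerated fraction of child voxels outside the
#'   parent (default 0.001).
#' @return A \linkS4class{TissueMasks}.
#' @export
deriveMasks <- function(enhancing, core, whole, voxelDims,
                        tolerance = 0.001) {
  enhancing <- array(as.logical(enhancing), dim(enhancing))
  core <- array(as.logical(core), dim(core))
  whole <- array(as.logical(whole), dim(whole))
  if (!identical(dim(enhancing), dim(core)) ||
      !identical(dim(core), dim(whole)))
    stop("enhancing, core and whole masks must share one grid")
  clip <- function(child, parent, what) {
    outside <- child & !parent
    nOut <- sum(outside)
    if (nOut > 0) {
      frac <- nOut / max(sum(child), 1L)
      if (frac > tolerance)
        stop(sprintf(
          "%d voxels (%.2f%%) of the %s mask lie outside its parent",
          nOut, 100 * frac, what))
      warning(sprintf("clipped %d %s voxels into the parent mask",
                      nOut, what))
      child <- child & parent
    }
    child
  }
  enhancing <- clip(enhancing, core, "enhancing")
  core <- clip(core, whole, "core")
  new("TissueMasks",
      enhancing = enhancing,
      nonEnhancing = core & !enhancing,
      edema = whole & !core,
      voxelDims = as.numeric(voxelDims),
      provenance = "derived: non_enhancing = core \\ enhancing; edema = whole \\ core")
}

#' Mask volume in milliliters
#'
#' @param mask logical (or 0/1) 3D array.
#' @param voxelDims numeric length-3 voxel size (mm).
#' @return voxel count times voxel volume (mm^3) / 1000, in mL.
#' @examples
#' maskVolumeMl(array(TRUE, c(10, 10, 10)), c(2, 2, 2))  # 8 mL
#' @export
maskVolumeMl <- function(mask, voxelDims) {
  if (any(voxelDims <= 0)) stop("voxelDims must be positive")
  sum(mask != 0) * prod(voxelDims) / 1000
}

#' @describeIn deriveMasks accessor for one tissue mask
#' @param x a TissueMasks.
#' @param tissue "enhancing", "non_enhancing" or "edema".
#' @export
tissueMask <- function(x, tissue = c("enhancing", "non_enhancing", "edema")) {
  tissue <- match.arg(tissue)
  slot(x, c(enhancing = "enhancing", non_enhancing = "nonEnhancing",
            edema = "edema")[[tissue]])
}

#' @describeIn deriveMasks per-tissue volumes (mL) of a TissueMasks
#' @export
tissueVolumes <- function(x) {
  vapply(TISSUES, function(tis) maskVolumeMl(tissueMask(x, tis),
                                             x@voxelDims), 0)
}

setMethod("show", "TissueMasks", function(object) {
  v <- tissueVolumes(object)
  cat("TissueMasks:", paste(dim(object@enhancing), collapse = "x"),
      "grid\n  volumes (mL):",
      paste(names(v), round(v, 2), sep = "=", collapse = ", "), "\n")
})
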