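#' Write / read a DWI series as NIfTI + b-table
#'
#' The 4D signal goes to one NIfTI file (voxel dimensions in the header)
#' and the scheme to a two-column whitespace-separated b-table.
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param niftiPath output NIfTI path (.nii or .nii.gz).
#' @param btablePath output b-table path.
#' @export
writeDwi <- function(dwi, niftiPath, btablePath) {
  img <- RNifti::asNifti(dwi@signal)
  RNifti::pixdim(img) <- c(dwi@voxelDims, 1)
  RNifti::writeNifti(img, niftiPath)
  writeBScheme(dwi@scheme, btablePath)
  invisible(niftiPath)
}

#' @rdname writeDwi
#' @return \code{readDwi}: a \linkS4class{DWISeries} (brain mask set to
#'   all-TRUE; apply your own).
#' @export
readDwi <- function(niftiPath, btablePath) {
  img <- RNifti::readNifti(niftiPath)
  scheme <- readBScheme(btablePath)
  sig <- array(as.numeric(img), dim(img))
  new("DWISeries", signal = pmax(sig, 0), scheme = scheme,
      voxelDims = RNifti::pixdim(img)[1:3],
      brainMask = array(TRUE, dim(img)[1:3]), truth = list())
}

#' Write a 3D volume (mask or parameter map) as NIfTI
#'
#' @param vol 3D array.
#' @param path output path.
#' @param voxelDims voxel size (mm).
#' @export
writeVolume <- function(vol, path, voxelDims) {
  img <- RNifti::asNifti(vol * 1)
  RNifti::pixdim(img) <- voxelDims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI path.
#' @return logical 3D array with attribute \code{voxelDims}.
#' @export
readMaskVolume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(array(as.numeric(img) != 0, dim(img)),
            voxelDims = RNifti::pixdim(img)[1:3])
}

#' Write all parameter maps, fit-quality map and validity mask
#'
#' One 3D NIfTI per volume (\code{f.nii.gz}, \code{D.nii.gz},
#' \code{Dstar.nii.gz}, \code{K.nii.gz}, \code{S0.nii.gz},
#' \code{residual.nii.gz}, \code{valid.nii.gz}).
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param dir output directory.
#' @export
writeParameterMaps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("f", "D", "Dstar", "K", "S0", "residual")) {
    v <- slot(maps, nm)
    v[is.na(v)] <- 0
    writeVolume(v, file.path(dir, paste0(nm, ".nii.gz")), maps@voxelDims)
  }
  writeVolume(maps@valid, file.path(dir, "valid.nii.gz"), maps@voxelDims)
  invisible(dir)
}
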