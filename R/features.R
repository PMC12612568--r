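HIST_STATS <- c("mean", "median", "sd", "min", "p5", "p25", "p75", "p95",
                "max", "skew", "kurt")
TISSUE_ABBR <- c(enhancing = "enh", non_enhancing = "nonenh",
                 edema = "edema")

#' Canonical feature names
#'
#' The fixed 135-name scheme \code{<param>_<tissue>_<stat>} for the 4
#' parameter maps (f, D, Dstar, K), 3 tissues (enh, nonenh, edema) and 11
#' first-order histogram statistics, plus the 3 tissue volumes
#' \code{vol_<tissue>}.  D and Dstar features are reported in 1e-6 mm^2/s,
#' volumes in mL.
#'
#' @return character vector of length 135.
#' @export
featureNames <- function() {
  c(as.vector(vapply(DIFF_PARAMS, function(p)
      as.vector(vapply(TISSUE_ABBR, function(t)
        paste(p, t, HIST_STATS, sep = "_"), character(length(HIST_STATS)))),
      character(length(HIST_STATS) * 3))),
    paste0("vol_", TISSUE_ABBR))
}

#' First-order histogram statistics of a voxel-value sample
#'
#' Mean; median; sample standard deviation (n-1 denominator); minimum; 5th,
#' 25th, 75th and 95th percentiles (linear interpolation between order
#' statistics); maximum; adjusted Fisher-Pearson skewness; and excess
#' kurtosis with sample bias correction (SPSS/type-2 convention, so a
#' normal sample is centered on 0).  Skewness and kurtosis are returned as
#' NA for fewer than 4 values or zero spread.
#'
#' @param values numeric vector with at least one finite value.
#' @return named numeric vector of the 11 statistics.
#' @examples
#' histogramStats(c(1, 2, 3, 4, 5))
#' @export
histogramStats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("histogramStats needs at least one finite value")
  n <- length(values)
  s <- stats::sd(values)
  if (n < 2) s <- 0
  q <- unname(stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                              type = 7))
  sk <- ku <- NA_real_
  if (n >= 4 && s > 0) {
    sk <- e1071::skewness(values, type = 2)
    ku <- e1071::kurtosis(values, type = 2)
  }
  c(mean = mean(values), median = q[3], sd = s, min = min(values),
    p5 = q[1], p25 = q[2], p75 = q[4], p95 = q[5], max = max(values),
    skew = sk, kurt = ku)
}

#' Extract the per-subject feature vector
#'
#' For each present tissue and each of the 4 parameter maps, the 11
#' histogram statistics over in-mask voxels inside the fit-validity mask,
#' plus the 3 tissue volumes: 135 named features.  Absent tissues (or
#' present tissues with no valid voxel, which are demoted to absent with a
#' warning) yield NA markers for all 45 of their entries; zero-imputation
#' is deliberately left to the classifier stage.
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param masks a \linkS4class{TissueMasks} on the same grid.
#' @param id subject identifier.
#' @param label group label ("HGG" or "metastasis"), NA if unknown.
#' @return one-row data.frame: id, label, then the 135 features in
#'   canonical order (D and Dstar scaled to 1e-6 mm^2/s).
#' @export
extractFeatures <- function(maps, masks, id = "subject", label = NA_character_) {
  if (!identical(dim(maps@f), dim(masks@enhancing)))
    stop("maps and masks must share one grid")
  out <- stats::setNames(rep(NA_real_, 135), featureNames())
  for (tis in TISSUES) {
    msk <- tissueMask(masks, tis) & maps@valid
    abbr <- TISSUE_ABBR[[tis]]
    if (!any(msk)) {
      if (any(tissueMask(masks, tis)))
        warning("tissue ", tis, " has no valid voxel; treated as absent")
      next
    }
    out[paste0("vol_", abbr)] <- maskVolumeMl(tissueMask(masks, tis),
                                              masks@voxelDims)
    for (par in DIFF_PARAMS) {
      vals <- slot(maps, par)[msk]
      if (par %in% c("D", "Dstar")) vals <- vals * 1e6
      out[paste(par, abbr, HIST_STATS, sep = "_")] <- histogramStats(vals)
    }
  }
  cbind(data.frame(id = id, label = label, stringsAsFactors = FALSE),
        as.data.frame(as.list(out), check.names = FALSE))
}

#' Assemble a feature table from per-subject feature rows
#'
#' @param rows list of one-row data.frames from
#'   \code{\link{extractFeatures}} (or one combined data.frame).
#' @return data.frame with columns id, label and the 135 features in
#'   canonical order; duplicate ids are rejected.
#' @export
buildFeatureTable <- function(rows) {
  if (is.data.frame(rows)) rows <- list(rows)
  if (!length(rows)) stop("no subjects supplied")
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$id)) stop("duplicate subject ids in feature table")
  tab[, c("id", "label", featureNames())]
}

#' Write / read a feature table as CSV
#'
#' Absent-tissue markers are encoded as empty cells, so the table
#' round-trips losslessly.
#'
#' @param table feature table data.frame.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE,
                         colClasses = c(id = "character",
                                        label = "character"))
  for (nm in setdiff(names(tab), c("id", "label")))
    tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}
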