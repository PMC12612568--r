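#' Build a group calibration
#'
#' @param params data.frame with columns tissue, param, median, q25, q75.
#'   Diffusivities (D, Dstar) are given in 1e-6 mm^2/s, f and K
#'   dimensionless.  The statistics describe subject-level tissue medians.
#' @param volumes data.frame with columns tissue, median, q25, q75 (mL).
#' @param absenceProb named numeric, per-tissue probability that the
#'   compartment is absent from a lesion.
#' @return A \linkS4class{GroupCalibration}.
#' @export
groupCalibration <- function(params, volumes, absenceProb) {
  new("GroupCalibration", params = params, volumes = volumes,
      absenceProb = absenceProb)
}

.calRow <- function(tissue, param, med, q25, q75)
  data.frame(tissue = tissue, param = param, median = med,
             q25 = q25, q75 = q75, stringsAsFactors = FALSE)

#' Default cohort calibrations
#'
#' Per-group medians and interquartile ranges of subject-level tissue-median
#' IVIM/kurtosis parameters and tissue volumes in high-grade glioma and
#' brain-metastasis cohorts, used as the generative anchors of the phantom
#' module.  Non-enhancing (necrotic/cystic) tissue may be absent, most often
#' in metastases; enhancing tumor and edema are always simulated as present.
#'
#' @param group "HGG" or "metastasis".
#' @return A \linkS4class{GroupCalibration}.
#' @export
defaultCalibration <- function(group = c("HGG", "metastasis")) {
  group <- match.arg(group)
  if (group == "HGG") {
    params <- rbind(
      .calRow("enhancing",     "f",     0.20,   0.18,    0.23),
      .calRow("non_enhancing", "f",     0.25,   0.19,    0.38),
      .calRow("edema",         "f",     0.20,   0.18,    0.23),
      .calRow("enhancing",     "D",     774.5,  680.75,  838),
      .calRow("non_enhancing", "D",     932,    724,     1198),
      .calRow("edema",         "D",     950,    810,     1023),
      .calRow("enhancing",     "Dstar", 5975.5, 5506,    7267.25),
      .calRow("non_enhancing", "Dstar", 4798,   4436,    5128),
      .calRow("edema",         "Dstar", 5053,   4581,    5364),
      .calRow("enhancing",     "K",     0.76,   0.68,    0.86),
      .calRow("non_enhancing", "K",     0.65,   0.54,    0.77),
      .calRow("edema",         "K",     0.63,   0.59,    0.75))
    volumes <- data.frame(
      tissue = TISSUES,
      median = c(11.73, 8.1, 39.41),
      q25 = c(4.59, 1.1, 9.81),
      q75 = c(23.54, 25.25, 67.67))
    absence <- c(enhancing = 0, non_enhancing = 0.05, edema = 0)
  } else {
    params <- rbind(
      .calRow("enhancing",     "f",     0.23,   0.21,    0.25),
      .calRow("non_enhancing", "f",     0.25,   0.20,    0.40),
      .calRow("edema",         "f",     0.24,   0.22,    0.27),
      .calRow("enhancing",     "D",     649,    602.75,  700.5),
      .calRow("non_enhancing", "D",     666,    618,     897),
      .calRow("edema",         "D",     1012,   905.25,  1091),
      .calRow("enhancing",     "Dstar", 6429,   5576.75, 6974),
      .calRow("non_enhancing", "Dstar", 5177,   4943,    6061),
      .calRow("edema",         "Dstar", 4611,   4333,    4949),
      .calRow("enhancing",     "K",     0.91,   0.84,    0.99),
      .calRow("non_enhancing", "K",     0.87,   0.70,    0.93),
      .calRow("edema",         "K",     0.62,   0.58,    0.70))
    volumes <- data.frame(
      tissue = TISSUES,
      median = c(9.07, 0.32, 42.63),
      q25 = c(3.94, 0, 15.7),
      q75 = c(22.06, 5.88, 95.32))
    absence <- c(enhancing = 0, non_enhancing = 0.4, edema = 0)
  }
  groupCalibration(params, volumes, absence)
}

setMethod("show", "GroupCalibration", function(object) {
  cat("GroupCalibration:", nrow(object@params), "parameter rows,",
      nrow(object@volumes), "tissue volumes\n")
  cat("absence probabilities:",
      paste(names(object@absenceProb), signif(object@absenceProb, 3),
            sep = "=", collapse = ", "), "\n")
})
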