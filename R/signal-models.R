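#' IVIM biexponential forward model
#'
#' \deqn{S(b) = S0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}
#' with perfusion fraction f, pseudo-diffusion coefficient D* and tissue
#' diffusion coefficient D (both mm^2/s).
#'
#' @param b b-values (s/mm^2), non-negative; vectorized.
#' @param S0 signal at b = 0.
#' @param f perfusion fraction in [0, 1].
#' @param Dstar pseudo-diffusion coefficient (mm^2/s).
#' @param D diffusion coefficient (mm^2/s).
#' @return signal values, same length as \code{b}.
#' @examples
#' ivimSignal(1000, S0 = 1, f = 0, Dstar = 6e-3, D = 1e-3)  # exp(-1)
#' @export
ivimSignal <- function(b, S0, f, Dstar, D) {
  if (any(b < 0)) stop("b-values must be non-negative")
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

#' Diffusion-kurtosis forward model
#'
#' \deqn{S(b) = S0 e^{-b D + b^2 D^2 K / 6}}
#' with kurtosis-model diffusion coefficient D (mm^2/s) and dimensionless
#' diffusion kurtosis K.
#'
#' @param b b-values (s/mm^2), non-negative; vectorized.
#' @param S0 signal at b = 0.
#' @param D kurtosis-model diffusion coefficient (mm^2/s).
#' @param K diffusion kurtosis.
#' @return signal values, same length as \code{b}.
#' @export
kurtosisSignal <- function(b, S0, D, K) {
  if (any(b < 0)) stop("b-values must be non-negative")
  S0 * exp(-b * D + b^2 * D^2 * K / 6)
}
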