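#' Construct a b-value scheme
#'
#' @param bvalues numeric vector of b-values (s/mm^2), strictly increasing,
#'   starting at 0.
#' @param nAverages integer vector of per-b signal-averaging counts.
#' @return A \linkS4class{BValueScheme}.
#' @examples
#' bScheme(c(0, 500, 1000), c(1, 3, 3))
#' @export
bScheme <- function(bvalues, nAverages = rep(1L, length(bvalues))) {
  new("BValueScheme", bvalues = as.numeric(bvalues),
      nAverages = as.integer(nAverages))
}

#' The clinical 10-b acquisition scheme
#'
#' The single-shot EPI scheme used throughout: b = 0, 10, 20, 30, 50, 100,
#' 200, 500, 1000, 2000 s/mm^2 with per-b signal averaging counts
#' 1, 1, 1, 1, 1, 2, 2, 3, 3, 6.
#'
#' @return A \linkS4class{BValueScheme}.
#' @export
paperBScheme <- function() {
  bScheme(c(0, 10, 20, 30, 50, 100, 200, 500, 1000, 2000),
          c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 6L))
}

#' @describeIn bScheme b-values of a scheme
#' @param x a BValueScheme.
#' @export
bValues <- function(x) x@bvalues

#' @describeIn bScheme per-b averaging counts
#' @export
nAverages <- function(x) x@nAverages

setMethod("show", "BValueScheme", function(object) {
  cat("BValueScheme:", length(object@bvalues), "b-values (s/mm^2)\n")
  cat(paste0(object@bvalues, "[", object@nAverages, "]", collapse = " "), "\n")
})

setMethod("length", "BValueScheme", function(x) length(x@bvalues))

#' Read / write a b-value table
#'
#' Two-column whitespace-separated text: b-value (s/mm^2) and number of
#' averages per line.
#'
#' @param path file path.
#' @return \code{readBScheme}: a \linkS4class{BValueScheme}.
#' @export
readBScheme <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("b", "n_averages"))
  bScheme(tab$b, tab$n_averages)
}

#' @rdname readBScheme
#' @param scheme a BValueScheme to write.
#' @export
writeBScheme <- function(scheme, path) {
  utils::write.table(
    data.frame(b = scheme@bvalues, n_averages = scheme@nAverages),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
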