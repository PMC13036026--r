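#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment: sort the p-values ascending, form
#' \code{p_(i) * n / i}, take running minima from the largest rank down,
#' cap at 1 and return in the original order. Delegates to
#' \code{stats::p.adjust(method = "BH")} after validating the input.
#'
#' @param p numeric vector of p-values, all in [0, 1].
#' @return q-values in the original order.
#' @export
bhFdr <- function(p) {
    p <- as.numeric(p)
    if (length(p) == 0L) return(numeric(0))
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("argument error: p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Significance stars from q-values
#'
#' \code{***} q < 0.001, \code{**} q < 0.01, \code{*} q < 0.05, else empty.
#'
#' @param q numeric vector of adjusted p-values.
#' @return character vector of star strings.
#' @export
starsFromQ <- function(q) {
    out <- character(length(q))
    out[q < 0.05] <- "*"
    out[q < 0.01] <- "**"
    out[q < 0.001] <- "***"
    out
}
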