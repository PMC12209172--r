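#' Crosstalk-corrected proximity ratio from two-channel intensities
#'
#' Computes the per-particle proximity ratio
#' \deqn{E_{PR} = (I_5 - \alpha I_3) / (I_5 + \beta I_3)}
#' where \eqn{I_3} and \eqn{I_5} are the donor (Cy3) and acceptor (Cy5)
#' channel intensities of one burst and \eqn{\alpha}/\eqn{\beta}
#' (defaults 0.19/0.81) correct the leakage of donor emission into the
#' acceptor channel. The proximity ratio is a FRET-efficiency proxy not
#' corrected for quantum yields or the detection (gamma) factor; for
#' non-negative inputs it lies in \eqn{[-\alpha/\beta, 1]} and is invariant
#' under rescaling of both channels.
#'
#' @param i3 donor-channel intensity (counts, >= 0); vectorised.
#' @param i5 acceptor-channel intensity (counts, >= 0); vectorised.
#' @param crosstalk a [CrosstalkModel-class]; default \code{crosstalkModel()}.
#' @return Numeric vector of proximity ratios.
#' @examples
#' computeEpr(100, 100)          # (100 - 19) / (100 + 81)
#' computeEpr(200, 0.19 * 200)   # crosstalk-only acceptor signal -> 0
#' computeEpr(0, 500)            # acceptor-only limit -> 1
#' @export
computeEpr <- function(i3, i5, crosstalk = crosstalkModel()) {
    stopifnot(is(crosstalk, "CrosstalkModel"))
    if (length(i3) != length(i5))
        stop("'i3' and 'i5' must have the same length")
    if (any(!is.finite(i3)) || any(!is.finite(i5)))
        stop("intensities must be finite")
    if (any(i3 < 0) || any(i5 < 0))
        stop("negative channel intensities are not allowed")
    if (any(i3 + i5 == 0))
        stop("proximity ratio undefined for I3 = I5 = 0")
    a <- crosstalk@alpha
    b <- crosstalk@beta
    (i5 - a * i3) / (i5 + b * i3)
}

#' Attainable proximity-ratio range for a crosstalk model
#'
#' For non-negative channel intensities the proximity ratio is bounded
#' below by \eqn{-\alpha/\beta} (donor-only signal with zero acceptor
#' counts) and above by 1 (acceptor-only signal).
#'
#' @param crosstalk a [CrosstalkModel-class].
#' @return Numeric(2): lower and upper attainable proximity ratio.
#' @examples
#' eprRange()   # c(-0.2346, 1) for the 0.19/0.81 defaults
#' @export
eprRange <- function(crosstalk = crosstalkModel()) {
    c(-crosstalk@alpha / crosstalk@beta, 1)
}
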