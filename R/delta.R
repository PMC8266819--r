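#' Convert raw isotope ratios to delta notation
#'
#' Stable isotope ratios are conventionally expressed in delta notation: the
#' per-mil deviation of the sample's heavy-to-light isotope ratio from that of
#' an international reference standard (VPDB for carbon, atmospheric N2 for
#' nitrogen),
#' \deqn{\delta R = \left(\frac{R_{sample} - R_{standard}}{R_{standard}}\right)
#'   \times 10^3.}
#'
#' @param r_sample Heavy-to-light isotope ratio of the sample (dimensionless,
#'   \eqn{\ge 0}). Vectorised.
#' @param r_standard Heavy-to-light isotope ratio of the reference standard
#'   (dimensionless, strictly positive).
#' @return Delta value(s) in per mil.
#' @examples
#' delta_from_ratio(0.011238, 0.011180)
#' @seealso [ratio_from_delta()] for the inverse.
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    abort("`r_sample` and `r_standard` must be numeric.")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    abort("`r_standard` must be finite and strictly positive.")
  }
  if (any(!is.finite(r_sample)) || any(r_sample < 0)) {
    abort("`r_sample` must be finite and non-negative.")
  }
  (r_sample - r_standard) / r_standard * 1e3
}

#' Recover a raw isotope ratio from a delta value
#'
#' Inverse of [delta_from_ratio()]: \eqn{R_{sample} = R_{standard}
#' (1 + \delta / 10^3)}.
#'
#' @param delta Delta value(s) in per mil.
#' @param r_standard Reference-standard ratio (strictly positive).
#' @return Sample ratio(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    abort("`r_standard` must be finite and strictly positive.")
  }
  r_standard * (1 + delta / 1e3)
}
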