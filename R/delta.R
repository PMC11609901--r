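#' Delta notation: convert isotope ratios to permil delta values
#'
#' Isotope compositions are reported as relative deviations of the rare/
#' abundant isotope ratio of a sample from that of an international
#' reference standard (VSMOW for \eqn{^{2}}H/\eqn{^{1}}H and
#' \eqn{^{18}}O/\eqn{^{16}}O, VPDB for \eqn{^{13}}C/\eqn{^{12}}C):
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}
#' in permil. `ratio_from_delta()` is the exact inverse.
#'
#' @param r_sample Isotope ratio(s) of the sample, \eqn{\ge 0}.
#' @param r_standard Isotope ratio(s) of the reference standard, \eqn{> 0}.
#' @param delta Delta value(s) in permil.
#' @return `delta_from_ratio()`: delta value(s) in permil.
#'   `ratio_from_delta()`: isotope ratio(s).
#' @examples
#' delta_from_ratio(2, 1)       # +1000 permil
#' delta_from_ratio(0.9, 1)     # -100 permil
#' ratio_from_delta(-100, 1)    # 0.9
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("`r_standard` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop("`r_sample` must be finite and >= 0", call. = FALSE)
  }
  1000 * (r_sample / r_standard - 1)
}

#' @rdname delta_from_ratio
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("`r_standard` must be finite and > 0", call. = FALSE)
  }
  r_standard * (delta / 1000 + 1)
}
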