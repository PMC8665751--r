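#' VPDB carbon isotope-ratio reference
#'
#' The 13C/12C abundance ratio of the Vienna Pee Dee Belemnite reference,
#' IAEA consensus value 0.011180.  All delta-based statistics in this package
#' are independent of this number; it is only needed when converting between
#' raw abundance ratios and delta notation.
#'
#' @return the reference 13C/12C ratio (dimensionless).
#' @export
vpdb_r13c <- function() 0.011180

#' Convert a 13C/12C abundance ratio to delta notation
#'
#' delta13C (per mil) = (R_sample - R_ref) * 1000 / R_ref, with R_ref the
#' VPDB reference ratio by default.
#'
#' @param r_sample 13C/12C ratio of the sample (> 0).
#' @param r_ref reference ratio (> 0), default [vpdb_r13c()].
#' @return delta value in per mil vs the reference.
#' @export
#' @examples
#' ratio_to_delta(1.01 * vpdb_r13c())   # exactly +10 permil
ratio_to_delta <- function(r_sample, r_ref = vpdb_r13c()) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0))
    stop("domain error: r_sample must be a positive finite ratio", call. = FALSE)
  if (any(!is.finite(r_ref)) || any(r_ref <= 0))
    stop("domain error: r_ref must be a positive finite ratio", call. = FALSE)
  (r_sample - r_ref) * 1000 / r_ref
}

#' Convert a delta value back to a 13C/12C abundance ratio
#'
#' Inverse of [ratio_to_delta()]: R = R_ref * (1 + delta/1000).  Deltas at or
#' below -1000 per mil would imply a non-positive ratio and are rejected.
#'
#' @param delta delta value in per mil (> -1000).
#' @param r_ref reference ratio (> 0), default [vpdb_r13c()].
#' @return 13C/12C abundance ratio.
#' @export
delta_to_ratio <- function(delta, r_ref = vpdb_r13c()) {
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("domain error: delta must be finite and > -1000 permil", call. = FALSE)
  if (any(!is.finite(r_ref)) || any(r_ref <= 0))
    stop("domain error: r_ref must be a positive finite ratio", call. = FALSE)
  r_ref * (1 + delta / 1000)
}
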