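#' Robust location/scale parameters
#'
#' Parameters for the robust estimators used in per-library length
#' profiling: a one-step Huber M-estimator of location with bending
#' constant `bend` (default 1.28, the conventional choice giving ~95%
#' Gaussian efficiency) and a MAD scale estimate with consistency factor
#' `mad_consistency` (default 1.4826, making MAD consistent for the
#' standard deviation under normality; set 1 for the raw MAD).
#'
#' @param bend positive bending constant of the Huber psi function.
#' @param mad_consistency positive consistency multiplier for the MAD.
#' @return A list of class `robust_params`.
#' @export
robust_params <- function(bend = 1.28, mad_consistency = 1.4826) {
  stopifnot(is.numeric(bend), length(bend) == 1L, bend > 0,
            is.numeric(mad_consistency), length(mad_consistency) == 1L,
            mad_consistency > 0)
  structure(list(m_estimator = "huber-one-step", bend = bend,
                 mad_consistency = mad_consistency),
            class = "robust_params")
}

#' M-estimator of location (MEL)
#'
#' One-step Huber M-estimate: one Newton step from the sample median,
#' scaled by the (normal-consistent) MAD,
#' \deqn{MEL = med + MAD_n \frac{\sum_i \psi((x_i - med)/MAD_n)}{\#\{|x_i - med| \le b\, MAD_n\}}}
#' with \eqn{\psi(u) = \max(-b, \min(b, u))}. For a symmetric sample the
#' correction term vanishes and the estimate equals the mean of the
#' central values; for a degenerate sample (MAD 0) the median is
#' returned.
#'
#' @param values numeric vector, length >= 1, no NAs.
#' @param params a [robust_params()] object.
#' @return The location estimate (scalar).
#' @seealso [mad_scale()]
#' @export
mel <- function(values, params = robust_params()) {
  if (length(values) == 0L) stop_fmt("mel(): empty input")
  stopifnot(is.numeric(values), !anyNA(values))
  med <- median(values)
  madn <- stats::mad(values, constant = 1.4826)
  if (madn == 0) return(med)
  u <- (values - med) / madn
  psi <- pmin(pmax(u, -params$bend), params$bend)
  b <- sum(abs(u) <= params$bend)
  med + madn * sum(psi) / b
}

#' MAD scale estimate
#'
#' Median absolute deviation from the median, multiplied by the
#' consistency factor of `params` (1.4826 by default).
#'
#' @inheritParams mel
#' @return The scale estimate (scalar, >= 0).
#' @export
mad_scale <- function(values, params = robust_params()) {
  if (length(values) == 0L) stop_fmt("mad_scale(): empty input")
  stopifnot(is.numeric(values), !anyNA(values))
  stats::mad(values, constant = params$mad_consistency)
}
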