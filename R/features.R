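#' Mean of a lag curve over positive lags
#'
#' Lag 0 is the normalisation point and carries no predictability
#' information, so the mean runs over `tau = 1..tau_max`.  Higher
#' values indicate a more regular (less complex) window.
#'
#' @param curve A [lag_curve()].
#' @return Scalar mean (`NaN` for a degenerate curve).
#' @export
curve_mean <- function(curve) {
  stopifnot(inherits(curve, "lag_curve"))
  mean(curve$values[-1])
}

#' Value at the first relative maximum of a lag curve
#'
#' The value at the smallest lag `tau >= 2` where the curve strictly
#' rises and then does not rise (`v(tau-1) < v(tau) >= v(tau+1)`; a
#' plateau takes its first point).  For AMIF curves of oscillatory
#' signals this sits near one signal period.  Undefined (`NaN`) when
#' the curve is monotone non-increasing.
#'
#' @param curve A [lag_curve()].
#' @return Scalar value, or `NaN` when no relative maximum exists.
#' @export
first_relative_max <- function(curve) {
  stopifnot(inherits(curve, "lag_curve"))
  v <- curve$values
  n <- length(v)
  if (n < 3L || anyNA(v)) return(NaN)
  for (i in 2:(n - 1L)) {
    if (v[i - 1L] < v[i] && v[i] >= v[i + 1L]) return(v[i])
  }
  NaN
}

#' Absolute minimum of a lag curve over positive lags
#'
#' The signed minimum over `tau = 1..tau_max` (autocorrelation curves
#' may go negative; Shannon AMIF curves are nonnegative).
#'
#' @param curve A [lag_curve()].
#' @return Scalar minimum.
#' @export
absolute_min <- function(curve) {
  stopifnot(inherits(curve, "lag_curve"))
  min(curve$values[-1])
}

#' First decay of a lag curve
#'
#' Difference between the lag-0 and lag-1 values; on a normalised
#' curve this is `1 - v(1)`.  Large first decay means the information
#' shared with the 1-sample-lagged copy is quickly lost: a more
#' complex, less predictable window.
#'
#' @param curve A [lag_curve()].
#' @return Scalar first decay.
#' @export
first_decay <- function(curve) {
  stopifnot(inherits(curve, "lag_curve"))
  curve$values[1] - curve$values[2]
}

#' All four scalar measures of a lag curve
#'
#' @param curve A [lag_curve()].
#' @return Named numeric vector with elements `m`, `maxL`, `min`, `FD`.
#' @export
curve_measures <- function(curve) {
  c(m = curve_mean(curve), maxL = first_relative_max(curve),
    min = absolute_min(curve), FD = first_decay(curve))
}

#' Conventional name of a curve-derived measure
#'
#' Builds names like `FD(Re_05)_VHF`, `m(Re_50)_theta`, `min(Sh)_beta`
#' or `maxL(Ac)_alpha`: measure, entropy family with q (two-digit
#' convention: 0.5 -> `05`, 50 -> `50`), and band.  These names key the
#' columns of the wide feature table.
#'
#' @param measure One of `"m"`, `"maxL"`, `"min"`, `"FD"`.
#' @param family `"Sh"`, `"Re"` or `"Ac"`.
#' @param q Renyi q (ignored unless `family == "Re"`).
#' @param band Band name.
#' @return Character scalar.
#' @export
measure_name <- function(measure, family, q = NA_real_, band) {
  fam <- if (family == "Re") paste0("Re_", format_q(q)) else family
  sprintf("%s(%s)_%s", measure, fam, band)
}

#' Two-digit q label used in measure names
#' @param q Renyi control parameter.
#' @return Character label, e.g. `"05"` for 0.5, `"2"` for 2, `"50"`
#'   for 50.
#' @export
format_q <- function(q) {
  ifelse(q < 1, paste0("0", sub("^0\\.", "", format(q, trim = TRUE))),
         format(q, trim = TRUE))
}
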