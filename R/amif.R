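#' Lag curve container
#'
#' Common container for auto-mutual-information and autocorrelation
#' curves: values over integer lags `0..tau_max` together with the
#' entropy family that produced them.
#'
#' @param values Numeric vector of curve values at lags `0, 1, ...`.
#' @param family `"Sh"` (Shannon AMIF), `"Re"` (Renyi AMIF) or `"Ac"`
#'   (autocorrelation).
#' @param q Renyi control parameter (NA otherwise).
#' @param normalized Has the curve been divided by its lag-0 value?
#' @param degenerate Flag set when the underlying window was constant.
#' @return An object of class `lag_curve`.
#' @export
lag_curve <- function(values, family = c("Sh", "Re", "Ac"), q = NA_real_,
                      normalized = FALSE, degenerate = FALSE) {
  family <- match.arg(family)
  structure(list(values = as.numeric(values),
                 lags = seq_along(values) - 1L,
                 family = family, q = q, normalized = normalized,
                 degenerate = degenerate),
            class = "lag_curve")
}

#' @export
print.lag_curve <- function(x, ...) {
  cat(sprintf("<lag_curve %s%s: %d lags%s%s>\n", x$family,
              if (!is.na(x$q)) sprintf("(q=%g)", x$q) else "",
              length(x$values) - 1L,
              if (x$normalized) ", normalized" else "",
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Renyi control parameters used throughout the pipeline
#'
#' The default q grid spans `q < 1` (rare symbol pairs emphasised),
#' and `q > 1` (common pairs emphasised); `q = 1` is the Shannon case,
#' handled by its own estimator.
#' @return Numeric vector of q values.
#' @export
default_q_set <- function() c(0.1, 0.2, 0.5, 2, 3, 5, 10, 30, 50, 100)

#' Entropy specification
#'
#' @param family `"Sh"` for Shannon or `"Re"` for Renyi.
#' @param q Renyi control parameter (`q > 0`, `q != 1`); ignored for
#'   Shannon.
#' @return An object of class `entropy_spec`.
#' @export
entropy_spec <- function(family = c("Sh", "Re"), q = NA_real_) {
  family <- match.arg(family)
  if (family == "Re") {
    if (!is.finite(q) || q <= 0 || q == 1) {
      stop("Renyi q must be > 0 and != 1 (q = 1 is the Shannon case)")
    }
  } else {
    q <- NA_real_
  }
  structure(list(family = family, q = q), class = "entropy_spec")
}

#' Quantize a window into 32 equidistant amplitude bins
#'
#' The amplitude range of the window itself defines the bin edges
#' (recomputed per window), making every AMIF measure invariant to
#' affine amplitude transforms.  The rightmost edge is inclusive, so
#' the maximum maps to bin `n_bins - 1`.
#'
#' @param samples Numeric vector (finite, length >= 2).
#' @param n_bins Number of bins, default 32.
#' @return An object of class `quantized_series`: `symbols` (integers
#'   in `0..n_bins-1`), `n_bins`, `bin_edges` (length `n_bins + 1`) and
#'   `degenerate` (TRUE for constant input, all symbols 0).
#' @export
quantize <- function(samples, n_bins = 32L) {
  x <- as.numeric(samples)
  if (length(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("samples must be finite")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    return(structure(list(symbols = integer(length(x)), n_bins = n_bins,
                          bin_edges = seq(lo, lo + 1, length.out = n_bins + 1),
                          degenerate = TRUE),
                     class = "quantized_series"))
  }
  sym <- as.integer(floor((x - lo) / (hi - lo) * n_bins))
  sym[sym == n_bins] <- n_bins - 1L   # inclusive right edge
  structure(list(symbols = sym, n_bins = as.integer(n_bins),
                 bin_edges = seq(lo, hi, length.out = n_bins + 1),
                 degenerate = FALSE),
            class = "quantized_series")
}

#' Joint and marginal distributions of a lagged symbol pair
#'
#' Builds the joint probability table of pairs `(s_i, s_{i+tau})` over
#' `i = 1..n-tau`, normalised to sum 1; the marginals are the row and
#' column sums of the joint table.
#'
#' @param qs A [quantize()]d series.
#' @param tau Lag in samples (`0 <= tau < n`).
#' @return List with `joint` (n_bins x n_bins matrix), `px` (row sums)
#'   and `py` (column sums).
#' @export
joint_distribution <- function(qs, tau) {
  stopifnot(inherits(qs, "quantized_series"))
  n <- length(qs$symbols)
  if (tau >= n) stop("tau must be smaller than the series length")
  nb <- qs$n_bins
  s1 <- qs$symbols[seq_len(n - tau)]
  s2 <- qs$symbols[seq_len(n - tau) + tau]
  counts <- tabulate(s1 * nb + s2 + 1L, nbins = nb * nb)
  joint <- matrix(counts / (n - tau), nrow = nb, ncol = nb, byrow = TRUE)
  list(joint = joint, px = rowSums(joint), py = colSums(joint))
}

#' Shannon auto-mutual-information curve
#'
#' Mutual information (bits) between the quantized window and its
#' tau-lagged copy for `tau = 0..tau_max`, with the `0 log 0 = 0`
#' convention.  The lag-0 value is the Shannon entropy of the symbol
#' marginal (at most `log2(n_bins)` = 5 bits for 32 bins).
#'
#' @param qs A [quantize()]d series.
#' @param tau_max Maximum lag in samples.
#' @return A [lag_curve()] (family `"Sh"`); a degenerate series yields
#'   an all-`NaN` curve with a warning.
#' @export
amif_shannon <- function(qs, tau_max) {
  curves <- amif_curves(qs, list(entropy_spec("Sh")), tau_max)
  curves[[1]]
}

#' Renyi auto-mutual-information curve
#'
#' Renyi-entropy generalisation of the auto-mutual information:
#' `1/(q-1) * log2( sum_ij P_ij^q / (P_i^(q-1) P_j^(q-1)) )`, summed
#' over cells with nonzero joint probability.  Converges to the
#' Shannon curve as `q -> 1`.
#'
#' @param qs A [quantize()]d series.
#' @param q Control parameter (`q > 0`, `q != 1`).
#' @param tau_max Maximum lag in samples.
#' @return A [lag_curve()] (family `"Re"`).
#' @export
amif_renyi <- function(qs, q, tau_max) {
  if (isTRUE(q == 1)) stop("q = 1 is the Shannon case: use amif_shannon()")
  curves <- amif_curves(qs, list(entropy_spec("Re", q)), tau_max)
  curves[[1]]
}

#' Compute several AMIF curves in one pass
#'
#' Shares the per-lag joint histogram across all requested entropy
#' specifications (the dominant cost), so computing the full Shannon +
#' ten-q Renyi battery costs little more than a single curve.
#'
#' @param qs A [quantize()]d series.
#' @param specs List of [entropy_spec()] objects.
#' @param tau_max Maximum lag in samples (`< n`).
#' @return List of [lag_curve()] objects, one per spec, in order.
#' @export
amif_curves <- function(qs, specs, tau_max) {
  stopifnot(inherits(qs, "quantized_series"), length(specs) >= 1L)
  n <- length(qs$symbols)
  if (tau_max >= n) stop("tau_max must be smaller than the series length")
  fam <- vapply(specs, `[[`, character(1), "family")
  qv <- vapply(specs, `[[`, numeric(1), "q")
  if (qs$degenerate) {
    warning("degenerate (constant) window: AMIF undefined")
    return(lapply(seq_along(specs), function(i) {
      lag_curve(rep(NaN, tau_max + 1L), family = fam[i], q = qv[i],
                degenerate = TRUE)
    }))
  }
  # Shannon encoded as q = 1 for the kernel
  qk <- ifelse(fam == "Sh", 1, qv)
  vals <- amif_all_cpp(qs$symbols, qs$n_bins, as.integer(tau_max),
                       as.numeric(qk))
  lapply(seq_along(specs), function(i) {
    lag_curve(vals[, i], family = fam[i], q = qv[i])
  })
}

#' Normalize a lag curve by its lag-0 value
#'
#' AMIF curves are normalised by their maximum (the lag-0 value), which
#' bounds them to `[0, 1]` for the Shannon family and limits
#' inter-individual amplitude variability of the derived measures.
#' Idempotent.
#'
#' @param curve A [lag_curve()].
#' @return The normalised [lag_curve()]; a zero lag-0 value yields an
#'   all-`NaN` curve with a warning.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "lag_curve"))
  if (curve$normalized) return(curve)
  v0 <- curve$values[1]
  if (!is.finite(v0) || v0 == 0) {
    warning("lag-0 value is zero or undefined: cannot normalize")
    curve$values <- rep(NaN, length(curve$values))
  } else {
    curve$values <- curve$values / v0
  }
  curve$normalized <- TRUE
  curve
}
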