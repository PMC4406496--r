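#' Welch power spectral density estimate
#'
#' Average of Hamming-tapered modified periodograms over one-second
#' segments with 25% overlap.  Density scaling includes the taper power
#' correction, so the integral of the density over frequency matches the
#' mean power of the signal up to discretisation (a Parseval-style
#' consistency used in the test-suite).
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_sec Segment length in seconds (default 1).
#' @param overlap Fractional overlap between segments (default 0.25).
#' @return An object of class `psd_estimate`: list with `freqs` (Hz,
#'   0..fs/2), `density` (uV^2/Hz) and `fs`.
#' @export
welch_psd <- function(samples, fs, seg_sec = 1, overlap = 0.25) {
  x <- as.numeric(samples)
  L <- round(seg_sec * fs)
  if (length(x) < 2L * L) {
    stop("window too short for Welch estimate: need >= ", 2L * L,
         " samples")
  }
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, length(x) - L + 1L, by = hop)
  w <- .hamming(L)
  U <- sum(w^2)                        # taper power correction
  nfreq <- L %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    half <- P[seq_len(nfreq)]
    # fold two-sided density into one-sided
    if (L %% 2 == 0) {
      half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    } else {
      half[2:nfreq] <- 2 * half[2:nfreq]
    }
    acc <- acc + half
  }
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / L,
                 density = acc / length(starts), fs = fs),
            class = "psd_estimate")
}

.hamming <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate: %d bins, 0-%g Hz, total area %.4g uV^2>\n",
              length(x$freqs), max(x$freqs), .trapz(x$freqs, x$density)))
  invisible(x)
}

# trapezoidal area over the whole grid
.trapz <- function(f, y) sum(diff(f) * (utils::head(y, -1) + y[-1]) / 2)

# trapezoidal area of the piecewise-linear density between a and b,
# with exact linear interpolation at the fractional edges
.trapz_between <- function(f, y, a, b) {
  a <- max(a, f[1]); b <- min(b, f[length(f)])
  if (b <= a) return(0)
  ya <- stats::approx(f, y, a)$y
  yb <- stats::approx(f, y, b)$y
  inner <- f > a & f < b
  ff <- c(a, f[inner], b)
  yy <- c(ya, y[inner], yb)
  .trapz(ff, yy)
}

#' Normalized band power
#'
#' Area under the PSD curve over the band, divided by the total PSD
#' area over the full support of the analysed stream (0 to fs/2).
#'
#' @param psd A [welch_psd()] estimate.
#' @param band A [band_definition()].
#' @return Fraction in `[0, 1]`; `NaN` with a warning when the total
#'   power is zero.
#' @export
band_power <- function(psd, band) {
  total <- .trapz(psd$freqs, psd$density)
  if (total <= 0) {
    warning("zero total power: band power undefined")
    return(NaN)
  }
  .trapz_between(psd$freqs, psd$density, band$f_lo, band$f_hi) / total
}

#' Weighted mean (centroid) frequency within a band
#'
#' @param psd A [welch_psd()] estimate.
#' @param band A [band_definition()].
#' @return Centroid frequency in Hz; `NaN` with a warning on zero
#'   in-band power.
#' @export
weighted_mean_frequency <- function(psd, band) {
  denom <- .trapz_between(psd$freqs, psd$density, band$f_lo, band$f_hi)
  if (denom <= 0) {
    warning("zero in-band power: mF undefined")
    return(NaN)
  }
  num <- .trapz_between(psd$freqs, psd$freqs * psd$density,
                        band$f_lo, band$f_hi)
  num / denom
}

#' Spectral edge frequency within a band
#'
#' Smallest frequency below which the given fraction of the in-band
#' spectral area lies, with linear interpolation of the cumulative area
#' between grid points.
#'
#' @param psd A [welch_psd()] estimate.
#' @param band A [band_definition()].
#' @param fraction Edge fraction, typically 0.50, 0.75 or 0.90.
#' @return Frequency in Hz; `NaN` on zero in-band power.
#' @export
spectral_edge <- function(psd, band, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  a <- max(band$f_lo, psd$freqs[1])
  b <- min(band$f_hi, max(psd$freqs))
  ya <- stats::approx(psd$freqs, psd$density, a)$y
  yb <- stats::approx(psd$freqs, psd$density, b)$y
  inner <- psd$freqs > a & psd$freqs < b
  ff <- c(a, psd$freqs[inner], b)
  yy <- c(ya, psd$density[inner], yb)
  areas <- diff(ff) * (utils::head(yy, -1) + yy[-1]) / 2
  cum <- c(0, cumsum(areas))
  total <- cum[length(cum)]
  if (total <= 0) {
    warning("zero in-band power: SEF undefined")
    return(NaN)
  }
  target <- fraction * total
  j <- which(cum >= target)[1]
  if (j == 1L) return(ff[1])
  # linear interpolation in cumulative area
  ff[j - 1] + (ff[j] - ff[j - 1]) * (target - cum[j - 1]) /
    (cum[j] - cum[j - 1])
}

#' Biased sample autocorrelation curve
#'
#' Autocorrelation over lags 0..`max_lag`, normalised so the lag-0
#' value is 1, returned as a lag curve compatible with the curve
#' measures ([curve_measures()]).
#'
#' @param samples Numeric vector.
#' @param max_lag Maximum lag in samples (< length of the window).
#' @return A `lag_curve` object (family `"Ac"`).
#' @export
autocorrelation <- function(samples, max_lag) {
  x <- as.numeric(samples)
  stopifnot(max_lag < length(x))
  if (stats::sd(x) == 0) stop("constant signal: autocorrelation undefined")
  ac <- stats::acf(x, lag.max = max_lag, type = "correlation",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag_curve(ac, family = "Ac", normalized = TRUE)
}
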