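#' Segmentation configuration
#'
#' Pre-event windows are taken nominally between `pre_start` and
#' `pre_end` seconds before the response annotation, to keep the
#' stimulation itself out of the analysed signal.  If the effect-site
#' concentrations drift by more than `dce_prop_max` / `dce_remi_max`
#' between the first and last second of the span, the span is shortened
#' from its start (keeping the pre-event-proximal end) one second at a
#' time until both stability conditions hold; windows shorter than
#' `min_len` are discarded.
#'
#' @param pre_start Seconds before the event where the nominal span
#'   starts (default 90).
#' @param pre_end Seconds before the event where the span ends
#'   (default 30).
#' @param min_len Minimum admissible window length in seconds
#'   (default 50).
#' @param dce_prop_max Propofol stability threshold (ug/ml, default 0.1).
#' @param dce_remi_max Remifentanil stability threshold (ng/ml,
#'   default 0.1).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(pre_start = 90, pre_end = 30, min_len = 50,
                                dce_prop_max = 0.1, dce_remi_max = 0.1) {
  stopifnot(pre_start > pre_end, pre_end >= 0,
            min_len <= pre_start - pre_end, min_len > 0)
  structure(list(pre_start = pre_start, pre_end = pre_end,
                 min_len = min_len, dce_prop_max = dce_prop_max,
                 dce_remi_max = dce_remi_max),
            class = "segmentation_config")
}

#' Resample a signal to a new rate
#'
#' FFT-based rational resampling: the spectrum is truncated at the
#' smaller Nyquist frequency (an ideal anti-alias filter) and inverse
#' transformed on the new grid, so any component below
#' `min(fs_in, fs_out)/2` is preserved essentially exactly away from
#' the window edges.
#'
#' @param samples Numeric vector.
#' @param fs_in,fs_out Input/output sampling rates (Hz).
#' @return Numeric vector of length `round(n * fs_out / fs_in)`.
#' @export
resample_signal <- function(samples, fs_in, fs_out) {
  if (length(samples) == 0L) stop("cannot resample an empty signal")
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(as.numeric(samples))
  n_in <- length(samples)
  n_out <- round(n_in * fs_out / fs_in)
  X <- stats::fft(samples)
  Y <- complex(n_out)
  # number of strictly-positive-frequency bins to keep
  k <- min(n_in, n_out) %/% 2
  Y[1] <- X[1]
  if (k >= 1) {
    Y[2:(k + 1)] <- X[2:(k + 1)]
    Y[n_out - (1:k) + 1] <- X[n_in - (1:k) + 1]
  }
  if (min(n_in, n_out) %% 2 == 0 && k >= 1) {
    # shared Nyquist-edge bin: split evenly to keep the signal real
    Y[k + 1] <- Y[k + 1] / 2
    Y[n_out - k + 1] <- Y[n_out - k + 1] + Y[k + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) * (n_out / n_in) / n_out
}

#' Design an FIR band-pass filter for a band
#'
#' Hamming windowed-sinc design (via [signal::fir1()]) of the given
#' order, scaled to unity gain at the passband centre.  Order 50 is the
#' pipeline default, chosen so stop-band attenuation and ripple stay
#' below 5% in the analysis bands.
#'
#' @param band A [band_definition()].
#' @param order Filter order (number of taps minus one), default 50.
#' @return Numeric vector of `order + 1` symmetric coefficients.
#' @export
design_fir_bandpass <- function(band, order = 50L) {
  fs <- band$fs_target
  if (band$f_hi >= fs / 2) {
    stop(sprintf("band f_hi = %g Hz must lie below Nyquist %g Hz",
                 band$f_hi, fs / 2))
  }
  w <- c(band$f_lo, band$f_hi) / (fs / 2)
  if (w[1] <= 0) {
    # degenerate high-pass edge: plain low-pass
    as.numeric(signal::fir1(order, w[2], type = "low"))
  } else {
    as.numeric(signal::fir1(order, w, type = "pass"))
  }
}

#' Zero-phase band filtering
#'
#' Applies the band's FIR filter forward and backward
#' ([signal::filtfilt()]) so that window-level measures are not
#' lag-shifted; the effective magnitude response is the squared design
#' response.
#'
#' @param samples Numeric vector sampled at `band$fs_target`.
#' @param band A [band_definition()].
#' @param order FIR order, default 50.
#' @return Filtered vector, same length as the input.
#' @export
filter_band <- function(samples, band, order = 50L) {
  b <- design_fir_bandpass(band, order)
  if (length(samples) < 3L * length(b)) {
    stop("input shorter than 3 x filter length (", 3L * length(b),
         " samples)")
  }
  signal::filtfilt(b, 1, as.numeric(samples))
}

#' Suppress high-amplitude peaks via the analytic-signal envelope
#'
#' Computes the instantaneous envelope as the magnitude of the analytic
#' signal (FFT construction of the Hilbert transform) and rescales every
#' sample whose envelope exceeds `k` times the median envelope so that
#' its local envelope equals that threshold.  Peak-free input passes
#' through unchanged; the EEG frequency content of the window is
#' preserved because only amplitudes are rescaled.
#'
#' Because rescaling a sample perturbs the (global) analytic envelope,
#' the rescaling pass is iterated against the threshold fixed by the
#' first-pass median until no envelope sample exceeds it (a handful of
#' FFTs at most), which makes the operation idempotent up to numerical
#' tolerance.
#'
#' @param samples Numeric vector (finite).
#' @param fs Sampling rate (unused by the algorithm, kept for
#'   interface symmetry and logging).
#' @param k Envelope multiplier threshold, default 5.
#' @param max_iter Maximum rescaling passes, default 8.
#' @return Numeric vector, same length.
#' @export
asef_suppress_peaks <- function(samples, fs = NULL, k = 5, max_iter = 8L) {
  x <- as.numeric(samples)
  if (!all(is.finite(x))) stop("samples must be finite")
  n <- length(x)
  if (n < 2L || all(x == 0)) return(x)
  env <- Mod(.analytic_signal(x))
  med <- stats::median(env)
  if (med <= 0) return(x)
  thr <- k * med
  for (it in seq_len(max_iter)) {
    hot <- env > thr * (1 + 1e-6)
    if (!any(hot)) break
    x[hot] <- x[hot] * (thr / env[hot])
    env <- Mod(.analytic_signal(x))
  }
  x
}

# analytic signal z with Re(z) = x, via the one-sided spectrum
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Reject samples after an abrupt amplitude jump
#'
#' Scans forward maintaining the running mean of absolute first
#' differences; at the first index where the current difference exceeds
#' `factor` times that running mean, the window is truncated just
#' before the offending sample and everything from it onward is
#' dropped (abrupt jumps mark electrode/contact artifacts whose
#' aftermath is untrustworthy).
#'
#' The running mean is only trusted after `min_history` differences
#' have been accumulated; with fewer observations a single small first
#' difference would make the rule fire on ordinary signal.
#'
#' @param samples Numeric vector (>= 2 samples).
#' @param factor Exceedance multiplier, default 10.
#' @param min_history Differences required before the rule is armed,
#'   default 50.
#' @return List with `samples` (possibly truncated) and `n_rejected`.
#' @export
reject_jumps <- function(samples, factor = 10, min_history = 50L) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  d <- abs(diff(x))
  cum <- cumsum(d)
  run_mean <- c(Inf, cum[-n] / seq_len(n - 1))[seq_len(n - 1)]
  # run_mean[i] = mean of diffs before diff i (Inf guard for the first)
  if (min_history > 1L) {
    run_mean[seq_len(min(min_history - 1L, n - 1L))] <- Inf
  }
  bad <- which(d > factor * run_mean & run_mean > 0)
  if (length(bad) == 0L) {
    list(samples = x, n_rejected = 0L)
  } else {
    keep <- bad[1]   # d[bad[1]] is the jump x[keep] -> x[keep+1]
    list(samples = x[seq_len(keep)], n_rejected = n - keep)
  }
}

#' Extract a pre-event analysis window
#'
#' Slices the nominal span `[event_time - pre_start, event_time -
#' pre_end)` from a stream of samples, applying the effect-site
#' concentration stability rule of [segmentation_config()]: while the
#' absolute change of either Ce trace between the first and last second
#' of the span exceeds its threshold, the span start advances one
#' second.  Returns `NULL` (with a log message) when the surviving span
#' is shorter than `min_len` or the event sits closer than `pre_start`
#' seconds to the record start.
#'
#' @param samples Stream samples (already resampled/broadband filtered).
#' @param fs Stream sampling rate (Hz).
#' @param event An [event_annotation()].
#' @param ce_prop,ce_remi Per-second concentration traces (may be
#'   `NULL`, in which case the corresponding stability rule is vacuous).
#' @param cfg A [segmentation_config()].
#' @param verbose Emit log messages for skipped events.
#' @return Numeric vector of window samples, with attributes `t0`
#'   (window start, seconds) and `event`, or `NULL`.
#' @export
extract_window <- function(samples, fs, event, ce_prop = NULL,
                           ce_remi = NULL, cfg = segmentation_config(),
                           verbose = FALSE) {
  t_ev <- event$time
  if (t_ev < cfg$pre_start) {
    if (verbose) message(sprintf(
      "event at %.1f s skipped: closer than %g s to record start",
      t_ev, cfg$pre_start))
    return(NULL)
  }
  t0 <- t_ev - cfg$pre_start
  t1 <- t_ev - cfg$pre_end
  ce_at <- function(trace, t) {
    if (is.null(trace)) return(NA_real_)
    trace[min(max(floor(t) + 1, 1), length(trace))]
  }
  stable <- function(t0) {
    dp <- abs(ce_at(ce_prop, t1 - 1) - ce_at(ce_prop, t0))
    dr <- abs(ce_at(ce_remi, t1 - 1) - ce_at(ce_remi, t0))
    (is.na(dp) || dp < cfg$dce_prop_max) &&
      (is.na(dr) || dr < cfg$dce_remi_max)
  }
  while (t0 < t1 && !stable(t0)) t0 <- t0 + 1
  if (t1 - t0 < cfg$min_len) {
    if (verbose) message(sprintf(
      "event at %.1f s skipped: stable span %.0f s < min_len %g s",
      t_ev, t1 - t0, cfg$min_len))
    return(NULL)
  }
  i0 <- floor(t0 * fs) + 1
  i1 <- floor(t1 * fs)
  i1 <- min(i1, length(samples))
  if (i1 - i0 + 1 < cfg$min_len * fs) return(NULL)
  out <- samples[i0:i1]
  attr(out, "t0") <- t0
  attr(out, "event") <- event
  out
}
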