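#' Prepare the two analysis streams of a record
#'
#' Traditional-band analysis runs on the record conditioned to
#' 0.1-45 Hz and resampled to 128 Hz; high-frequency analysis runs on
#' the record conditioned to 0.1-145 Hz and resampled to 300 Hz.  The
#' stream-level conditioning uses the ideal spectral filter inherent in
#' the FFT resampler (bins outside the stream passband are zeroed);
#' the order-50 FIR filters are reserved for the seven analysis bands.
#'
#' @param record An [eeg_record()].
#' @return List with elements `trad` and `hf`, each a list
#'   `(samples, fs)`.
#' @export
prepare_streams <- function(record) {
  list(
    trad = list(samples = .condition_stream(record$samples, record$fs,
                                            128, 0.1, 45), fs = 128),
    hf = list(samples = .condition_stream(record$samples, record$fs,
                                          300, 0.1, 145), fs = 300))
}

# FFT resample + brick-wall band limitation to [f_lo, f_hi]
.condition_stream <- function(samples, fs_in, fs_out, f_lo, f_hi) {
  y <- resample_signal(samples, fs_in, fs_out)
  n <- length(y)
  Y <- stats::fft(y)
  f <- (seq_len(n) - 1) / n * fs_out
  f <- pmin(f, fs_out - f)             # folded frequency axis
  Y[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Default entropy-spec battery
#'
#' Shannon plus the Renyi q grid of [default_q_set()].
#' @param q_set Renyi q values.
#' @return List of [entropy_spec()] objects.
#' @export
default_entropy_specs <- function(q_set = default_q_set()) {
  c(list(entropy_spec("Sh")),
    lapply(q_set, function(q) entropy_spec("Re", q)))
}

#' Compute the per-window measure table of a record
#'
#' Runs the full measurement pipeline: stream preparation, pre-event
#' window extraction with drug-stability truncation, analytic-envelope
#' peak suppression, jump rejection, order-50 FIR band filtering, and
#' then spectral measures (band power, weighted mean frequency,
#' SEF50/75/90, standard deviation) plus the four curve measures
#' (m, maxL, min, FD) of the normalised AMIF curves and of the
#' autocorrelation, per band.
#'
#' @param record An [eeg_record()].
#' @param bands Character vector of canonical band names to analyse.
#' @param specs List of [entropy_spec()] objects for the AMIF battery.
#' @param seg_cfg A [segmentation_config()].
#' @param asef_k Envelope multiplier for [asef_suppress_peaks()].
#' @param jump_factor Exceedance multiplier for [reject_jumps()].
#' @param include_ac Compute autocorrelation curve measures.
#' @param include_spectral Compute spectral measures.
#' @param verbose Log one line per window (band counts, rejected
#'   samples).
#' @return A data frame with one row per usable event: metadata columns
#'   `event_time`, `event_kind`, `event_value`, `n_rejected`, then one
#'   column per measure, named per the glossary convention (e.g.
#'   `P_beta`, `mF_alpha`, `FD(Re_05)_VHF`, `m(Re_50)_theta`,
#'   `min(Ac)_delta`).
#' @export
compute_measures <- function(record,
                             bands = names(canonical_bands()),
                             specs = default_entropy_specs(),
                             seg_cfg = segmentation_config(),
                             asef_k = 5, jump_factor = 10,
                             include_ac = TRUE, include_spectral = TRUE,
                             verbose = FALSE) {
  streams <- prepare_streams(record)
  band_defs <- canonical_bands(bands)
  rows <- list()
  for (ev in record$events) {
    row <- .event_measures(ev, streams, band_defs, specs, record,
                           seg_cfg, asef_k, jump_factor, include_ac,
                           include_spectral, verbose)
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    stop("no usable windows: all events skipped by segmentation/artifacts")
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r$values), check.names = FALSE)
  }))
  meta <- data.frame(
    event_time = vapply(rows, function(r) r$event$time, numeric(1)),
    event_kind = vapply(rows, function(r) r$event$kind, character(1)),
    event_value = vapply(rows, function(r) r$event$value, numeric(1)),
    n_rejected = vapply(rows, function(r) r$n_rejected, numeric(1)))
  cbind(meta, df)
}

.event_measures <- function(ev, streams, band_defs, specs, record,
                            seg_cfg, asef_k, jump_factor, include_ac,
                            include_spectral, verbose) {
  wins <- list()
  n_rej_total <- 0L
  for (snm in c("trad", "hf")) {
    st <- streams[[snm]]
    w <- extract_window(st$samples, st$fs, ev, record$ce_prop,
                        record$ce_remi, seg_cfg, verbose)
    if (is.null(w)) return(NULL)
    w <- asef_suppress_peaks(as.numeric(w), st$fs, k = asef_k)
    rj <- reject_jumps(w, factor = jump_factor)
    if (length(rj$samples) < seg_cfg$min_len * st$fs) {
      if (verbose) message(sprintf(
        "event at %.1f s skipped: %d samples rejected leaves < min_len",
        ev$time, rj$n_rejected))
      return(NULL)
    }
    n_rej_total <- n_rej_total + rj$n_rejected
    wins[[snm]] <- list(samples = rj$samples, fs = st$fs)
  }
  vals <- c()
  psd_cache <- list()
  for (bnm in names(band_defs)) {
    band <- band_defs[[bnm]]
    snm <- if (band$fs_target == 128) "trad" else "hf"
    win <- wins[[snm]]
    if (verbose) message(sprintf(
      "event %.1f s | band %s | %d samples | %d rejected",
      ev$time, bnm, length(win$samples), n_rej_total))
    filtered <- filter_band(win$samples, band)
    if (include_spectral) {
      if (is.null(psd_cache[[snm]])) {
        psd_cache[[snm]] <- welch_psd(win$samples, win$fs)
      }
      psd <- psd_cache[[snm]]
      sp <- c(band_power(psd, band),
              weighted_mean_frequency(psd, band),
              spectral_edge(psd, band, 0.50),
              spectral_edge(psd, band, 0.75),
              spectral_edge(psd, band, 0.90),
              stats::sd(filtered))
      names(sp) <- paste0(c("P_", "mF_", "SEF50_", "SEF75_", "SEF90_",
                            "std_"), bnm)
      vals <- c(vals, sp)
    }
    tau_max <- win$fs                  # 1 s horizon at the stream rate
    qs <- quantize(filtered)
    curves <- amif_curves(qs, specs, tau_max)
    for (i in seq_along(specs)) {
      cm <- curve_measures(normalize_curve(curves[[i]]))
      names(cm) <- vapply(names(cm), measure_name, character(1),
                          family = specs[[i]]$family, q = specs[[i]]$q,
                          band = bnm)
      vals <- c(vals, cm)
    }
    if (include_ac) {
      ac <- autocorrelation(filtered, tau_max)
      cm <- curve_measures(ac)
      names(cm) <- vapply(names(cm), measure_name, character(1),
                          family = "Ac", q = NA_real_, band = bnm)
      vals <- c(vals, cm)
    }
  }
  list(event = ev, values = vals, n_rejected = n_rej_total)
}
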