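#' Event annotation
#'
#' One annotated stimulation event: either an RSS score (Ramsay sedation
#' scale, 2-6) observed after nail-bed compression, or a GAG flag (0/1)
#' observed at endoscopy tube insertion.
#'
#' @param time Seconds from record start.
#' @param kind `"RSS"` or `"GAG"`.
#' @param value RSS score in 2..6, or GAG flag 0/1.
#' @return An object of class `event_annotation`.
#' @export
event_annotation <- function(time, kind, value) {
  kind <- match.arg(kind, c("RSS", "GAG"))
  if (!is.finite(time) || time < 0) stop("event time must be finite and >= 0")
  if (kind == "RSS" && !(value %in% 2:6)) {
    stop("RSS value must be one of 2,3,4,5,6; got ", value)
  }
  if (kind == "GAG" && !(value %in% c(0, 1))) {
    stop("GAG value must be 0 or 1; got ", value)
  }
  structure(list(time = as.numeric(time), kind = kind,
                 value = as.numeric(value)),
            class = "event_annotation")
}

#' EEG recording with annotation streams
#'
#' Container for one sedation session: the raw single-channel EEG
#' (microvolts) plus per-second annotation streams — predicted
#' effect-site concentrations of propofol (`ce_prop`, ug/ml) and
#' remifentanil (`ce_remi`, ng/ml), an optional BIS trace, and the list
#' of stimulation events.
#'
#' @param samples Numeric vector of EEG amplitudes (uV).
#' @param fs Sampling rate in Hz (> 0).
#' @param events List of [event_annotation()] objects.
#' @param ce_prop,ce_remi,bis Optional numeric per-second traces
#'   (1 sample per second, starting at t = 0).
#' @param subject_id Opaque identifier string.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, events = list(), ce_prop = NULL,
                       ce_remi = NULL, bis = NULL, subject_id = "anon") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single finite value > 0")
  }
  samples <- as.numeric(samples)
  dur <- length(samples) / fs
  events <- lapply(events, function(ev) {
    if (!inherits(ev, "event_annotation")) {
      ev <- event_annotation(ev$time, ev$kind, ev$value)
    }
    if (ev$time > dur) {
      stop(sprintf("event at t = %g s lies beyond record duration %g s",
                   ev$time, dur))
    }
    ev
  })
  for (nm in c("ce_prop", "ce_remi", "bis")) {
    tr <- get(nm)
    if (!is.null(tr) && !is.numeric(tr)) stop(nm, " trace must be numeric")
  }
  structure(list(samples = samples, fs = fs, events = events,
                 ce_prop = ce_prop, ce_remi = ce_remi, bis = bis,
                 subject_id = subject_id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s': %d samples @ %g Hz (%.1f s), %d events%s>\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, length(x$events),
              if (!is.null(x$bis)) ", BIS" else ""))
  invisible(x)
}

#' Record duration in seconds
#' @param record An [eeg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$fs

.sidecar_paths <- function(path) {
  stem <- sub("\\.[^.]*$", "", path)
  list(events = paste0(stem, "_events.csv"),
       traces = paste0(stem, "_traces.csv"))
}

#' Read an EEG record
#'
#' Reads the EEG signal from `path` (CSV dialect: header row, columns
#' `t_s, eeg_uV`; or 16-bit EDF) and, when present, the sidecar
#' annotation CSV (`<stem>_events.csv`: columns `t_s, kind, value`) and
#' per-second trace CSV (`<stem>_traces.csv`: columns
#' `t_s, ce_prop, ce_remi, bis`).  Missing sidecars yield absent fields,
#' not errors.  For EDF input the first signal channel is taken as the
#' EEG channel.
#'
#' @param path Path to the signal file.
#' @param dialect `"csv"` or `"edf"`.
#' @param subject_id Identifier stored on the record; defaults to the
#'   file stem.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, dialect = c("csv", "edf"),
                        subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "csv") {
    sig <- utils::read.csv(path)
    if (!all(c("t_s", "eeg_uV") %in% names(sig))) {
      stop("signal CSV must have columns t_s, eeg_uV; got: ",
           paste(names(sig), collapse = ", "))
    }
    if (nrow(sig) < 2L) stop("signal CSV needs at least 2 rows")
    dt <- diff(sig$t_s[1:2])
    if (!is.finite(dt) || dt <= 0) {
      stop("bad time step in first rows of ", path)
    }
    fs <- 1 / dt
    samples <- sig$eeg_uV
  } else {
    edf <- read_edf(path)
    fs <- edf$fs[1]
    samples <- edf$signals[[1]]
  }
  side <- .sidecar_paths(path)
  events <- list()
  if (file.exists(side$events)) {
    ev <- utils::read.csv(side$events)
    events <- lapply(seq_len(nrow(ev)), function(i) {
      event_annotation(ev$t_s[i], ev$kind[i], ev$value[i])
    })
  }
  ce_prop <- ce_remi <- bis <- NULL
  if (file.exists(side$traces)) {
    tr <- utils::read.csv(side$traces)
    if ("ce_prop" %in% names(tr)) ce_prop <- tr$ce_prop
    if ("ce_remi" %in% names(tr)) ce_remi <- tr$ce_remi
    if ("bis" %in% names(tr) && !all(is.na(tr$bis))) bis <- tr$bis
  }
  eeg_record(samples, fs, events, ce_prop, ce_remi, bis, subject_id)
}

#' Write an EEG record
#'
#' Inverse of [read_record()]: writes the signal file plus the sidecar
#' event/trace CSVs next to it (only for streams present on the
#' record).  CSV output round-trips samples at full double precision;
#' EDF output quantises to the 16-bit EDF grid.
#'
#' @param record An [eeg_record()].
#' @param path Output path for the signal file.
#' @param dialect `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  n <- length(record$samples)
  if (dialect == "csv") {
    t_s <- (seq_len(n) - 1) / record$fs
    df <- data.frame(t_s = t_s, eeg_uV = record$samples)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    write_edf(path, list(EEG = record$samples), record$fs)
  }
  side <- .sidecar_paths(path)
  if (length(record$events)) {
    ev <- data.frame(
      t_s = vapply(record$events, `[[`, numeric(1), "time"),
      kind = vapply(record$events, `[[`, character(1), "kind"),
      value = vapply(record$events, `[[`, numeric(1), "value"))
    utils::write.csv(ev, side$events, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(record$ce_prop) || !is.null(record$ce_remi) ||
      !is.null(record$bis)) {
    len <- max(length(record$ce_prop), length(record$ce_remi),
               length(record$bis))
    pad <- function(x) if (is.null(x)) rep(NA_real_, len) else x
    tr <- data.frame(t_s = seq_len(len) - 1, ce_prop = pad(record$ce_prop),
                     ce_remi = pad(record$ce_remi), bis = pad(record$bis))
    utils::write.csv(tr, side$traces, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
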