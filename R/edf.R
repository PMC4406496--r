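## Minimal European Data Format (EDF) support: plain 16-bit EDF,
## ASCII headers, little-endian data records.  Enough to exchange
## single-channel EEG with standard biosignal tools; no EDF+
## annotations (events travel in the CSV sidecars).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF file
#'
#' @param path Path to a 16-bit EDF file.
#' @return A list with elements `signals` (named list of numeric
#'   vectors, physical units), `fs` (per-signal sampling rates, Hz) and
#'   `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  n_records <- as.integer(field(237, 8))
  rec_dur <- as.numeric(field(245, 8))
  ns <- as.integer(field(253, 4))
  if (!is.finite(ns) || ns < 1L) stop("unparseable EDF header in ", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfield <- function(offset, len) {
    vapply(seq_len(ns) - 1L, function(i) {
      trimws(substr(sig_hdr, offset * ns + i * len + 1,
                    offset * ns + (i + 1) * len))
    }, character(1))
  }
  labels <- sfield(0L, 16L)
  phys_min <- as.numeric(sfield(104L, 8L))   # after label+transducer+dim
  phys_max <- as.numeric(sfield(112L, 8L))
  dig_min <- as.numeric(sfield(120L, 8L))
  dig_max <- as.numeric(sfield(128L, 8L))
  spr <- as.integer(sfield(216L, 8L))        # samples per data record
  sigs <- vector("list", ns)
  for (i in seq_len(ns)) sigs[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      sigs[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  list(signals = stats::setNames(sigs, labels),
       fs = spr / rec_dur, labels = labels)
}

#' Write an EDF file
#'
#' Signals are scaled to the full 16-bit digital range; the physical
#' range is taken from the data.  Signal length must be a whole number
#' of seconds (1 s data records).
#'
#' @param path Output path.
#' @param signals Named list of numeric vectors (equal durations).
#' @param fs Sampling rate in Hz (integer, shared by all signals).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs) {
  ns <- length(signals)
  stopifnot(ns >= 1L, !is.null(names(signals)))
  if (fs != round(fs)) stop("EDF writer requires an integer fs")
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop("all signals must have equal length")
  if (n %% fs != 0) {
    stop("EDF writer requires a whole number of seconds (n divisible by fs)")
  }
  n_records <- n %/% fs
  phys_min <- vapply(signals, function(x) min(x, -1e-6), numeric(1))
  phys_max <- vapply(signals, function(x) max(x, 1e-6), numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) {
    writeBin(charToRaw(.edf_pad(x, width)), con)
  }
  put("0", 8); put("X X X X", 80); put("Startdate X X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256L * (1L + ns), 8); put("", 44)
  put(n_records, 8); put(format(1), 8); put(ns, 4)
  for (nm in names(signals)) put(nm, 16)
  for (i in seq_len(ns)) put("", 80)            # transducer
  for (i in seq_len(ns)) put("uV", 8)           # physical dimension
  for (i in seq_len(ns)) put(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) put(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) put("-32768", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80)            # prefiltering
  for (i in seq_len(ns)) put(as.integer(fs), 8) # samples per record
  for (i in seq_len(ns)) put("", 32)
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][(r - 1) * fs + seq_len(fs)]
      dig <- round((seg - phys_min[i]) / scale[i]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
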