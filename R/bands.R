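#' Frequency band definition
#'
#' A band is a named passband together with the sampling rate of the
#' processing stream it is analysed on.  The traditional EEG bands
#' (delta, theta, alpha, beta) live on the 128 Hz stream; the
#' high-frequency bands (HF 60-95 Hz, VHF 105-145 Hz) and the total band
#' (TB 0.1-145 Hz) live on the 300 Hz stream, where scalp/facial EMG
#' dominates the biopotential.
#'
#' @param name Band name, one of `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"HF"`, `"VHF"`, `"TB"` (free names are allowed for
#'   ad-hoc bands).
#' @param f_lo,f_hi Passband edges in Hz, `0 <= f_lo < f_hi <= fs_target/2`.
#' @param fs_target Sampling rate (Hz) of the stream the band is
#'   filtered on.
#' @return An object of class `band_definition`.
#' @seealso [canonical_bands()]
#' @export
band_definition <- function(name, f_lo, f_hi, fs_target) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || !is.finite(fs_target) ||
      fs_target <= 0) {
    stop("band edges and fs_target must be finite, fs_target > 0")
  }
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= fs_target / 2)) {
    stop(sprintf("invalid band [%g, %g] Hz at fs_target = %g Hz", f_lo, f_hi,
                 fs_target))
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 fs_target = fs_target),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz @ %g Hz>\n", x$name, x$f_lo, x$f_hi,
              x$fs_target))
  invisible(x)
}

# fixed canonical band table; greek labels kept for display only
.canonical_band_table <- list(
  delta = c(0.1, 4,   128),
  theta = c(4,   8,   128),
  alpha = c(8,   12,  128),
  beta  = c(12,  30,  128),
  HF    = c(60,  95,  300),
  VHF   = c(105, 145, 300),
  TB    = c(0.1, 145, 300)
)

#' Canonical analysis bands
#'
#' Returns the seven canonical bands in fixed order: delta 0.1-4 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz (all on the 128 Hz
#' stream), HF 60-95 Hz, VHF 105-145 Hz and TB 0.1-145 Hz (on the
#' 300 Hz stream).  Mains interference around 50 Hz and the device
#' self-test peak around 100 Hz fall outside every passband by
#' construction, so no notch filtering is applied anywhere in the
#' pipeline.
#'
#' @param names Optional character vector restricting (and reordering)
#'   the returned bands.
#' @return A named list of [band_definition()] objects.
#' @export
canonical_bands <- function(names = NULL) {
  tab <- .canonical_band_table
  if (!is.null(names)) {
    bad <- setdiff(names, base::names(tab))
    if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "))
    tab <- tab[names]
  }
  out <- lapply(base::names(tab), function(nm) {
    v <- tab[[nm]]
    band_definition(nm, v[1], v[2], v[3])
  })
  stats::setNames(out, base::names(tab))
}

#' Display label for a canonical band name
#'
#' Maps the ASCII band keys used in code and column names to the
#' conventional greek symbols used in figures.
#' @param name Character vector of band names.
#' @return Character vector of labels.
#' @export
band_label <- function(name) {
  map <- c(delta = "δ", theta = "θ", alpha = "α",
           beta = "β", HF = "HF", VHF = "VHF", TB = "TB")
  out <- unname(map[name])
  out[is.na(out)] <- name[is.na(out)]
  out
}
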