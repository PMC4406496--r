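# shared fixture builders: everything generated in code, no stored data

sinusoid <- function(freq, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs + phase)
}

# band-limited unit-RMS noise via spectral truncation (independent of
# the package's internal generator helper)
test_band_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# tiny record with one RSS event and stable concentrations
tiny_record <- function(fs = 300, dur = 200, rss = 5, ev_time = 150,
                        seed = 1) {
  set.seed(seed)
  eeg_record(stats::rnorm(dur * fs, sd = 10), fs,
             events = list(event_annotation(ev_time, "RSS", rss)),
             ce_prop = rep(2, dur), ce_remi = rep(1, dur),
             subject_id = "tiny")
}

# literal nested-sum AMIF oracle (Shannon and Renyi), built from raw
# pair counting -- independent of the package's kernel and of
# joint_distribution()
oracle_amif <- function(sym, nbins, tau, q = 1) {
  n <- length(sym)
  s1 <- sym[seq_len(n - tau)]
  s2 <- sym[seq_len(n - tau) + tau]
  pj <- matrix(0, nbins, nbins)
  for (i in seq_along(s1)) pj[s1[i] + 1, s2[i] + 1] <- pj[s1[i] + 1, s2[i] + 1] + 1
  pj <- pj / (n - tau)
  px <- rowSums(pj); py <- colSums(pj)
  total <- 0
  for (a in seq_len(nbins)) for (b in seq_len(nbins)) {
    p <- pj[a, b]
    if (p > 0) {
      if (q == 1) {
        total <- total + p * log2(p / (px[a] * py[b]))
      } else {
        total <- total + p^q / (px[a]^(q - 1) * py[b]^(q - 1))
      }
    }
  }
  if (q == 1) total else log2(total) / (q - 1)
}

# brute-force Pk oracle: explicit double loop over between-class pairs
oracle_pk <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  conc <- ties <- 0
  for (a in s1) for (b in s0) {
    if (a > b) conc <- conc + 1 else if (a == b) ties <- ties + 1
  }
  (conc + 0.5 * ties) / (length(s1) * length(s0))
}
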