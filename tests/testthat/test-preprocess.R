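test_that("resampling preserves a 10 Hz sinusoid from 900 to 128 Hz", {
  x <- sinusoid(10, 900, 60)
  y <- resample_signal(x, 900, 128)
  expect_length(y, 60 * 128)
  # steady-state amplitude within 2% of 1 (edges excluded)
  mid <- y[500:7000]
  ref <- sinusoid(10, 128, 60)[500:7000]
  expect_lt(max(abs(mid - ref)), 0.02)
  # identity when rates match
  expect_identical(resample_signal(x, 900, 900), x)
  expect_error(resample_signal(numeric(0), 900, 128), "empty")
})

test_that("FIR band filters are symmetric with unity passband gain", {
  bands <- canonical_bands()
  b <- design_fir_bandpass(bands$alpha)
  expect_length(b, 51)
  expect_equal(b, rev(b), tolerance = 1e-12)
  # frequency-response oracle: evaluate the designed filter directly
  gain_at <- function(coef, f, fs) {
    Mod(sum(coef * exp(-2i * pi * f / fs * (seq_along(coef) - 1))))
  }
  expect_gt(gain_at(b, 10, 128), 0.95)
  expect_lt(gain_at(b, 10, 128), 1.05)
  btb <- design_fir_bandpass(bands$TB)
  expect_gt(gain_at(btb, 120, 300), 0.9)
  expect_error(design_fir_bandpass(band_definition("x", 10, 64, 128)),
               "Nyquist")
})

test_that("zero-phase band filtering passes in-band and rejects out-of-band", {
  bands <- canonical_bands()
  x <- sinusoid(10, 128, 30)
  rms <- function(v) sqrt(mean(v^2))
  y_alpha <- filter_band(x, bands$alpha)
  expect_equal(rms(y_alpha) / rms(x), 1, tolerance = 0.05)
  y_theta <- filter_band(x, bands$theta)
  expect_lt(rms(y_theta) / rms(x), 0.15)
  expect_equal(filter_band(numeric(1000), bands$alpha), numeric(1000))
  expect_error(filter_band(rnorm(100), bands$alpha), "shorter")
  # zero-phase: cross-correlation peak of in-band signal at lag 0
  set.seed(4)
  xb <- test_band_noise(128 * 20, 128, 8, 12)
  yb <- filter_band(xb, bands$alpha)
  cc <- ccf(xb, yb, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("window extraction truncates by concentration stability", {
  fs <- 128
  dur <- 200
  set.seed(9)
  x <- rnorm(dur * fs)
  ev <- event_annotation(150, "RSS", 5)
  flat <- rep(1, dur)
  # stable concentrations: full 60 s window
  w <- extract_window(x, fs, ev, flat, flat)
  expect_length(w, 60 * fs)
  expect_equal(attr(w, "t0"), 60)
  # step ramp (0.2/s) until t = 70 forces truncation to exactly 50 s
  ce <- c(seq(0, 14, by = 0.2), rep(14, dur - 71))
  w2 <- extract_window(x, fs, ev, ce_prop = flat, ce_remi = ce)
  expect_length(w2, 6400)
  expect_equal(attr(w2, "t0"), 70)
  # stability only over the final 40 s: window discarded
  ce3 <- c(seq(0, 16, by = 0.2), rep(16, dur - 81))
  expect_null(extract_window(x, fs, ev, ce_prop = flat, ce_remi = ce3))
  # event too close to the record start is skipped
  expect_null(extract_window(x, fs, event_annotation(50, "RSS", 5),
                             flat, flat))
})

test_that("ASEF suppression removes peaks, preserves clean signal", {
  s <- sinusoid(5, 300, 10)
  expect_equal(asef_suppress_peaks(s, 300), s, tolerance = 1e-9)
  expect_equal(asef_suppress_peaks(numeric(600), 300), numeric(600))
  sp <- s
  sp[1500] <- 20
  out <- asef_suppress_peaks(sp, 300, k = 5)
  expect_length(out, length(sp))
  # derived check: recompute the envelope of the result
  env_of <- function(x) {
    n <- length(x)
    X <- fft(x)
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else h[2:((n + 1) / 2)] <- 2
    Mod(fft(X * h, inverse = TRUE) / n)
  }
  thr <- 5 * median(env_of(sp))
  expect_lt(max(env_of(out)), thr * 1.02)
  # idempotent on its own output
  expect_equal(asef_suppress_peaks(out, 300, k = 5), out,
               tolerance = 1e-4)
})

test_that("jump rejection truncates at an abrupt step and is idempotent", {
  x <- sinusoid(3, 128, 20)
  r <- reject_jumps(x, factor = 10)
  expect_equal(r$n_rejected, 0L)
  set.seed(6)
  xs <- rnorm(3000)
  md <- mean(abs(diff(xs[1:1000])))
  xs[1001:3000] <- xs[1001:3000] + 100 * md
  r2 <- reject_jumps(xs, factor = 10)
  expect_length(r2$samples, 1000)
  expect_equal(r2$n_rejected, 2000L)
  # idempotent on its own output
  r3 <- reject_jumps(r2$samples, factor = 10)
  expect_equal(r3$n_rejected, 0L)
  # constant signal: all diffs zero, rule vacuously passes
  rc <- reject_jumps(rep(3, 500))
  expect_equal(rc$n_rejected, 0L)
  expect_error(reject_jumps(1), "at least 2")
})
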