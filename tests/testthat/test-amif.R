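test_that("quantization partitions the amplitude range into 32 bins", {
  # ramp over [0, 32): each bin holds an equal count
  qs <- quantize(seq(0, 31.999, length.out = 3200))
  expect_equal(unname(tabulate(qs$symbols + 1, 32)), rep(100L, 32))
  expect_false(qs$degenerate)
  # exact maximum goes to the last bin, not one past it
  expect_equal(max(qs$symbols), 31L)
  q2 <- quantize(c(0, 1, 2, 3, 4))
  expect_equal(q2$symbols[5], 31L)
  # constant input: degenerate, all symbols zero
  qc <- quantize(rep(2.5, 100))
  expect_true(qc$degenerate)
  expect_true(all(qc$symbols == 0L))
  expect_error(quantize(c(1, NA, 3)), "finite")
  expect_error(quantize(1), "at least 2")
})

test_that("joint distributions are normalized with marginal consistency", {
  set.seed(12)
  qs <- quantize(rnorm(500))
  for (tau in c(0, 1, 7)) {
    jd <- joint_distribution(qs, tau)
    expect_equal(sum(jd$joint), 1, tolerance = 1e-12)
    expect_equal(rowSums(jd$joint), jd$px, tolerance = 1e-12)
    expect_equal(colSums(jd$joint), jd$py, tolerance = 1e-12)
  }
  # tau = 0: all mass on the diagonal
  jd0 <- joint_distribution(qs, 0)
  expect_equal(sum(diag(jd0$joint)), 1, tolerance = 1e-12)
  # alternating symbols at lag 1 occupy exactly two cells
  qa <- quantize(rep(c(0, 1), 50))
  ja <- joint_distribution(qa, 1)
  expect_equal(sum(ja$joint > 0), 2)
  expect_error(joint_distribution(qs, 500), "smaller")
})

test_that("Shannon AMIF attains the 5-bit ceiling on uniform symbols", {
  qs <- quantize(seq(0, 31.99, length.out = 3200))
  cur <- amif_shannon(qs, 5)
  expect_equal(cur$values[1], 5, tolerance = 1e-12)
  # Renyi at tau = 0 on uniform symbols is also 5 bits for any q
  for (q in c(0.2, 2, 30)) {
    expect_equal(amif_renyi(qs, q, 2)$values[1], 5, tolerance = 1e-9)
  }
})

test_that("AMIF implementation matches the literal nested-sum oracle", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    qs <- quantize(x, n_bins = 8)
    tau_max <- min(5, n - 2)
    curves <- amif_curves(qs, list(entropy_spec("Sh"),
                                   entropy_spec("Re", 0.5),
                                   entropy_spec("Re", 3)), tau_max)
    for (tau in 0:tau_max) {
      expect_equal(curves[[1]]$values[tau + 1],
                   oracle_amif(qs$symbols, 8, tau, q = 1),
                   tolerance = 1e-12)
      expect_equal(curves[[2]]$values[tau + 1],
                   oracle_amif(qs$symbols, 8, tau, q = 0.5),
                   tolerance = 1e-12)
      expect_equal(curves[[3]]$values[tau + 1],
                   oracle_amif(qs$symbols, 8, tau, q = 3),
                   tolerance = 1e-12)
    }
  }
})

test_that("Renyi AMIF converges to the Shannon curve as q -> 1", {
  set.seed(14)
  qs <- quantize(rnorm(3000))
  sh <- amif_shannon(qs, 30)$values
  for (q in c(1 - 1e-3, 1 + 1e-3)) {
    re <- amif_renyi(qs, q, 30)$values
    expect_lt(max(abs(re - sh)), 1e-2)
  }
  expect_error(amif_renyi(qs, 1, 10), "Shannon")
})

test_that("Shannon AMIF is nonnegative, bounded by its lag-0 value, and
           symmetric under time reversal", {
  set.seed(15)
  for (rep in 1:5) {
    x <- test_band_noise(1500, 300, 5, 100)
    qs <- quantize(x)
    cur <- amif_shannon(qs, 40)
    expect_true(all(cur$values >= 0))
    expect_true(all(cur$values <= cur$values[1] + 1e-9))
    # reversal: identical pair sets at every lag
    qr <- qs
    qr$symbols <- rev(qs$symbols)
    expect_equal(amif_shannon(qr, 40)$values, cur$values,
                 tolerance = 1e-12)
  }
})

test_that("AMIF is invariant to affine amplitude transforms", {
  set.seed(16)
  x <- rnorm(2000)
  c1 <- amif_shannon(quantize(x), 20)$values
  c2 <- amif_shannon(quantize(3.7 * x - 11), 20)$values
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("deterministic structure shows up at the right lags", {
  # period-2 symbol sequence: lag-2 information equals lag-0
  qa <- quantize(rep(c(0, 5), 100))
  cur <- amif_shannon(qa, 4)
  expect_equal(cur$values[3], cur$values[1], tolerance = 1e-12)
  # independent shuffled symbols: near-zero information at lag 1
  set.seed(17)
  qs <- quantize(sample(rnorm(20000)))
  expect_lt(amif_shannon(qs, 1)$values[2], 0.2)
})

test_that("normalization divides by the lag-0 value and is idempotent", {
  set.seed(18)
  qs <- quantize(rnorm(1000))
  cur <- amif_shannon(qs, 10)
  nrm <- normalize_curve(cur)
  expect_equal(nrm$values[1], 1)
  expect_true(nrm$normalized)
  expect_identical(normalize_curve(nrm), nrm)
  expect_equal(nrm$values, cur$values / cur$values[1], tolerance = 1e-12)
  # degenerate series propagates NaN with warnings
  expect_warning(bad <- amif_shannon(quantize(rep(1, 50)), 5),
                 "degenerate")
  expect_true(all(is.nan(bad$values)))
})
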