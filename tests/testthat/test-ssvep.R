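mkStimRecording <- function(data, fs, onsets) {
  Recording(data, fs,
            channelNames = c(paste0("E", seq_len(nrow(data) - 1)), "ECG"),
            events = data.frame(sample = as.integer(onsets),
                                kind = "stimulus"))
}

test_that("linear detrending removes its own model exactly", {
  fs <- 500
  n <- 2000
  t <- seq_len(n)
  line <- 3 + 0.02 * t
  rec <- mkStimRecording(rbind(line, 0 * t), fs, onsets = 500)
  ep <- epochAndClean(rec)
  expect_lt(max(abs(ep@data[1, 1, ])), 1e-9)
})

test_that("the 700-uV rejection flags exactly the right trials", {
  fs <- 500
  n <- 20000
  set.seed(5)
  x <- rnorm(n, 0, 10)
  onsets <- c(2000L, 6000L, 10000L)
  # post-detrend maxima about 100 / 800 / 400 uV
  x[2201] <- 100; x[6201] <- 800; x[10201] <- 400
  rec <- mkStimRecording(rbind(x, rep(0, n)), fs, onsets)
  ep <- epochAndClean(rec)
  expect_identical(ep@kept, c(TRUE, FALSE, TRUE))
  # rejected trials stay in storage
  expect_identical(dim(ep@data)[1], 3L)
})

test_that("generator-spiked trials are exactly the rejected ones", {
  sess <- cachedSession(duration_s = 180, n_spiked_trials = 5, seed = 6,
                        key = "spiked")
  ep <- epochAndClean(sess$recording)
  expect_identical(which(!ep@kept), as.integer(sess$truth$spiked_trials))
  expect_identical(sum(!ep@kept), 5L)
})

test_that("Morlet TFR peaks at the carrier and vanishes on silence", {
  fs <- 500
  n <- 3000
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 15 * t)
  rec <- mkStimRecording(rbind(x, rep(0, n)), fs, onsets = 1000)
  tfr <- morletTFR(epochAndClean(rec), freqs = 5:30)
  midT <- which(tfr@times > 0.2 & tfr@times < 0.8)
  prof <- rowMeans(tfr@power[1, , midT])
  expect_identical(tfr@freqs[which.max(prof)], 15)
  z <- morletTFR(epochAndClean(mkStimRecording(matrix(0, 2, n), fs, 1000)),
                 freqs = c(10, 15))
  expect_true(all(z@power == 0))
  expect_error(morletTFR(epochAndClean(rec), freqs = c(15, 300)), "Nyquist")
})

test_that("a 15-Hz burst lifts in-window power 10x above baseline", {
  fs <- 500
  n <- 5000
  t <- (seq_len(n) - 1) / fs
  onset <- 2000L
  x <- rnorm(n, 0, 0.05)
  w <- t >= (onset / fs + 0.2) & t <= (onset / fs + 1.0)
  x[w] <- x[w] + 5 * sin(2 * pi * 15 * t[w])
  rec <- mkStimRecording(rbind(x, rep(0, n)), fs, onset)
  tfr <- morletTFR(epochAndClean(rec), freqs = c(10, 15, 20))
  inWin <- evokedPower(tfr, channels = 1, window = c(0.25, 0.95))
  base <- evokedPower(tfr, channels = 1, window = c(-0.2, -0.05))
  expect_gt(inWin / base, 10)
})

test_that("evoked power averages constants and scales quadratically", {
  fs <- 500
  n <- 4000
  t <- (seq_len(n) - 1) / fs
  mk <- function(a) mkStimRecording(rbind(a * sin(2 * pi * 15 * t),
                                          rep(0, n)), fs, 1000)
  tfr1 <- morletTFR(epochAndClean(mk(1)), freqs = c(10, 15, 20))
  tfr2 <- morletTFR(epochAndClean(mk(2)), freqs = c(10, 15, 20))
  p1 <- evokedPower(tfr1, channels = 1, window = c(0.3, 0.9))
  p2 <- evokedPower(tfr2, channels = 1, window = c(0.3, 0.9))
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
  # constant power returns that constant
  tfrC <- tfr1
  tfrC@power[] <- 7
  expect_equal(evokedPower(tfrC, channels = 1:2), 7)
  expect_error(evokedPower(tfr1, channels = "Oz"), "not found")
  expect_error(evokedPower(tfr1, channels = 1, freqHz = 17), "17")
})

test_that("recovered sinusoid power matches the analytic wavelet response", {
  # L2-normalized Morlet at the carrier: |response|^2 = A^2/4 * 2 sigma sqrt(pi) fs
  fs <- 500
  A <- 5
  n <- 6000
  t <- (seq_len(n) - 1) / fs
  x <- A * sin(2 * pi * 15 * t)
  rec <- mkStimRecording(rbind(x, rep(0, n)), fs, 2500)
  tfr <- morletTFR(epochAndClean(rec), freqs = 15)
  got <- evokedPower(tfr, channels = 1, window = c(0.3, 0.9))
  sigma <- 5 / (2 * pi * 15)
  expected <- A^2 / 4 * 2 * sigma * sqrt(pi) * fs
  expect_lt(abs(got / expected - 1), 0.2)
})

test_that("noise normalization divides by baseline SD and is scale-free", {
  fs <- 500
  n <- 6000
  set.seed(2)
  x <- rnorm(n)
  rec <- mkStimRecording(rbind(x, rnorm(n)), fs, c(2000L, 4000L))
  tfr <- morletTFR(epochAndClean(rec), freqs = c(10, 15))
  nn <- noiseNormalize(tfr)
  bi <- which(tfr@times >= -0.2 & tfr@times <= 0)
  s <- sd(tfr@power[1, 2, bi])
  expect_equal(nn@power[1, 2, ], tfr@power[1, 2, ] / s)
  # scaling the recording leaves the normalized TFR unchanged
  rec10 <- mkStimRecording(recData(rec) * 10, fs, c(2000L, 4000L))
  nn10 <- noiseNormalize(morletTFR(epochAndClean(rec10), freqs = c(10, 15)))
  expect_equal(nn10@power, nn@power, tolerance = 1e-9)
  # white-noise-only epochs normalize to O(1)
  post <- which(nn@times > 0.2)
  expect_lt(median(nn@power[1, 2, post]), 50)
  expect_gt(median(nn@power[1, 2, post]), 0.02)
  degen <- tfr
  degen@power[1, 1, bi] <- 3
  expect_error(noiseNormalize(degen), "zero SD")
})

test_that("ROC/AUC behaves at the separable, chance and enumerated cases", {
  expect_equal(rocAuc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(rocAuc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc,
               0.5)
  r <- rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(31)
  for (i in 1:10) {
    stat <- rnorm(40)
    truth <- stat * 0.8 + rnorm(40) > 0
    if (!any(truth) || all(truth)) next
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(truth, stat, quiet = TRUE,
                                     direction = "<"))))
    expect_equal(rocAuc(stat, truth)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(4)
  for (i in 1:20) {
    stat <- rnorm(30)
    truth <- stat + rnorm(30) > 0.2
    if (!any(truth) || all(truth)) next
    a0 <- rocAuc(stat, truth)$auc
    expect_equal(rocAuc(exp(stat), truth)$auc, a0)
    expect_equal(rocAuc(atan(stat / 3), truth)$auc, a0)
  }
})

test_that("bootstrap comparison is seeded, calibrated and sensitive", {
  a <- c(1.0, 1.2, 0.9, 1.1, 1.05)
  r1 <- bootstrapCompare(a, a + 10, seed = 7)
  r2 <- bootstrapCompare(a, a + 10, seed = 7)
  expect_identical(r1$t, r2$t)
  expect_identical(r1$p, r2$p)
  expect_lt(r1$p, 0.001)
  # identical samples resample along the same seed path: never significant
  nonsig <- vapply(1:100, function(s) {
    set.seed(s)
    v <- rnorm(8)
    bootstrapCompare(v, v, seed = 1000 + s)$p > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.95)
  expect_error(bootstrapCompare(a, a, nBoot = 1), "nBoot")
})
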