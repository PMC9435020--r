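test_that("zero jitter and zero respiration give perfectly regular beats", {
  cfg <- synthConfig(duration_s = 30, rr_jitter_sd_s = 0, rr_resp_amp_s = 0,
                     seed = 1)
  ek <- synthEKG(cfg)
  expect_true(all(diff(ek$r_peaks) == cfg$mean_rr_s * cfg$fs))
})

test_that("RR statistics match the configured jitter over long runs", {
  means <- sds <- numeric(10)
  for (s in 1:10) {
    cfg <- synthConfig(duration_s = 300, seed = s)
    ek <- synthEKG(cfg)
    rr <- diff(ek$r_peaks) / cfg$fs
    means[s] <- mean(rr); sds[s] <- sd(rr)
  }
  expect_lt(abs(mean(means) - 1.0), 0.02)
  expect_lt(abs(mean(sds) - 0.05) / 0.05, 0.30)
})

test_that("the generator is deterministic given its seed", {
  cfg <- synthConfig(duration_s = 20, seed = 7)
  a <- composeRecording(cfg)
  b <- composeRecording(cfg)
  expect_identical(recData(a$recording), recData(b$recording))
  expect_identical(a$truth$r_peaks, b$truth$r_peaks)
  expect_identical(a$truth$stim_onsets, b$truth$stim_onsets)
  # and the serialized fixture is byte-identical across runs
  f1 <- file.path(tempfile(), "a.fx"); f2 <- file.path(tempfile(), "b.fx")
  writeFixture(a$recording, f1); writeFixture(b$recording, f2)
  expect_identical(tools::md5sum(file.path(f1, "data.bin"))[[1]],
                   tools::md5sum(file.path(f2, "data.bin"))[[1]])
})

test_that("unmodulated BCG repeats identically within the amplitude range", {
  cfg <- synthConfig(duration_s = 40, rr_jitter_sd_s = 0, rr_resp_amp_s = 0,
                     bcg_mod = 0, ekg_mod = 0, ekg_noise_uv = 0, seed = 1)
  ek <- synthEKG(cfg)
  bcg <- synthBCG(ek, cfg)
  pk <- ek$r_peaks
  seg <- function(m) bcg[1, pk[m]:(pk[m] + 400)]
  expect_lt(max(abs(seg(5) - seg(10))), 1e-9)
  expect_gte(max(abs(bcg)), 150)
  expect_lte(max(abs(bcg)), 200)
})

test_that("BCG modulation is a deterministic function of the beat dynamics", {
  cfg <- synthConfig(duration_s = 20, seed = 2)
  # beats on an exact sample grid with alternating +/-10% RR deviation
  nb <- 18
  tR <- 0.5 + (seq_len(nb) - 1) * 1.0
  ek <- list(t_r = tR, r_peaks = round(tR * cfg$fs) + 1L,
             rr_s = rep(1, nb),
             rr_dev = rep(c(0.1, -0.1), length.out = nb),
             resp_phase = rep(0, nb))
  bcg <- synthBCG(ek, cfg)
  pk <- ek$r_peaks
  seg <- function(m) bcg[1, pk[m] + 120:380]
  # same-deviation beats match; opposite-deviation beats differ
  expect_lt(max(abs(seg(5) - seg(7))), 1e-9)
  expect_gt(max(abs(seg(5) - seg(6))), 1)
})

test_that("default BCG stays inside the specified amplitude range", {
  sess <- cachedSession(duration_s = 120, seed = 3, key = "dmh120")
  m <- max(abs(sess$truth$bcg))
  expect_gte(m, 150)
  expect_lte(m, 200)
})

test_that("neural component: silent SSVEP, carrier purity, stimulus count", {
  cfg0 <- synthConfig(duration_s = 60, ssvep_amp_uv = 0, seed = 4)
  neu0 <- synthNeural(cfg0)
  # evoked average of pure noise is near zero relative to noise scale
  on <- neu0$stim_onsets
  epochs <- sapply(on[on + 500 <= ncol(neu0$neural)],
                   function(o) neu0$neural[29, o:(o + 499)])
  expect_lt(max(abs(rowMeans(epochs))), 3)

  # burst-only channel: exact 15-Hz carrier
  cfgB <- synthConfig(duration_s = 60, noise_pink_uv = 0, noise_white_uv = 0,
                      seed = 4)
  neuB <- synthNeural(cfgB)
  o1 <- neuB$stim_onsets[2]
  x <- neuB$neural[29, (o1 + 100):(o1 + 400)]   # plateau of the burst
  sp <- Mod(fft(x))[1:150]
  fgrid <- (0:149) * cfgB$fs / length(x)
  expect_lt(abs(fgrid[which.max(sp)] - 15), 1.7)

  # counting bound on the number of stimuli
  cfg6 <- synthConfig(duration_s = 360, seed = 5)
  neu6 <- synthNeural(cfg6)
  expect_gte(length(neu6$stim_onsets),
             0.5 * cfg6$duration_s / (cfg6$min_isi_s + cfg6$stim_dur_s))
})

test_that("components sum exactly to the recording and GA toggles", {
  sess <- cachedSession(duration_s = 60, seed = 3, key = "io60")
  eeg <- channelsByRole(sess$recording, "EEG")
  expect_identical(recData(sess$recording)[eeg, ],
                   sess$truth$neural + sess$truth$bcg + sess$truth$ga)
  expect_true(all(sess$truth$ga == 0))
  expect_false(any(recEvents(sess$recording)$kind == "volume_trigger"))
  ga <- composeRecording(synthConfig(duration_s = 20, ga_enabled = TRUE,
                                     seed = 1))
  expect_true(any(recEvents(ga$recording)$kind == "volume_trigger"))
  expect_gt(max(abs(ga$truth$ga)), 0)
})

test_that("beats with nearest EKG embeddings have more similar artifacts", {
  # the premise of dynamic modeling: EKG dynamics predict BCG shape
  diffs <- matrix(0, 5, 2)
  for (s in 1:5) {
    cfg <- synthConfig(duration_s = 120, seed = s)
    sess <- cachedSession(duration_s = 120, seed = s,
                          key = paste0("prem", s))
    tr <- sess$truth
    q <- QRSAnnotations(tr$r_peaks, cfg$fs)
    ekg <- tr$ekg
    dcfg <- dmhConfig(e = 8, tau = 10, n = 1, exclusion_radius = 1)
    man <- buildManifold(ekg, q, phi = 0, dcfg)
    segLen <- 350
    usable <- man$cycles[tr$r_peaks[man$cycles] + segLen <=
                           ncol(tr$bcg)]
    segRMS <- function(a, b)
      sqrt(mean((tr$bcg[1, tr$r_peaks[a] + 0:segLen] -
                   tr$bcg[1, tr$r_peaks[b] + 0:segLen])^2))
    nnD <- vapply(usable, function(m) {
      ns <- findNeighbors(man, m, dcfg)
      if (ns$empty || !(ns$cycles[1] %in% usable)) return(NA_real_)
      segRMS(m, ns$cycles[1])
    }, numeric(1))
    set.seed(s)
    rndD <- vapply(usable, function(m) {
      other <- setdiff(usable, c(m - 1, m, m + 1))
      segRMS(m, sample(other, 1))
    }, numeric(1))
    diffs[s, ] <- c(mean(nnD, na.rm = TRUE), mean(rndD))
  }
  expect_lt(mean(diffs[, 1]), mean(diffs[, 2]))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synthConfig(min_isi_s = 0.5, stim_dur_s = 1), "min_isi")
  expect_error(synthConfig(rr_jitter_sd_s = 0.3), "refractory")
  expect_error(synthConfig(duration_s = 2), "5 s")
  expect_error(synthConfig(ssvep_amp_uv = -1), "amplitudes")
})
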