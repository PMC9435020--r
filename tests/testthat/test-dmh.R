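test_that("phase map assigns cardiac coordinates and inverts exactly", {
  q <- QRSAnnotations(c(100, 600, 1100), 500)
  pm <- buildPhaseMap(q, 1500)
  expect_identical(pm$cycle[650], 2L)
  expect_identical(pm$phi[650], 50L)
  expect_true(is.na(pm$cycle[50]))          # before the first peak
  expect_true(is.na(pm$cycle[1101]))        # at/after the last peak
  expect_error(buildPhaseMap(QRSAnnotations(100, 500), 1500), "2 R peaks")
})

test_that("phase map is a bijection on its assigned domain", {
  set.seed(11)
  pk <- sort(sample(5000, 12))
  q <- QRSAnnotations(pk, 500)
  pm <- buildPhaseMap(q, 5000)
  assigned <- which(!is.na(pm$cycle))
  expect_identical(assigned, seq.int(pk[1], pk[length(pk)] - 1L))
  expect_identical(pm$inverse(pm$cycle[assigned], pm$phi[assigned]), assigned)
  expect_true(all(pm$phi[assigned] >= 0))
  rr <- diff(pk)
  expect_true(all(pm$phi[assigned] < rr[pm$cycle[assigned]]))
})

test_that("manifold rows are lagged EKG samples with the eligibility rule", {
  ekg <- as.numeric(1:1000)
  q <- QRSAnnotations(c(100, 300, 500, 700, 995), 500)
  cfg <- dmhConfig(e = 2, tau = 10)
  man <- buildManifold(ekg, q, phi = 5, cfg)
  # each row is a pair of EKG samples 10 apart at latency 5
  expect_identical(man$cycles, 1:4)
  expect_equal(man$vectors[1, ], c(ekg[105], ekg[115]))
  expect_equal(man$vectors[3, ], c(ekg[505], ekg[515]))
  # a cycle whose last lagged sample overruns the recording is dropped
  man2 <- buildManifold(ekg, q, phi = 0, dmhConfig(e = 3, tau = 10))
  expect_false(5L %in% man2$cycles)   # 995 + 20 > 1000
  expect_true(4L %in% man2$cycles)
  # constant EKG: all rows equal, all pairwise distances zero
  man3 <- buildManifold(rep(7, 1000), q, phi = 0, cfg)
  expect_true(all(man3$vectors == 7))
})

test_that("neighbor search matches simple 1-D expectations and tie-breaks", {
  ekg <- rep(0, 500)
  pk <- c(10, 110, 210, 310, 410)
  ekg[pk] <- c(0, 1, 3, 7, 0)
  q <- QRSAnnotations(pk, 500)
  cfg <- dmhConfig(e = 2, tau = 50, n = 2, exclusion_radius = 0)
  man <- buildManifold(ekg, q, 0, cfg)
  ns <- findNeighbors(man, 1, cfg)
  expect_identical(ns$cycles, c(2L, 3L))
  expect_equal(ns$distances, c(1, 3))
  # identical rows: stable order by ascending cycle index
  manEq <- buildManifold(rep(2, 500), q, 0, cfg)
  nsEq <- findNeighbors(manEq, 3, dmhConfig(e = 2, tau = 50, n = 3,
                                            exclusion_radius = 0))
  expect_identical(nsEq$cycles, c(1L, 2L, 4L))
  expect_true(all(nsEq$distances == 0))
})

test_that("neighbor search equals a brute-force all-pairs sort", {
  set.seed(3)
  fs <- 250
  nCyc <- 200
  pk <- round(cumsum(c(50, rnorm(nCyc, fs, fs * 0.05))))
  ekg <- rnorm(max(pk) + 200)
  q <- QRSAnnotations(pk, fs)
  cfg <- dmhConfig(e = 8, tau = 7, n = 10, exclusion_radius = 1)
  man <- buildManifold(ekg, q, phi = 12, cfg)
  for (m in sample(man$cycles, 50)) {
    ns <- findNeighbors(man, m, cfg)
    # oracle: exhaustive distances over all manifold rows
    qi <- match(m, man$cycles)
    d <- sqrt(colSums((t(man$vectors) - man$vectors[qi, ])^2))
    keep <- abs(man$cycles - m) > cfg$exclusion_radius
    o <- order(d, man$cycles)
    o <- o[keep[o]][1:cfg$n]
    expect_identical(ns$cycles, man$cycles[o])
    expect_equal(ns$distances, d[o])
  }
})

test_that("weights follow the kernel law and normalize", {
  expect_equal(computeWeights(rep(2.5, 6)), rep(1 / 6, 6))
  expect_equal(computeWeights(1.7), 1)
  d <- c(0, 1, 2)
  u <- exp(d[1] - d)                 # 1, e^-1, e^-2
  expect_equal(computeWeights(d, "exp_diff"), u / sum(u))
  us <- exp(-c(1, 2, 3) / 1)
  expect_equal(computeWeights(c(1, 2, 3), "sugihara"), us / sum(us))
  # sugihara fallback at d1 = 0: uniform over zero-distance neighbors
  expect_equal(computeWeights(c(0, 0, 5), "sugihara"), c(0.5, 0.5, 0))
  expect_error(computeWeights(numeric(0)), "empty")
  expect_error(computeWeights(c(2, 1)), "ascending")
})

test_that("weights sum to one and never increase with distance", {
  set.seed(21)
  for (i in 1:200) {
    d <- sort(runif(sample(1:15, 1), 0, 10))
    for (k in c("exp_diff", "sugihara")) {
      w <- computeWeights(d, k)
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_true(all(w >= 0))
      expect_true(all(diff(w) <= 1e-15))
    }
  }
})

test_that("a cycle-invariant artifact is reproduced exactly", {
  # identical EKG and EEG in every cycle: interpolating identical segments
  fs <- 250
  beat <- numeric(250)
  beat[30:32] <- c(5, 40, -10)
  beat[85:124] <- sin(seq(0, pi, length.out = 40)) * 8
  nCyc <- 24
  ekg <- rep(beat, nCyc)
  art <- rep(cos(2 * pi * (0:249) / 250) * 100, nCyc)
  pk <- seq(31, by = 250, length.out = nCyc)
  rec <- Recording(rbind(art, art / 2, ekg), fs,
                   channelNames = c("C3", "C4", "ECG"))
  q <- QRSAnnotations(pk, fs)
  est <- suppressWarnings(estimateArtifact(rec, q, dmhConfig(e = 4, tau = 5, n = 5)))
  cov <- coverageMask(est)
  expect_gt(mean(cov), 0.8)
  expect_lt(max(abs(est@data[1, cov] - art[cov])), 1e-9)
  expect_lt(max(abs(est@data[2, cov] - art[cov] / 2)), 1e-9)
})

test_that("estimate of cardiac-independent white noise shrinks its variance", {
  set.seed(8)
  fs <- 250
  nCyc <- 40
  pk <- seq(20, by = 250, length.out = nCyc)
  n <- max(pk) + 300
  ekg <- rep(0, n); ekg[pk] <- 800
  noise <- rnorm(n)
  rec <- Recording(rbind(noise, ekg), fs, channelNames = c("Cz", "ECG"))
  q <- QRSAnnotations(pk, fs)
  cfg <- dmhConfig(e = 4, tau = 5, n = 10)
  est <- suppressWarnings(estimateArtifact(rec, q, cfg))
  cov <- coverageMask(est)
  # each estimate is a convex combination of >= n other noise samples:
  # Var <= sum(w^2) <= weight bound; empirically well below the input variance
  ratio <- var(est@data[1, cov]) / var(noise)
  expect_lt(ratio, 0.5)
})

test_that("the modeled trace tracks the BCG, not the neural signal", {
  sess <- cachedSession(duration_s = 120, seed = 3, key = "dmh120")
  rec <- sess$recording; tr <- sess$truth
  q <- detectQRS(rec)
  # two-dimensional embedding with five neighbors: the illustrative setting
  est <- suppressWarnings(
    estimateArtifact(rec, q, dmhConfig(e = 2, tau = 10, n = 5)))
  cov <- coverageMask(est)
  ch <- 1
  cb <- cor(est@data[ch, cov], tr$bcg[ch, cov])
  cn <- cor(est@data[ch, cov], tr$neural[ch, cov])
  expect_gt(cb, cn)
  expect_gt(cb, 0.8)
})

test_that("subtraction is the exact inverse of adding the estimate", {
  sess <- cachedSession(duration_s = 60, seed = 3, key = "io60")
  rec <- sess$recording
  q <- detectQRS(rec)
  est <- suppressWarnings(estimateArtifact(rec, q, dmhConfig()))
  clean <- suppressBCG(rec, est)
  eeg <- channelsByRole(rec, "EEG")
  back <- recData(clean)[eeg, ] + est@data
  expect_lt(max(abs(back - recData(rec)[eeg, ])) / max(abs(recData(rec))),
            1e-12)
  # EKG passes through and events are preserved
  expect_identical(ekgChannel(clean), ekgChannel(rec))
  expect_identical(recEvents(clean), recEvents(rec))
  # zero artifact: identity
  zero <- new("ArtifactEstimate", data = matrix(0, length(eeg), nSamples(rec)),
              coverage = rep(FALSE, nSamples(rec)),
              channelNames = channelNames(rec)[eeg])
  expect_identical(recData(suppressBCG(rec, zero)), recData(rec))
})

test_that("the artifact estimate is linear in the EEG at fixed EKG/QRS", {
  set.seed(14)
  fs <- 250
  cfgS <- synthConfig(duration_s = 40, fs = fs, n_eeg_channels = 2, seed = 9)
  ek <- synthEKG(cfgS)
  n <- length(ek$ekg)
  x <- matrix(rnorm(2 * n), 2, n)
  y <- matrix(rnorm(2 * n), 2, n)
  q <- QRSAnnotations(ek$r_peaks, fs)
  mk <- function(mat) Recording(rbind(mat, ek$ekg), fs,
                                channelNames = c("C3", "C4", "ECG"))
  cfg <- dmhConfig(e = 4, tau = 8, n = 5)
  ex <- suppressWarnings(estimateArtifact(mk(x), q, cfg))@data
  ey <- suppressWarnings(estimateArtifact(mk(y), q, cfg))@data
  exy <- suppressWarnings(estimateArtifact(mk(2 * x - 0.5 * y), q, cfg))@data
  expect_lt(max(abs(exy - (2 * ex - 0.5 * ey))) / max(abs(exy)), 1e-9)
})

test_that("with exclusion radius 1 the estimate never reads adjacent cycles", {
  sess <- cachedSession(duration_s = 60, seed = 3, key = "io60")
  rec <- sess$recording
  q <- detectQRS(rec)
  pk <- peaks(q)
  cfg <- dmhConfig()
  est0 <- suppressWarnings(estimateArtifact(rec, q, cfg))
  m <- 20L
  # perturb the EEG inside cycles m-1, m, m+1 only
  pert <- rec
  zone <- pk[m - 1]:(pk[m + 2] - 1)
  eeg <- channelsByRole(rec, "EEG")
  pert@data[eeg, zone] <- pert@data[eeg, zone] + 1000
  est1 <- suppressWarnings(estimateArtifact(pert, q, cfg))
  inM <- pk[m]:(pk[m + 1] - 1)
  expect_identical(est0@data[, inM], est1@data[, inM])
})

test_that("DMH is deterministic", {
  sess <- cachedSession(duration_s = 60, seed = 3, key = "io60")
  q <- detectQRS(sess$recording)
  a <- suppressWarnings(estimateArtifact(sess$recording, q, dmhConfig()))
  b <- suppressWarnings(estimateArtifact(sess$recording, q, dmhConfig()))
  expect_identical(a@data, b@data)
  expect_identical(a@coverage, b@coverage)
})
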