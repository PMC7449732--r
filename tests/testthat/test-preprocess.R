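fullScale <- chargeToPower(detectorSpec()@fullWell, timingScheme()@tLong)

test_that("channel pruning applies the intensity, SNR and saturation rules", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 100L
  set.seed(21)
  mk <- function(mean, relSd) mean * (1 + rnorm(nt, sd = relSd))
  P <- matrix(0, nrow(ch), nt)
  for (r in seq_len(nrow(ch))) P[r, ] <- mk(1e-3 * fullScale, 0.01)

  # constant bright channel passes (zero-sd convention)
  P[1, ] <- 1e-3 * fullScale
  # pair (channel 3 + its 855 partner): mean below 500 ppm of full scale
  key <- paste(ch$source, ch$detector)
  p3 <- which(key == key[3])
  for (r in p3) P[r, ] <- mk(400e-6 * fullScale, 0.01)
  # pair of channel 5: SNR below 12
  p5 <- which(key == key[5])
  for (r in p5) P[r, ] <- mk(1e-3 * fullScale, 1 / 5)
  cs <- makeIntensitySeries(P)
  good <- pruneChannels(cs)
  expect_true(good[1])
  expect_false(any(good[p3]))
  expect_false(any(good[p5]))
  expect_true(all(good[-c(p3, p5)]))

  # one bad wavelength kills the dual-wavelength pair
  P2 <- P
  partner <- setdiff(which(key == key[1]), 1L)
  P2[partner, ] <- mk(100e-6 * fullScale, 0.01)
  expect_false(pruneChannels(makeIntensitySeries(P2))[1])

  # ever-saturated channels are excluded when flagged
  ch2 <- ch; ch2$saturatedEver <- FALSE; ch2$saturatedEver[7] <- TRUE
  cs2 <- channelSeries(list(intensity = P), ch2, sampleTimes(cs))
  g2 <- pruneChannels(cs2)
  expect_false(any(g2[which(key == key[7])]))
  expect_error(pruneChannels(channelSeries(
    list(intensity = P[, 0, drop = FALSE]), ch,
    numeric(0))), "zero-length")
})

test_that("optical-density conversion is exact and flags bad channels", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 101L
  P <- matrix(2e-9, nrow(ch), nt)
  cs <- makeIntensitySeries(P)
  od <- SummarizedExperiment::assay(intensityToOd(cs), "od")
  expect_true(all(od == 0))

  # a sample at mean * exp(-1) has OD exactly 1
  P2 <- P
  a <- exp(-1) * (100 * 2e-9) / (101 - exp(-1))  # solves a = mean * e^-1
  P2[1, 1] <- a
  od2 <- SummarizedExperiment::assay(intensityToOd(makeIntensitySeries(P2)),
                                     "od")
  expect_equal(od2[1, 1], 1)

  # non-positive sample: channel flagged and excluded
  P3 <- P; P3[2, 5] <- 0
  odc <- intensityToOd(makeIntensitySeries(P3))
  expect_false(channelInfo(odc)$odValid[2])
  expect_true(all(is.na(SummarizedExperiment::assay(odc, "od")[2, ])))
})

test_that("motion detection marks planted artifacts and walking blocks", {
  rate <- 3
  tms <- seq(0, 200, by = 1 / rate)
  clean <- 0.05 * sin(2 * pi * 0.1 * tms)
  env0 <- detectMotion(rbind(clean), rate = rate)
  expect_false(any(env0$perSeries))
  expect_equal(env0$burden, 0)

  # planted spike: envelope covers the spike +/- pad
  x <- clean
  spikeIdx <- which.min(abs(tms - 100))
  x[spikeIdx + 0:2] <- x[spikeIdx + 0:2] + c(1, 0.6, 0.3)
  env <- detectMotion(rbind(x), rate = rate)
  expect_true(all(env$collapsed[tms >= 99.5 & tms <= 101]))
  expect_false(any(env$collapsed[tms < 95 | tms > 106]))

  # artifact burden is invariant to channel order and scale
  y <- 2 * x
  e2 <- detectMotion(rbind(x, y), rate = rate, ampThresh = 0.5)
  e3 <- detectMotion(rbind(y, x), rate = rate, ampThresh = 0.5 / 1)
  expect_equal(mean(e2$collapsed), mean(e3$collapsed))

  # walking-block accelerometer trace: envelope ~ the whole blocks
  wb <- data.frame(start = c(40, 120), end = c(60, 140))
  mp <- simulateMpu(duration = 200, nModules = 1, walkingBlocks = wb,
                    seed = 9)
  envM <- detectMotion(mp, window = 1, stdMult = 5, ampThresh = 0.2,
                       maskPad = 1)
  tmsM <- seq(0, 200, by = 1 / mp@rate)
  inBlocks <- (tmsM >= 40 & tmsM <= 60) | (tmsM >= 120 & tmsM <= 140)
  expect_gt(mean(envM$collapsed[inBlocks]), 0.95)
  expect_lt(mean(envM$collapsed[!inBlocks]), 0.2)

  expect_error(detectMotion(rbind(clean), rate = rate, window = 1000),
               "window")
})

test_that("band-pass filter has the commanded frequency response", {
  rate <- 3
  tms <- seq(0, 600, by = 1 / rate)
  resp <- function(f, dc = 0) {
    x <- dc + sin(2 * pi * f * tms)
    y <- bandpassFilter(rbind(x), rate = rate)[1, ]
    core <- tms > 60 & tms < 540          # trim filter edges
    sd(y[core]) / sd(x[core])
  }
  # DC attenuated by >= 40 dB
  dc <- bandpassFilter(rbind(rep(1, length(tms))), rate = rate)[1, ]
  expect_lt(max(abs(dc[tms > 60 & tms < 540])), 0.01)
  # 0.1 Hz in the passband within 1 dB
  expect_gt(resp(0.1), 10^(-1 / 20))
  # 1.1 Hz cardiac attenuated by >= 20 dB
  expect_lt(resp(1.1), 10^(-20 / 20))
  expect_error(bandpassFilter(rbind(sin(tms)), band = c(0.01, 2), rate = 3),
               "Nyquist")
})

test_that("kurtosis-wavelet correction removes spikes, keeps responses", {
  set.seed(13)
  n <- 512L
  g <- rnorm(n)
  # Gaussian-only input passes through nearly unchanged
  gc <- waveletCorrect(g)
  expect_gt(cor(g, gc), 0.99)

  # HRF-like responses over physiological oscillations + spike
  tms <- seq(0, by = 1 / 3, length.out = n)
  resp <- 0.1 * (hrfDoubleGamma(tms - 30) + hrfDoubleGamma(tms - 90) +
                   hrfDoubleGamma(tms - 150))
  phys <- 0.02 * sin(2 * pi * 0.1 * tms) + 0.01 * sin(2 * pi * 0.25 * tms + 1)
  x <- resp + phys + rnorm(n, sd = 0.005)
  spike <- which.min(abs(tms - 60)) + 0:1
  xs <- x; xs[spike] <- xs[spike] + c(1.2, 0.7)
  fixed <- waveletCorrect(xs)
  excBefore <- max(abs(xs[spike] - x[spike]))
  excAfter <- max(abs(fixed[spike] - x[spike]))
  expect_gt(excBefore / excAfter, 5)
  # block response amplitude preserved within 10%
  pk <- tms > 35 & tms < 42
  expect_equal(mean(fixed[pk]), mean(x[pk]), tolerance = 0.1)
  # non-artifact segments barely touched
  quiet <- tms > 115 & tms < 145
  expect_gt(cor(fixed[quiet], xs[quiet]), 0.95)

  # idempotence: second pass changes the output by < 1% RMS
  second <- waveletCorrect(fixed)
  expect_lt(sqrt(mean((second - fixed)^2)) / sd(fixed), 0.01)

  # transform itself is perfectly invertible
  expect_lt(max(abs(idwt(dwt(xs)) - xs)), 1e-10)
  expect_error(dwt(rnorm(8), levels = 4), "too short")
})

test_that("Beer-Lambert conversion round-trips known concentrations", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 50L
  ext <- extinctionTable()
  dpf <- c(`740` = 7.5, `855` = 7)
  tms <- seq(0, by = 1 / 3, length.out = nt)
  hboT <- 5e-6 * sin(2 * pi * 0.05 * tms)
  hbrT <- -2e-6 * sin(2 * pi * 0.05 * tms)
  od <- matrix(0, nrow(ch), nt)
  for (r in seq_len(nrow(ch))) {
    e <- ext[match(ch$wavelength[r], ext$wavelength), ]
    od[r, ] <- (e$hbo * hboT + e$hbr * hbrT) * ch$separation[r] *
      dpf[[as.character(ch$wavelength[r])]]
  }
  cs <- channelSeries(list(od = od), ch, tms)
  conc <- mbll(cs)
  hbo <- SummarizedExperiment::assay(conc, "HbO")
  hbr <- SummarizedExperiment::assay(conc, "HbR")
  expect_equal(nrow(hbo), 8L)
  for (r in seq_len(8)) {
    expect_equal(hbo[r, ], hboT, tolerance = 1e-10)
    expect_equal(hbr[r, ], hbrT, tolerance = 1e-10)
  }

  # zero OD maps to zero concentrations
  conc0 <- mbll(channelSeries(list(od = od * 0), ch, tms))
  expect_true(all(SummarizedExperiment::assay(conc0, "HbO") == 0))

  # linearity: doubling the separation halves recovered concentrations
  ch2 <- ch; ch2$separation <- 2 * ch$separation
  conc2 <- mbll(channelSeries(list(od = od), ch2, tms))
  expect_equal(SummarizedExperiment::assay(conc2, "HbO"), hbo / 2,
               tolerance = 1e-10)
})
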