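test_that("channel enumeration matches the probe combinatorics", {
  lay12 <- arrayLayout(2, 6)
  ch <- enumerateChannels(lay12, 740)
  expect_equal(nrow(ch), 1152L)

  ch1 <- enumerateChannels(lay1, 740)
  expect_equal(nrow(ch1), 8L)
  expect_equal(sort(round(ch1$separation)), c(10, 10, 23, 23, 23, 23, 28, 28))

  ch2 <- enumerateChannels(lay2, c(740, 855))
  expect_equal(nrow(ch2), 64L)

  # brute-force oracle: every source x detector pair, for M <= 4 modules
  for (m in 1:4) {
    lay <- arrayLayout(1, m)
    pos <- optodePositions(lay)
    cnt <- 0L
    for (s in seq_len(nrow(pos$sources)))
      for (d in seq_len(nrow(pos$detectors))) cnt <- cnt + 1L
    expect_equal(nrow(enumerateChannels(lay, 740)), cnt)
    expect_equal(cnt, 8L * m^2)
  }

  expect_error(enumerateChannels(lay1, numeric(0)), "wavelength")
})

test_that("charge-to-power conversion reproduces the device figures", {
  expect_equal(chargeToPower(50, 6.3), 16.3e-9, tolerance = 0.01)
  expect_equal(chargeToPower(0.63e-3, 6.3), 205e-15, tolerance = 0.01)
  expect_identical(chargeToPower(0, 5), 0)
  expect_error(chargeToPower(1, 0), "positive")
  expect_error(powerToCharge(1e-9, -1), "positive")

  # round trip to 1 part in 1e12
  q <- c(1e-4, 0.63e-3, 1, 50)
  expect_equal(powerToCharge(chargeToPower(q, 6.3), 6.3), q,
               tolerance = 1e-12)
})

test_that("NEP from dark measurements recovers the generating noise", {
  expect_equal(nepFromDark(rep(3, 100)), 0)
  expect_error(nepFromDark(1), "2 dark samples")

  # charge std exactly the converter RMS noise -> approx 205 fW
  expect_equal(chargeToPower(sd(c(-0.63e-3, 0.63e-3)) / sqrt(2) * sqrt(2),
                             6.3),
               chargeToPower(sd(c(-0.63e-3, 0.63e-3)), 6.3))
  dk <- c(-1, 1) * 0.63e-3 / sqrt(2) * sqrt(100 / 99)  # sd = 0.63 fC
  expect_equal(nepFromDark(c(rep(dk, 50))), 205e-15, tolerance = 0.02)

  # Monte-Carlo: generating power-equivalent std of 318 fW, 1e4 samples
  qSd <- powerToCharge(318e-15, 6.3)
  set.seed(42)
  dark <- rnorm(1e4, mean = 0.01, sd = qSd)
  expect_equal(nepFromDark(dark), 318e-15, tolerance = 0.03)

  # matrix input: one NEP per detector row
  dm <- rbind(dark, rnorm(1e4, sd = qSd * 2))
  neps <- nepFromDark(dm)
  expect_length(neps, 2L)
  expect_gt(neps[2], neps[1])
})

test_that("dynamic range matches the charge- and power-domain figures", {
  expect_equal(dynamicRangeDb(16.3e-9, 318e-15), 94.2, tolerance = 0.1 / 94.2)
  expect_equal(dynamicRangeDb(50, 0.63e-3), 98, tolerance = 0.1 / 98)
  expect_equal(dynamicRangeDb(7, 7), 0)
  expect_error(dynamicRangeDb(-1, 1), "positive")

  # log additivity
  set.seed(7)
  for (k in 1:10) {
    abc <- sort(runif(3, 1e-12, 1))
    expect_equal(dynamicRangeDb(abc[3], abc[2]) + dynamicRangeDb(abc[2], abc[1]),
                 dynamicRangeDb(abc[3], abc[1]))
  }
})

test_that("dual-integration gain and frame rate follow the timing scheme", {
  expect_equal(effectiveGainRatio(), 315)
  expect_gt(effectiveGainRatio(), 300)
  expect_equal(effectiveGainRatio(tauMin = 0.1), 63)
  expect_equal(effectiveGainRatio(timingScheme(tLong = 0.02, tShort = 6.78)),
               1)

  expect_gte(frameRate(), 3)
  expect_equal(frameRate(), 1 / (49 * 6.8e-3))
  expect_equal(frameRate(timingScheme(slotsPerFrame = 1L)), 147.0588,
               tolerance = 1e-6)
  expect_equal(frameRate(timingScheme(tShort = 1, tLong = 9,
                                      slotsPerFrame = 10L)), 10)
})

test_that("overlap-time calibration is the exhaustive grid maximum", {
  spec <- detectorSpec()
  # dim channels: nothing saturates, clamp at the grid maximum
  tau <- calibrateOverlap(c(1e-9, 2e-9))
  expect_equal(as.numeric(tau), 0.5)
  expect_false(attr(tau, "saturated"))

  # power that saturates only above 0.1 ms
  p <- detectorSpec()@fullWell * 1e-12 / (spec@responsivity * 0.11e-3)
  tau <- calibrateOverlap(c(1e-9, p))
  expect_equal(as.numeric(tau), 0.1)

  # even the minimum saturates -> minimum plus warning flag
  tau <- calibrateOverlap(1e-3)
  expect_equal(as.numeric(tau), 0.02)
  expect_true(attr(tau, "saturated"))

  # brute-force oracle over random power vectors
  set.seed(11)
  grid <- tauOvpGrid()
  for (k in 1:20) {
    pw <- 10^runif(5, -9, -5.5)
    got <- as.numeric(calibrateOverlap(pw))
    qAt <- function(tau) max(pw) * spec@responsivity * tau * 1e-3 / 1e-12
    ok <- grid[sapply(grid, function(tg) qAt(tg) < spec@fullWell)]
    want <- if (length(ok)) max(ok) else min(grid)
    expect_equal(got, want)
    # returned tau never saturates the short integration (when unflagged)
    if (length(ok)) expect_lt(qAt(got), spec@fullWell)
  }
})

test_that("integration selection flags saturating channels", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 20L
  P <- matrix(1e-9, nrow(ch), nt)
  cs <- makeIntensitySeries(P)
  fr <- toFrames(cs, seed = 1)
  sel <- selectIntegration(fr)
  expect_true(all(sel$integration == "long"))
  expect_false(any(sel$failed))

  # one channel saturating the long integration in frame 7 only
  P2 <- P
  P2[3, 7] <- 17e-9
  fr2 <- toFrames(makeIntensitySeries(P2), seed = 1)
  sel2 <- selectIntegration(fr2)
  expect_equal(sel2$integration[3], "short")
  expect_true(all(sel2$integration[-3] == "long"))
  expect_false(any(sel2$failed))

  # power saturating both integrations -> failed flag
  P3 <- P
  P3[5, ] <- 1e-3
  sel3 <- selectIntegration(toFrames(makeIntensitySeries(P3), seed = 1))
  expect_true(sel3$failed[5])
  expect_equal(sum(sel3$failed), 1L)
})

test_that("timing scheme and detector spec enforce their invariants", {
  expect_error(timingScheme(tShort = 0.5, tLong = 6.0, slot = 6.8), "slot")
  expect_error(timingScheme(tauOvp = 0.03), "grid")
  expect_error(timingScheme(tauOvp = 0.6), "grid|tShort")
  expect_error(detectorSpec(responsivity = 1.5), "responsivity")
  expect_error(detectorSpec(fullWell = -1), "fullWell")
})
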