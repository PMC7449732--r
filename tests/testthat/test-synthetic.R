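quietTruth <- function(conditions = "task", centers, blobSigma = 0,
                       hbo = rep(10e-6, length(conditions))) {
  groundTruth(conditions = conditions, centers = centers, hbo = hbo,
              blobSigma = blobSigma,
              superficial = data.frame(name = "none", freq = 1, amp = 0))
}

test_that("protocol durations match the paradigm designs", {
  # texting: 16 blocks, 8 per hand, ~11 min
  p <- makeProtocol(seed = 3)
  expect_equal(nrow(p@onsets), 16L)
  expect_equal(sum(p@onsets$condition == "left"), 8L)
  d <- protocolDuration(p)
  expect_gte(d, 10 * 60)
  expect_lte(d, 12 * 60)

  # walking: 12 blocks, one condition, ~8.5 min
  w <- makeProtocol(nBlocks = 12, conditions = "walk", seed = 3)
  expect_gte(protocolDuration(w), 7.5 * 60)
  expect_lte(protocolDuration(w), 9.5 * 60)

  # zero blocks: lead + tail rest only
  z <- makeProtocol(nBlocks = 0, conditions = "x", seed = 1)
  expect_equal(protocolDuration(z), 60)

  # ISIs inside the commanded range, blocks non-overlapping
  on <- p@onsets[order(p@onsets$onset), ]
  isis <- on$onset[-1] - (on$onset[-16] + on$duration[-16])
  expect_true(all(isis >= 17.5 - 1e-9 & isis <= 22.5 + 1e-9))

  # reproducibility and error handling
  expect_identical(makeProtocol(seed = 9)@onsets, makeProtocol(seed = 9)@onsets)
  expect_error(makeProtocol(isiRange = c(-1, 2)), "ISI")
})

test_that("noise-free simulation is a pure forward model", {
  ctr <- c(30, 15, 12.5)
  truth <- quietTruth(centers = matrix(ctr, 1),
                      hbo = 0)  # zero amplitude
  truth@amplitudes$hbr <- 0
  prot <- makeProtocol(nBlocks = 2, conditions = "task", seed = 4)
  cs <- simulateChannels(lay2, prot, truth,
                         list(`740` = j740.8, `855` = j855.8),
                         seed = 4, noise = FALSE)
  P <- SummarizedExperiment::assay(cs, "intensity")
  expect_true(all(apply(P, 1, sd) == 0))       # constant baselines
  expect_true(all(P > 0))

  # single active voxel: channel OD proportional to that Jacobian column
  vc <- voxelCenters(grid8)
  v <- which.min(rowSums(sweep(vc, 2, ctr)^2))
  truth2 <- quietTruth(centers = matrix(vc[v, ], 1), blobSigma = 0)
  cs2 <- simulateChannels(lay2, prot, truth2,
                          list(`740` = j740.8, `855` = j855.8),
                          seed = 4, noise = FALSE)
  odB <- S4Vectors::metadata(cs2)$odBrain
  tpk <- which.max(colSums(abs(odB)))
  col <- j740.8@matrix[, v]        # rows 1..32 of odB are the 740 nm block
  sel <- which(col > max(col) * 1e-6)
  ratio <- odB[sel, tpk] / col[sel]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("short channels carry relatively more superficial signal", {
  truth <- groundTruth(conditions = "task",
                       centers = matrix(c(30, 15, 12.5), 1), blobSigma = 8)
  prot <- makeProtocol(nBlocks = 2, conditions = "task", seed = 4)
  cs <- simulateChannels(lay2, prot, truth,
                         list(`740` = j740.8, `855` = j855.8),
                         seed = 4, noise = FALSE)
  md <- S4Vectors::metadata(cs)
  ch <- channelInfo(cs)
  supPow <- rowMeans(md$odSuperficial^2)
  brainPow <- rowMeans(md$odBrain^2)
  is740 <- ch$wavelength == 740
  shortIdx <- which(is740 & ch$separation <= 10.5)
  longIdx <- which(is740 & abs(ch$separation - 28) < 0.5)
  relShort <- median(supPow[shortIdx] / pmax(brainPow[shortIdx], 1e-300))
  relLong <- median(supPow[longIdx] / pmax(brainPow[longIdx], 1e-300))
  expect_gte(relShort, relLong)
})

test_that("frame conversion reproduces saturation boundaries", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 10L
  P <- matrix(1e-9, nrow(ch), nt)
  P[1, ] <- 16.3e-9                      # full-scale power
  cs <- makeIntensitySeries(P)
  fr <- toFrames(cs, scheme = timingScheme(tauOvp = 0.02), seed = 2)
  expect_true(all(fr@satLong[1, ]))
  expect_true(all(fr@longCounts[1, ] == detectorSpec()@fullWell))
  # short integration at 0.02 ms: 50 pC / 315, unflagged
  expect_false(any(fr@satShort[1, ]))
  expect_equal(mean(fr@shortCounts[1, ]), 50 / 315, tolerance = 0.02)

  # zero power: dark-noise-only counts
  fr0 <- toFrames(makeIntensitySeries(matrix(0, nrow(ch), nt)), seed = 2)
  expect_true(all(fr0@longCounts >= 0 & fr0@longCounts < 0.005))

  # flags appear iff noiseless charge crosses the full well (15-sigma margin)
  set.seed(31)
  Pr <- matrix(10^runif(nrow(ch) * nt, -9.5, -7.5), nrow(ch), nt)
  frR <- toFrames(makeIntensitySeries(Pr), seed = 3)
  qL <- powerToCharge(Pr, timingScheme()@tLong)
  expect_true(all(frR@satLong[qL >= detectorSpec()@fullWell + 0.01]))
  expect_true(!any(frR@satLong[qL <= detectorSpec()@fullWell - 0.01]))

  # frames -> intensity honours the integration look-up table
  csBack <- framesToIntensity(fr)
  Pb <- SummarizedExperiment::assay(csBack, "intensity")
  expect_equal(mean(Pb[1, ]), 16.3e-9, tolerance = 0.05)  # via short
  expect_equal(mean(Pb[3, ]), 1e-9, tolerance = 0.05)     # via long
})

test_that("motion injection produces the commanded artifact signatures", {
  ch <- enumerateChannels(lay1, c(740, 855))
  nt <- 300L
  set.seed(5)
  P <- matrix(1e-9 * exp(rnorm(nrow(ch) * nt, sd = 0.01)), nrow(ch), nt)
  cs <- makeIntensitySeries(P)

  # no events: identity
  cs0 <- injectMotion(cs, data.frame(time = numeric(), kind = character(),
                                     magnitude = numeric(), module = integer()))
  expect_identical(SummarizedExperiment::assay(cs0, "intensity"), P)

  # spike raises the kurtosis of log-intensity
  ev <- data.frame(time = 50, kind = "spike", magnitude = 0.5, module = 1L)
  csS <- injectMotion(cs, ev, seed = 6)
  l0 <- log(P[1, ]); l1 <- log(SummarizedExperiment::assay(csS, "intensity")[1, ])
  k <- function(x) { x <- x - mean(x); mean(x^4) / mean(x^2)^2 }
  expect_gt(k(l1), k(l0))

  # shift changes the pre/post mean by the commanded step
  ev2 <- data.frame(time = 50, kind = "shift", magnitude = 0.3, module = 1L)
  csH <- injectMotion(cs, ev2, seed = 6)
  lh <- log(SummarizedExperiment::assay(csH, "intensity")[1, ])
  tms <- sampleTimes(cs)
  dShift <- mean(lh[tms >= 50] - l0[tms >= 50]) -
    mean(lh[tms < 50] - l0[tms < 50])
  expect_equal(abs(dShift), 0.3, tolerance = 1e-6)

  # events outside the record are rejected
  expect_error(injectMotion(cs, data.frame(time = 1e5, kind = "spike",
                                           magnitude = 1, module = 1L)),
               "within the record")
})

test_that("accelerometer traces show walking variance and optional coincidence", {
  mp0 <- simulateMpu(duration = 60, nModules = 2, seed = 8)
  expect_s4_class(mp0, "MpuTrace")
  expect_equal(mp0@rate, 150)
  expect_lt(sd(mp0@data[1, ]), 0.02)
  expect_true(all(mp0@data >= 0))

  wb <- data.frame(start = 20, end = 40)
  mpW <- simulateMpu(duration = 60, nModules = 2, walkingBlocks = wb, seed = 8)
  tms <- seq(0, 60, by = 1 / 150)
  inW <- tms >= 20 & tms <= 40
  expect_gt(var(mpW@data[1, inW]), 5 * var(mpW@data[1, !inW]))

  # zero coincidence probability: artifacts leave no accelerometer feature
  ev <- data.frame(time = c(10, 50))
  mpN <- simulateMpu(duration = 60, nModules = 2, artifactEvents = ev,
                     coincidenceProb = 0, seed = 8)
  expect_identical(mpN@data, mp0@data)
  expect_error(simulateMpu(duration = 10,
                           walkingBlocks = data.frame(start = 5, end = 20)),
               "within the record")
})

test_that("identical seeds give bit-identical synthetic runs", {
  truth <- groundTruth(conditions = "task",
                       centers = matrix(c(30, 15, 12.5), 1))
  prot <- makeProtocol(nBlocks = 2, conditions = "task", seed = 4)
  a <- simulateChannels(lay2, prot, truth,
                        list(`740` = j740.8, `855` = j855.8), seed = 10)
  b <- simulateChannels(lay2, prot, truth,
                        list(`740` = j740.8, `855` = j855.8), seed = 10)
  expect_identical(SummarizedExperiment::assay(a, "intensity"),
                   SummarizedExperiment::assay(b, "intensity"))
  c2 <- simulateChannels(lay2, prot, truth,
                         list(`740` = j740.8, `855` = j855.8), seed = 11)
  expect_false(identical(SummarizedExperiment::assay(a, "intensity"),
                         SummarizedExperiment::assay(c2, "intensity")))

  fa <- toFrames(a, seed = 2); fb <- toFrames(b, seed = 2)
  expect_identical(fa@longCounts, fb@longCounts)
  expect_identical(fa@darkCounts, fb@darkCounts)
})

test_that("noise-free closed loop recovers the activation blob", {
  ctr <- c(30, 15, 12.5)
  truth <- quietTruth(centers = matrix(ctr, 1), blobSigma = 8)
  prot <- makeProtocol(nBlocks = 3, conditions = "task", seed = 5)
  cs <- simulateChannels(lay2, prot, truth,
                         list(`740` = j740.8, `855` = j855.8),
                         seed = 5, noise = FALSE)
  od <- intensityToOd(cs)
  odB <- S4Vectors::metadata(cs)$odBrain

  # OD conversion round-trips the generating OD (mean-reference offset)
  odm <- SummarizedExperiment::assay(od, "od")
  offset <- log(rowMeans(exp(-odB)))
  expect_lt(max(abs(odm - (odB + offset))), 1e-10)

  # reconstruct the plateau frame
  act <- hddot:::activationCourses(prot, truth, sampleTimes(cs))[1, ]
  tpk <- which.max(act)
  img <- reconstructImage(odB[, tpk], msj8,
                          reconConfig(lambda = 1e-4, maxIter = 2000,
                                      tol = 1e-12))
  vc <- voxelCenters(grid8)
  truthPk <- which.max(hddot:::blobField(grid8, ctr, 8))
  pk <- which.max(img@hbo)
  expect_lte(sqrt(sum((vc[pk, ] - vc[truthPk, ])^2)) / grid8@spacing, 1)
  expect_equal(img@hbo[pk], 10e-6 * act[tpk], tolerance = 0.1)
  expect_lt(img@hbr[pk], 0)
})
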