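#' Generate a block-design stimulus protocol
#'
#' Blocks of fixed duration alternate with inter-stimulus intervals jittered
#' uniformly within \code{isiRange}; conditions follow a balanced
#' pseudorandom sequence. Defaults mirror a unimanual texting paradigm:
#' 16 blocks (8 per hand) of 17.5 s, ISI 17.5-22.5 s, 30 s lead and tail
#' rest, for a total of roughly 11 minutes.
#'
#' @param nBlocks total number of blocks.
#' @param conditions condition labels; blocks are divided equally among them.
#' @param blockDuration s. @param isiRange length-2, s. @param leadRest s.
#' @param seed integer seed; the protocol is reproducible given the seed.
#' @return a \linkS4class{StimulusProtocol}.
#' @export
makeProtocol <- function(nBlocks = 16L, conditions = c("left", "right"),
                         blockDuration = 17.5, isiRange = c(17.5, 22.5),
                         leadRest = 30, seed = 1L) {
  if (any(isiRange < 0) || diff(isiRange) < 0)
    stop("infeasible ISI range")
  if (nBlocks %% length(conditions) != 0L)
    stop("nBlocks must be a multiple of the number of conditions")
  withSeed(seed, {
    labels <- if (nBlocks > 0L)
      sample(rep(conditions, each = nBlocks / length(conditions))) else character()
    isis <- runif(max(nBlocks - 1L, 0L), isiRange[1], isiRange[2])
    onsets <- numeric(nBlocks)
    t <- leadRest
    for (k in seq_len(nBlocks)) {
      onsets[k] <- t
      t <- t + blockDuration + if (k < nBlocks) isis[k] else 0
    }
  })
  new("StimulusProtocol",
      onsets = data.frame(condition = labels, onset = onsets,
                          duration = rep(blockDuration, nBlocks)),
      leadRest = leadRest, isiRange = isiRange)
}

#' Total protocol duration (s), lead and tail rest included
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @export
protocolDuration <- function(protocol) {
  on <- protocol@onsets
  if (nrow(on) == 0L) return(2 * protocol@leadRest)
  max(on$onset + on$duration) + protocol@leadRest
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities with unit peak; default peak at 6 s and
#' undershoot at 16 s.
#'
#' @param t times in s (>= 0 contribute; t < 0 gives 0).
#' @param peak,undershoot gamma shape parameters = peak times (s) at unit rate.
#' @param ratio undershoot amplitude relative to the peak gamma.
#' @return kernel values, max-normalized to 1.
#' @export
hrfDoubleGamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- ifelse(t > 0,
              t^(peak - 1) * exp(-t) / gamma(peak) -
                ratio * t^(undershoot - 1) * exp(-t) / gamma(undershoot),
              0)
  tg <- seq(0, 40, by = 0.05)
  hg <- tg^(peak - 1) * exp(-tg) / gamma(peak) -
    ratio * tg^(undershoot - 1) * exp(-tg) / gamma(undershoot)
  h / max(hg)
}

#' Default generator ground truth
#'
#' One activation blob per condition, centred under opposite ends of the
#' probe at cortical depth, with a +HbO / -HbR amplitude pattern
#' (10 uM / -3 uM), double-gamma temporal kernel, superficial cardiac
#' (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) oscillations,
#' in-vivo-scale NEP of 318 fW and a 1 nW baseline at 23 mm separation.
#'
#' @param conditions condition labels.
#' @param centers nConditions x 3 matrix (mm); default places blobs at
#'   12 mm depth under the lateral thirds of a 12-module probe.
#' @param hbo,hbr molar amplitudes per condition.
#' @param blobSigma mm (default 6).
#' @param nep W. @param baselinePower W at 23 mm.
#' @param superficial data.frame(name, freq, amp).
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(conditions = c("left", "right"),
                        centers = NULL,
                        hbo = rep(10e-6, length(conditions)),
                        hbr = -0.3 * hbo,
                        blobSigma = 6,
                        nep = 318e-15,
                        baselinePower = 1e-9,
                        superficial = data.frame(
                          name = c("cardiac", "respiratory", "mayer"),
                          freq = c(1.1, 0.25, 0.1),
                          amp = c(0.01, 0.008, 0.012))) {
  n <- length(conditions)
  if (is.null(centers)) {
    centers <- cbind(x = seq(50, 140, length.out = max(n, 2))[seq_len(n)],
                     y = rep(32, n), z = rep(12, n))
  }
  new("GroundTruth",
      centers = centers,
      amplitudes = data.frame(condition = conditions, hbo = hbo, hbr = hbr),
      blobSigma = blobSigma,
      hrf = list(peak = 6, undershoot = 16, ratio = 1 / 6),
      superficial = superficial,
      nep = nep, baselinePower = baselinePower)
}

# condition x time activation courses: unit boxcar convolved with the HRF
# kernel, max-normalized so amplitudes are the plateau chromophore changes
activationCourses <- function(protocol, truth, times) {
  conds <- truth@amplitudes$condition
  dt <- median(diff(times))
  kern <- hrfDoubleGamma(seq(0, 40, by = dt), truth@hrf$peak,
                         truth@hrf$undershoot, truth@hrf$ratio)
  out <- matrix(0, length(conds), length(times),
                dimnames = list(conds, NULL))
  on <- protocol@onsets
  for (ci in seq_along(conds)) {
    box <- rep(0, length(times))
    oc <- on[on$condition == conds[ci], , drop = FALSE]
    for (k in seq_len(nrow(oc)))
      box[times >= oc$onset[k] & times < oc$onset[k] + oc$duration[k]] <- 1
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(times)] * dt
    # normalize so a sustained block reaches the commanded amplitude
    plateau <- sum(kern) * dt
    out[ci, ] <- conv / plateau
  }
  out
}

# voxel weights of one activation blob on a grid (sums to 1 in weight)
blobField <- function(grid, center, sigma) {
  vc <- voxelCenters(grid)
  if (sigma <= 0) {
    d2 <- rowSums(sweep(vc, 2, center)^2)
    w <- numeric(nrow(vc)); w[which.min(d2)] <- 1
    return(w)
  }
  w <- exp(-rowSums(sweep(vc, 2, center)^2) / (2 * sigma^2))
  w / max(w)
}

#' Simulate channel-wise intensities for a synthetic experiment
#'
#' Forward-synthesizes continuous-wave intensities: activation chromophore
#' fields (boxcar convolved with the HRF kernel, Gaussian spatial blob) are
#' pushed through the sensitivity matrices to channel optical-density
#' changes; superficial physiological oscillations are added with a partial
#' pathlength that decays with source-detector separation; baseline power
#' follows a distance-decay law anchored at \code{baselinePower} for a 23 mm
#' channel; shot noise and NEP-equivalent dark noise are added.
#'
#' @param layout an \linkS4class{ArrayLayout}.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param jacobians named list of \linkS4class{Jacobian}s, one per
#'   wavelength (names = nm as character).
#' @param props an \code{opticalProperties()} list (baseline decay).
#' @param rate sampling rate in Hz (default the 49-slot frame rate).
#' @param seed integer seed.
#' @param noise logical; FALSE disables shot and dark noise.
#' @return a \linkS4class{ChannelSeries} with assay "intensity" (W);
#'   metadata holds layout, protocol, truth and the noise-free brain
#'   optical-density matrix ("odBrain") for closed-loop checks.
#' @export
simulateChannels <- function(layout, protocol, truth, jacobians,
                             props = opticalProperties(),
                             rate = frameRate(timingScheme()),
                             seed = 1L, noise = TRUE) {
  wls <- as.numeric(names(jacobians))
  channels <- do.call(rbind, lapply(names(jacobians),
                                    function(w) jacobians[[w]]@channels))
  rownames(channels) <- NULL
  channels$channel <- seq_len(nrow(channels))
  nch <- nrow(channels)
  times <- seq(0, protocolDuration(protocol), by = 1 / rate)
  nt <- length(times)
  grid <- jacobians[[1]]@grid
  for (j in jacobians)
    if (!identical(j@grid@shape, grid@shape)) stop("mismatched Jacobian grids")

  act <- activationCourses(protocol, truth, times)       # cond x time
  ext <- extinctionTable()

  # brain OD: for each wavelength, J %*% mu_a(t); mu_a(v,t) separable per blob
  odBrain <- matrix(0, nch, nt)
  row0 <- 0L
  for (w in names(jacobians)) {
    J <- jacobians[[w]]@matrix
    eps <- ext[ext$wavelength == as.numeric(w), ]
    idx <- row0 + seq_len(nrow(J))
    for (ci in seq_len(nrow(truth@centers))) {
      fld <- blobField(grid, truth@centers[ci, ], truth@blobSigma)
      amp <- truth@amplitudes[ci, ]
      muaAmp <- eps$hbo * amp$hbo + eps$hbr * amp$hbr   # mm^-1 at plateau
      odBrain[idx, ] <- odBrain[idx, ] +
        (J %*% (fld * muaAmp)) %*% act[ci, , drop = FALSE]
    }
    row0 <- row0 + nrow(J)
  }

  # superficial physiology: amplitude in OD at 23 mm, pathlength decays with
  # separation so short channels carry relatively more scalp signal
  odSup <- matrix(0, nch, nt)
  withSeed(seed, {
    for (k in seq_len(nrow(truth@superficial))) {
      f <- truth@superficial$freq[k]
      a <- truth@superficial$amp[k]
      phase <- runif(nModules(layout), 0, 2 * pi)
      ph <- phase[channels$sourceModule]
      wave <- sin(outer(2 * pi * f * times, rep(1, nch)) + rep(ph, each = nt))
      scale <- a * exp(-(channels$separation - 23) / 60)
      odSup <- odSup + t(wave) * scale
    }

    # baseline power: inverse-square distance decay with effective attenuation
    mueff <- vapply(channels$wavelength, function(w) {
      p <- props[[as.character(w)]]
      sqrt(3 * p$mua * (p$mua + p$musp))
    }, numeric(1))
    base <- truth@baselinePower * (23 / channels$separation)^2 *
      exp(-mueff * (channels$separation - 23))

    intensity <- base * exp(-(odBrain + odSup))
    if (noise) {
      spec <- detectorSpec()
      scheme <- timingScheme()
      eCharge <- 1.602176634e-19
      q <- intensity * spec@responsivity * scheme@tLong * 1e-3  # coulombs
      nElec <- pmax(q / eCharge, 1)
      shot <- matrix(rnorm(nch * nt), nch, nt) / sqrt(nElec)
      dark <- matrix(rnorm(nch * nt, sd = truth@nep), nch, nt)
      intensity <- pmax(intensity * (1 + shot) + dark, 0)
    }
  })

  channelSeries(list(intensity = intensity), channels, times,
                metadata = list(layout = layout, protocol = protocol,
                                truth = truth, odBrain = odBrain,
                                odSuperficial = odSup))
}

#' Convert intensities to dual-integration frame charges
#'
#' Long charge = P R tLong, short charge = P R tauOvp, both clipped at the
#' full well and flagged when clipped; the dark slot draws Gaussian noise at
#' the RMS charge noise around \code{darkOffset}. Gaussian charge noise at
#' the RMS level is added to all counts.
#'
#' @param cs a \linkS4class{ChannelSeries} with assay "intensity" (W).
#' @param scheme a \linkS4class{TimingScheme} (its tauOvp is used).
#' @param spec a \linkS4class{DetectorSpec}.
#' @param seed integer seed.
#' @param darkOffset mean dark charge, pC.
#' @param nDetectors number of detector dark traces to synthesize.
#' @return a \linkS4class{FrameSeries}.
#' @export
toFrames <- function(cs, scheme = timingScheme(), spec = detectorSpec(),
                     seed = 1L, darkOffset = 0.01, nDetectors = 48L) {
  P <- SummarizedExperiment::assay(cs, "intensity")
  nch <- nrow(P); nt <- ncol(P)
  noisePc <- spec@rmsNoise * 1e-3   # fC -> pC
  withSeed(seed, {
    long <- powerToCharge(P, scheme@tLong, spec) +
      matrix(rnorm(nch * nt, sd = noisePc), nch, nt)
    short <- powerToCharge(P, scheme@tauOvp, spec) +
      matrix(rnorm(nch * nt, sd = noisePc), nch, nt)
    dark <- matrix(rnorm(nDetectors * nt, mean = darkOffset, sd = noisePc),
                   nDetectors, nt)
  })
  satL <- long >= spec@fullWell
  satS <- short >= spec@fullWell
  long <- pmin(pmax(long, 0), spec@fullWell)
  short <- pmin(pmax(short, 0), spec@fullWell)
  long[satL] <- spec@fullWell
  short[satS] <- spec@fullWell
  new("FrameSeries", longCounts = long, shortCounts = short,
      darkCounts = pmax(dark, 0), satLong = satL, satShort = satS,
      scheme = scheme, spec = spec, channels = channelInfo(cs),
      times = sampleTimes(cs))
}

#' Recover intensities from frame charges
#'
#' Applies the per-channel integration look-up table from
#' \code{\link{selectIntegration}}: channels whose long integration ever
#' saturates are read from the short integration (scaled by the overlap
#' time), all others from the long integration.
#'
#' @param frames a \linkS4class{FrameSeries}.
#' @param selection optional table from \code{\link{selectIntegration}}.
#' @return a \linkS4class{ChannelSeries} with assay "intensity" (W) and a
#'   rowData column \code{saturatedEver} for channels that failed both
#'   integrations.
#' @export
framesToIntensity <- function(frames, selection = selectIntegration(frames)) {
  scheme <- frames@scheme; spec <- frames@spec
  useShort <- selection$integration == "short"
  P <- chargeToPower(frames@longCounts, scheme@tLong, spec)
  if (any(useShort))
    P[useShort, ] <- chargeToPower(frames@shortCounts[useShort, , drop = FALSE],
                                   scheme@tauOvp, spec)
  ch <- frames@channels
  ch$saturatedEver <- selection$failed
  channelSeries(list(intensity = P), ch, frames@times,
                metadata = list(scheme = scheme, spec = spec))
}

#' Inject motion artifacts into channel intensities
#'
#' Spikes add a transient optical-density excursion (exponential decay,
#' sub-2 s); shifts add a step change; "noise" events add low-amplitude
#' broadband optical-density noise over a sustained interval
#' (walking-style micro-artifacts that raise signal variance without the
#' large fast excursions artifact detection keys on). Artifacts are applied
#' coherently to all channels whose source or detector belongs to the
#' event's module.
#'
#' @param cs a \linkS4class{ChannelSeries} with assay "intensity".
#' @param events data.frame(time (s), kind ("spike"/"shift"/"noise"),
#'   magnitude (OD units; noise: OD standard deviation), module (integer);
#'   optional duration (s) for "noise" events, default 17.5.
#' @param tauSpike spike decay constant, s (default 0.3).
#' @param seed integer seed (sign jitter across channels).
#' @return the modified \linkS4class{ChannelSeries}; metadata gains
#'   \code{motionEvents}.
#' @export
injectMotion <- function(cs, events, tauSpike = 0.3, seed = 1L) {
  if (nrow(events) == 0L) return(cs)
  times <- sampleTimes(cs)
  if (any(events$time < min(times)) || any(events$time > max(times)))
    stop("events must lie within the record")
  ch <- channelInfo(cs)
  P <- SummarizedExperiment::assay(cs, "intensity")
  withSeed(seed, {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      hit <- ch$sourceModule == ev$module | ch$detectorModule == ev$module
      sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
      if (ev$kind == "spike") {
        prof <- ifelse(times >= ev$time,
                       exp(-(times - ev$time) / tauSpike), 0)
        prof[times > ev$time + 2] <- 0
        dOd <- outer(sgn * ev$magnitude, prof)
      } else if (ev$kind == "shift") {
        prof <- as.numeric(times >= ev$time)
        dOd <- outer(sgn * ev$magnitude, prof)
      } else if (ev$kind == "noise") {
        dur <- if (!is.null(ev$duration) && !is.na(ev$duration))
          ev$duration else 17.5
        sel <- times >= ev$time & times <= ev$time + dur
        dOd <- matrix(0, sum(hit), length(times))
        dOd[, sel] <- rnorm(sum(hit) * sum(sel), sd = ev$magnitude)
      } else stop("unknown event kind: ", ev$kind)
      P[hit, ] <- P[hit, , drop = FALSE] * exp(-dOd)
    }
  })
  out <- cs
  SummarizedExperiment::assay(out, "intensity") <- P
  md <- S4Vectors::metadata(out)
  md$motionEvents <- events
  S4Vectors::metadata(out) <- md
  out
}

#' Simulate per-module accelerometer-norm traces
#'
#' Baseline 1 g plus low-level noise; walking intervals superimpose a
#' high-variance oscillation at the step frequency; DOT artifact events
#' produce coincident acceleration spikes with probability
#' \code{coincidenceProb}.
#'
#' @param duration s. @param nModules modules. @param rate Hz (default 150).
#' @param walkingBlocks data.frame(start, end) in s (may be empty).
#' @param artifactEvents data.frame with a \code{time} column (may be empty).
#' @param coincidenceProb probability an artifact shows in the MPU trace.
#' @param stepFreq Hz. @param walkAmp g. @param noiseSd g.
#' @param seed integer seed.
#' @return an \linkS4class{MpuTrace}.
#' @export
simulateMpu <- function(duration, nModules = 12L, rate = 150,
                        walkingBlocks = data.frame(start = numeric(),
                                                   end = numeric()),
                        artifactEvents = data.frame(time = numeric()),
                        coincidenceProb = 0.8, stepFreq = 2, walkAmp = 0.3,
                        noiseSd = 0.01, seed = 1L) {
  times <- seq(0, duration, by = 1 / rate)
  nt <- length(times)
  if (nrow(walkingBlocks) && (any(walkingBlocks$start < 0) ||
                              any(walkingBlocks$end > duration)))
    stop("walking intervals must lie within the record")
  withSeed(seed, {
    dat <- matrix(1 + rnorm(nModules * nt, sd = noiseSd), nModules, nt)
    for (k in seq_len(nrow(walkingBlocks))) {
      sel <- times >= walkingBlocks$start[k] & times <= walkingBlocks$end[k]
      for (m in seq_len(nModules)) {
        ph <- runif(1, 0, 2 * pi)
        dat[m, sel] <- dat[m, sel] +
          walkAmp * abs(sin(2 * pi * stepFreq * times[sel] + ph)) +
          rnorm(sum(sel), sd = walkAmp / 3)
      }
    }
    for (k in seq_len(nrow(artifactEvents))) {
      if (runif(1) > coincidenceProb) next
      prof <- ifelse(times >= artifactEvents$time[k],
                     exp(-(times - artifactEvents$time[k]) / 0.2), 0)
      dat <- dat + matrix(rep(0.5 * prof, each = nModules), nModules, nt)
    }
  })
  new("MpuTrace", data = pmax(dat, 0), rate = rate)
}
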