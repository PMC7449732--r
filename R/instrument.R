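#' Construct the dual-integration timing scheme
#'
#' Defaults describe one 6.8 ms illumination slot holding a 0.5 ms short
#' integration (A) and a 6.3 ms long integration (B), with 49 slots per
#' frame (48 LED illuminations plus one dark measurement), giving a frame
#' rate just above 3 Hz.
#'
#' @param tShort,tLong,slot durations in ms.
#' @param tauOvp LED overlap time in ms on the programmable grid
#'   \code{tauOvpGrid()}.
#' @param slotsPerFrame slots per frame.
#' @return a \linkS4class{TimingScheme}.
#' @export
timingScheme <- function(tShort = 0.5, tLong = 6.3, slot = tShort + tLong,
                         tauOvp = 0.1, slotsPerFrame = 49L) {
  new("TimingScheme", tShort = tShort, tLong = tLong, slot = slot,
      tauOvp = tauOvp, slotsPerFrame = as.integer(slotsPerFrame))
}

#' Construct the detector specification
#'
#' Defaults describe a charge-to-digital converter with a 50 pC full well
#' and 0.63 fC RMS noise. The default responsivity of 0.488 A/W is derived
#' from the requirement that 0.63 fC integrated over 6.3 ms correspond to
#' 205 fW of optical power (it then also maps the 50 pC full well to a
#' 16.3 nW full-scale power).
#'
#' @param fullWell pC. @param rmsNoise fC. @param responsivity A/W.
#' @return a \linkS4class{DetectorSpec}.
#' @export
detectorSpec <- function(fullWell = 50, rmsNoise = 0.63, responsivity = 0.488) {
  new("DetectorSpec", fullWell = fullWell, rmsNoise = rmsNoise,
      responsivity = responsivity)
}

#' Convert integrated charge to optical power
#'
#' P = q / (t * R): the optical power that deposits charge \code{q} on the
#' integrator over integration time \code{t} at photodiode responsivity R.
#'
#' @param q charge in pC.
#' @param t integration time in ms.
#' @param spec a \linkS4class{DetectorSpec}.
#' @return optical power in W.
#' @export
chargeToPower <- function(q, t, spec = detectorSpec()) {
  if (any(t <= 0)) stop("integration time must be positive")
  (q * 1e-12) / (t * 1e-3 * spec@responsivity)
}

#' Convert optical power to integrated charge
#'
#' Inverse of \code{\link{chargeToPower}}: q = P * R * t.
#'
#' @param p optical power in W.
#' @param t integration time in ms.
#' @param spec a \linkS4class{DetectorSpec}.
#' @return charge in pC.
#' @export
powerToCharge <- function(p, t, spec = detectorSpec()) {
  if (any(t <= 0)) stop("integration time must be positive")
  p * spec@responsivity * (t * 1e-3) / 1e-12
}

#' Noise-equivalent power from dark measurements
#'
#' The NEP is the optical power whose integrated charge equals the standard
#' deviation of the dark (LED-off) measurements over time, referred to the
#' long integration period.
#'
#' @param darkSeries numeric vector (or matrix, detectors x frames) of dark
#'   charges in pC.
#' @param scheme a \linkS4class{TimingScheme}.
#' @param spec a \linkS4class{DetectorSpec}.
#' @return NEP in W (one value per row if a matrix is given).
#' @export
nepFromDark <- function(darkSeries, scheme = timingScheme(), spec = detectorSpec()) {
  if (is.matrix(darkSeries)) {
    if (ncol(darkSeries) < 2L) stop("need at least 2 dark samples")
    s <- apply(darkSeries, 1, sd)
  } else {
    if (length(darkSeries) < 2L) stop("need at least 2 dark samples")
    s <- sd(darkSeries)
  }
  chargeToPower(s, scheme@tLong, spec)
}

#' Dynamic range in decibels
#'
#' 20 log10(pMax / pMin); used both in the optical-power domain (full-scale
#' power over NEP) and the charge domain (full well over RMS noise).
#'
#' @param pMax,pMin positive values in the same units.
#' @return dB.
#' @export
dynamicRangeDb <- function(pMax, pMin) {
  if (any(pMax <= 0) || any(pMin <= 0)) stop("inputs must be positive")
  20 * log10(pMax / pMin)
}

#' Effective gain of the dual-integration strategy
#'
#' Ratio of the long integration period to the minimum overlap time: the
#' factor by which dual integration raises the maximum detectable intensity.
#' With the full programmable grid (minimum 0.02 ms) the ratio is 315.
#'
#' @param scheme a \linkS4class{TimingScheme}.
#' @param tauMin minimum overlap time in ms (default the grid minimum).
#' @return dimensionless ratio.
#' @export
effectiveGainRatio <- function(scheme = timingScheme(), tauMin = min(tauOvpGrid())) {
  scheme@tLong / tauMin
}

#' Acquisition frame rate
#'
#' @param scheme a \linkS4class{TimingScheme}.
#' @return Hz.
#' @export
frameRate <- function(scheme = timingScheme()) {
  1 / (scheme@slotsPerFrame * scheme@slot * 1e-3)
}

#' Calibrate the LED overlap time against saturation
#'
#' Returns the largest grid value of tau_ovp for which no channel's short
#' integration saturates given the per-channel peak optical powers; if even
#' the grid minimum saturates, the minimum is returned with attribute
#' \code{saturated = TRUE}.
#'
#' @param peakPowers positive per-channel peak powers in W.
#' @param scheme a \linkS4class{TimingScheme}.
#' @param spec a \linkS4class{DetectorSpec}.
#' @return tau_ovp in ms, with logical attribute \code{saturated}.
#' @export
calibrateOverlap <- function(peakPowers, scheme = timingScheme(),
                             spec = detectorSpec()) {
  stopifnot(length(peakPowers) >= 1L, all(peakPowers > 0))
  grid <- tauOvpGrid()
  pmax <- max(peakPowers)
  ok <- powerToCharge(pmax, grid, spec) < spec@fullWell
  if (any(ok)) {
    tau <- max(grid[ok])
    attr(tau, "saturated") <- FALSE
  } else {
    tau <- min(grid)
    attr(tau, "saturated") <- TRUE
  }
  tau
}

#' Choose the integration period per channel
#'
#' A channel is marked "short" iff any of its long-integration samples
#' reaches the full-well charge; channels whose short integration also
#' saturates are flagged as failed. The result is the look-up table applied
#' in post-processing when converting frames back to intensities.
#'
#' @param frames a \linkS4class{FrameSeries}.
#' @return data.frame with columns channel, integration ("long"/"short"),
#'   failed (logical).
#' @export
selectIntegration <- function(frames) {
  satL <- rowSums(frames@satLong) > 0L
  satS <- rowSums(frames@satShort) > 0L
  data.frame(
    channel = seq_len(nrow(frames@longCounts)),
    integration = ifelse(satL, "short", "long"),
    failed = satL & satS
  )
}
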