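#' Channel quality control
#'
#' A channel is good iff its mean intensity is at least \code{minMeanFrac}
#' of the detector full scale, its mean-over-standard-deviation ratio is at
#' least \code{minSnr} (a zero standard deviation passes: the threshold
#' targets noisy dim channels, not synthetic constants), and it never
#' saturated. Both wavelengths of a source-detector pair must pass for the
#' dual-wavelength channel to be good.
#'
#' @param cs a \linkS4class{ChannelSeries} with assay "intensity" (W); a
#'   rowData column \code{saturatedEver} is honoured when present.
#' @param minMeanFrac minimum mean intensity as a fraction of full scale
#'   (default 500 ppm).
#' @param minSnr minimum mean/sd (default 12).
#' @param excludeSaturated drop ever-saturated channels (default TRUE).
#' @param fullScalePower full-scale optical power in W (default the
#'   full-well charge over the long integration).
#' @return logical vector, one element per channel row.
#' @export
pruneChannels <- function(cs, minMeanFrac = 500e-6, minSnr = 12,
                          excludeSaturated = TRUE,
                          fullScalePower = chargeToPower(
                            detectorSpec()@fullWell, timingScheme()@tLong)) {
  stopifnot(minMeanFrac > 0, minSnr > 0)
  P <- SummarizedExperiment::assay(cs, "intensity")
  if (ncol(P) == 0L) stop("zero-length series")
  mu <- rowMeans(P)
  s <- apply(P, 1, sd)
  ok <- (mu / fullScalePower >= minMeanFrac) &
    (s == 0 | mu / s >= minSnr)
  ch <- channelInfo(cs)
  if (excludeSaturated && !is.null(ch$saturatedEver))
    ok <- ok & !ch$saturatedEver
  # dual-wavelength pairing: both wavelengths must pass
  key <- paste(ch$source, ch$detector)
  pairOk <- tapply(ok, key, all)
  as.logical(pairOk[key])
}

#' Convert intensity to optical-density change
#'
#' dOD(t) = -log(I(t) / mean(I)) per channel (natural log). Channels with
#' any non-positive sample are flagged invalid (rowData column
#' \code{odValid}) and their series set to NA.
#'
#' @param cs a \linkS4class{ChannelSeries} with assay "intensity".
#' @return a \linkS4class{ChannelSeries} with assay "od".
#' @export
intensityToOd <- function(cs) {
  P <- SummarizedExperiment::assay(cs, "intensity")
  bad <- apply(P <= 0, 1, any)
  od <- -log(P / rowMeans(P))
  od[bad, ] <- NA_real_
  ch <- channelInfo(cs)
  ch$odValid <- !bad
  channelSeries(list(od = od), ch, sampleTimes(cs),
                metadata = S4Vectors::metadata(cs))
}

# windowed artifact scan of one series: TRUE where any covering window
# trips the amplitude or local-std criterion
scanSeries <- function(x, w, stdMult, ampThresh) {
  nt <- length(x)
  step <- max(1L, w %/% 2L)
  starts <- unique(c(seq(1L, max(nt - w + 1L, 1L), by = step),
                     max(nt - w + 1L, 1L)))
  rng <- numeric(length(starts)); sds <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:min(starts[i] + w - 1L, nt)]
    rng[i] <- max(seg) - min(seg)
    sds[i] <- sd(seg)
  }
  ref <- median(sds)
  bad <- rng > ampThresh | (ref > 0 & sds > stdMult * ref)
  env <- logical(nt)
  for (i in which(bad))
    env[starts[i]:min(starts[i] + w - 1L, nt)] <- TRUE
  env
}

#' Detect motion artifacts in channel data
#'
#' Sliding-window scan: a time point is artifactual when any window covering
#' it has a signal excursion above \code{ampThresh} or a local standard
#' deviation above \code{stdMult} times the channel's median windowed
#' standard deviation. The envelope is padded by \code{maskPad}. Defaults
#' follow channel-space fNIRS processing conventions; none are instrument
#' constants. The same scan applies to accelerometer-norm traces (pass an
#' \linkS4class{MpuTrace}).
#'
#' @param x a \linkS4class{ChannelSeries} with assay "od" (NA rows are
#'   skipped), an \linkS4class{MpuTrace}, or a numeric matrix (rows =
#'   series).
#' @param rate sampling rate in Hz (taken from the object when possible).
#' @param window window length, s (default 1).
#' @param stdMult local-std multiplier (default 50).
#' @param ampThresh excursion threshold in the units of \code{x}
#'   (default 0.5).
#' @param maskPad envelope padding, s (default 1).
#' @return list(perSeries = logical matrix, collapsed = logical vector,
#'   burden = fraction of time points in the collapsed envelope).
#' @export
detectMotion <- function(x, rate = NULL, window = 1, stdMult = 50,
                         ampThresh = 0.5, maskPad = 1) {
  if (is(x, "ChannelSeries")) {
    m <- SummarizedExperiment::assay(x, 1)
    if (is.null(rate)) rate <- sampleRate(x)
  } else if (is(x, "MpuTrace")) {
    m <- x@data
    if (is.null(rate)) rate <- x@rate
  } else {
    m <- as.matrix(x)
    if (is.null(rate)) stop("rate required for plain matrices")
  }
  w <- max(2L, round(window * rate))
  if (w >= ncol(m)) stop("window must be shorter than the record")
  pad <- round(maskPad * rate)
  per <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    if (anyNA(m[r, ])) next
    env <- scanSeries(m[r, ], w, stdMult, ampThresh)
    if (pad > 0L && any(env)) {
      idx <- which(env)
      lo <- pmax(idx - pad, 1L); hi <- pmin(idx + pad, ncol(m))
      for (k in seq_along(idx)) env[lo[k]:hi[k]] <- TRUE
    }
    per[r, ] <- env
  }
  collapsed <- colSums(per) > 0L
  list(perSeries = per, collapsed = collapsed, burden = mean(collapsed))
}

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase); the default 0.01-0.5 Hz band removes drift
#' and DC below and cardiac-band power above the haemodynamic band.
#'
#' @param cs a \linkS4class{ChannelSeries} (first assay filtered) or matrix.
#' @param band length-2 Hz (default c(0.01, 0.5)).
#' @param rate Hz (taken from the object when possible).
#' @return same type as the input, filtered.
#' @export
bandpassFilter <- function(cs, band = c(0.01, 0.5), rate = NULL) {
  isCs <- is(cs, "ChannelSeries")
  if (isCs) {
    m <- SummarizedExperiment::assay(cs, 1)
    if (is.null(rate)) rate <- sampleRate(cs)
  } else m <- as.matrix(cs)
  if (is.null(rate)) stop("rate required")
  nyq <- rate / 2
  if (band[2] >= nyq || band[1] <= 0 || band[1] >= band[2])
    stop("band edges must satisfy 0 < low < high < Nyquist")
  hp <- signal::butter(3, band[1] / nyq, type = "high")
  lp <- signal::butter(3, band[2] / nyq, type = "low")
  out <- m
  for (r in seq_len(nrow(m))) {
    if (anyNA(m[r, ])) next
    y <- m[r, ] - mean(m[r, ])           # remove DC before the recursion
    y <- signal::filtfilt(hp, y)
    out[r, ] <- signal::filtfilt(lp, y)
  }
  if (isCs) {
    SummarizedExperiment::assay(cs, 1) <- out
    cs
  } else out
}

#' Modified Beer-Lambert law: optical density to chromophore changes
#'
#' Pairs the two wavelengths of each source-detector combination and solves,
#' per time point, the 2 x 2 system
#' dOD_wl = (e_HbO,wl dHbO + e_HbR,wl dHbR) d DPF_wl,
#' where d is the source-detector separation and DPF the differential
#' pathlength factor (defaults 7.5 at 740 nm and 7 at 855 nm).
#'
#' @param cs a \linkS4class{ChannelSeries} with assay "od".
#' @param dpf named numeric: DPF per wavelength.
#' @param extinction \code{\link{extinctionTable}}-style table
#'   (mm^-1 M^-1, natural log).
#' @return a \linkS4class{ChannelSeries} with one row per source-detector
#'   pair and assays "HbO" and "HbR" (molar); pairs with an invalid
#'   wavelength are NA.
#' @export
mbll <- function(cs, dpf = c(`740` = 7.5, `855` = 7),
                 extinction = extinctionTable()) {
  od <- SummarizedExperiment::assay(cs, "od")
  ch <- channelInfo(cs)
  wls <- sort(unique(ch$wavelength))
  if (length(wls) != 2L) stop("exactly two wavelengths required")
  E <- rbind(
    c(extinction$hbo[match(wls[1], extinction$wavelength)],
      extinction$hbr[match(wls[1], extinction$wavelength)]),
    c(extinction$hbo[match(wls[2], extinction$wavelength)],
      extinction$hbr[match(wls[2], extinction$wavelength)]))
  if (abs(det(E)) < max(abs(E))^2 / 1e3)
    stop("extinction matrix is ill-conditioned")
  Einv <- solve(E)
  key <- paste(ch$source, ch$detector)
  i1 <- which(ch$wavelength == wls[1])
  i2 <- match(paste(ch$source[i1], ch$detector[i1]),
              key[ch$wavelength == wls[2]])
  i2 <- which(ch$wavelength == wls[2])[i2]
  hbo <- matrix(NA_real_, length(i1), ncol(od))
  hbr <- matrix(NA_real_, length(i1), ncol(od))
  for (k in seq_along(i1)) {
    d <- ch$separation[i1[k]]
    y1 <- od[i1[k], ] / (d * dpf[[as.character(wls[1])]])
    y2 <- od[i2[k], ] / (d * dpf[[as.character(wls[2])]])
    if (anyNA(y1) || anyNA(y2)) next
    conc <- Einv %*% rbind(y1, y2)
    hbo[k, ] <- conc[1, ]
    hbr[k, ] <- conc[2, ]
  }
  pairCh <- ch[i1, setdiff(names(ch), "wavelength")]
  pairCh$channel <- seq_len(nrow(pairCh))
  channelSeries(list(HbO = hbo, HbR = hbr), pairCh, sampleTimes(cs),
                metadata = S4Vectors::metadata(cs))
}
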