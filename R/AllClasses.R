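#' @import methods
#' @importFrom stats sd rnorm runif rpois median quantile lm.fit var
#' @importFrom utils head tail write.csv read.csv
NULL

#' ModuleLayout: optode geometry of one sensor module
#'
#' Positions (mm, board frame) of the two dual-wavelength LED source sites,
#' the two corner photodiode detectors and the two short-separation
#' detectors on a single square module board. The contractual geometry is
#' the within-board separation multiset {10, 10, 23, 23, 23, 23, 28, 28} mm;
#' exact coordinates are configuration.
#'
#' @slot boardSide board edge length in mm.
#' @slot sourcePositions 2 x 2 matrix, one source site per row (mm).
#' @slot cornerDetectorPositions 2 x 2 matrix (mm).
#' @slot shortDetectorPositions 2 x 2 matrix (mm); row i is paired with
#'   source i and sits 10 mm from it.
#' @exportClass ModuleLayout
setClass("ModuleLayout",
  representation(
    boardSide = "numeric",
    sourcePositions = "matrix",
    cornerDetectorPositions = "matrix",
    shortDetectorPositions = "matrix"
  )
)

setValidity("ModuleLayout", function(object) {
  msg <- character()
  pts <- rbind(object@sourcePositions, object@cornerDetectorPositions,
               object@shortDetectorPositions)
  if (!all(dim(object@sourcePositions) == c(2L, 2L)) ||
      !all(dim(object@cornerDetectorPositions) == c(2L, 2L)) ||
      !all(dim(object@shortDetectorPositions) == c(2L, 2L)))
    msg <- c(msg, "all position slots must be 2 x 2 matrices")
  if (length(msg) == 0L) {
    side <- object@boardSide
    if (any(pts < -1e-9) || any(pts > side + 1e-9))
      msg <- c(msg, "all optode positions must lie within [0, boardSide]^2")
    dss <- sqrt(rowSums((object@shortDetectorPositions -
                           object@sourcePositions)^2))
    if (any(abs(dss - 10) > 0.5))
      msg <- c(msg, "each short detector must be 10 +/- 0.5 mm from its source")
    seps <- sort(round(c(outer(seq_len(2), seq_len(4), function(i, j) {
      dets <- rbind(object@cornerDetectorPositions,
                    object@shortDetectorPositions)
      sqrt(rowSums((matrix(object@sourcePositions[i, ], length(i), 2,
                           byrow = FALSE) - dets[j, , drop = FALSE])^2))
    }))))
    # recompute cleanly: all 2x4 source-detector separations
    dets <- rbind(object@cornerDetectorPositions, object@shortDetectorPositions)
    seps <- sort(round(as.vector(apply(object@sourcePositions, 1, function(s)
      sqrt(rowSums(sweep(dets, 2, s)^2))))))
    if (!identical(seps, c(10, 10, 23, 23, 23, 23, 28, 28)))
      msg <- c(msg, sprintf(
        "within-board separation multiset must be {10x2, 23x4, 28x2} mm, got {%s}",
        paste(seps, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ArrayLayout: a probe built from placed modules
#'
#' A planar probe of identical modules laid out on a rows x cols raster with
#' a configurable inter-module gap. Placements are rigid in-plane transforms
#' of the module frame.
#'
#' @slot module the shared \linkS4class{ModuleLayout}.
#' @slot translations n_modules x 2 matrix of module origin offsets (mm).
#' @slot rotations numeric vector of in-plane rotations (radians).
#' @slot nRows,nCols raster dimensions.
#' @slot gap inter-module gap in mm.
#' @exportClass ArrayLayout
setClass("ArrayLayout",
  representation(
    module = "ModuleLayout",
    translations = "matrix",
    rotations = "numeric",
    nRows = "integer",
    nCols = "integer",
    gap = "numeric"
  )
)

setValidity("ArrayLayout", function(object) {
  msg <- character()
  m <- nrow(object@translations)
  if (m < 1L) msg <- c(msg, "at least one module required")
  if (length(object@rotations) != m)
    msg <- c(msg, "rotations length must match number of modules")
  pos <- optodePositions(object)
  all_pts <- rbind(pos$sources[, c("x", "y")], pos$detectors[, c("x", "y")])
  d <- as.matrix(dist(all_pts))
  diag(d) <- Inf
  if (any(d < 1e-6))
    msg <- c(msg, "optode positions must not coincide")
  if (length(msg)) msg else TRUE
})

#' TimingScheme: dual-integration frame timing
#'
#' Each illumination slot holds a short integration (A) and a long
#' integration (B); the LED switches on tauOvp before B starts, so the short
#' integration sees the source for only tauOvp. A frame is 48 illumination
#' slots plus one dark slot.
#'
#' @slot tShort,tLong,slot durations in ms; tShort + tLong = slot.
#' @slot tauOvp LED overlap time in ms, on the programmable grid
#'   seq(0.02, 0.5, by = 0.02).
#' @slot slotsPerFrame integer, default 49 (48 illuminations + 1 dark).
#' @exportClass TimingScheme
setClass("TimingScheme",
  representation(
    tShort = "numeric",
    tLong = "numeric",
    slot = "numeric",
    tauOvp = "numeric",
    slotsPerFrame = "integer"
  )
)

#' Programmable overlap-time grid (ms)
#' @export
tauOvpGrid <- function() seq(0.02, 0.5, by = 0.02)

setValidity("TimingScheme", function(object) {
  msg <- character()
  if (abs(object@tShort + object@tLong - object@slot) > 1e-9)
    msg <- c(msg, "tShort + tLong must equal slot")
  if (min(abs(object@tauOvp - tauOvpGrid())) > 1e-9)
    msg <- c(msg, "tauOvp must lie on the 0.02..0.5 ms grid (step 0.02)")
  if (object@tauOvp > object@tShort + 1e-9)
    msg <- c(msg, "tauOvp must not exceed tShort")
  if (object@slotsPerFrame < 1L)
    msg <- c(msg, "slotsPerFrame must be >= 1")
  if (length(msg)) msg else TRUE
})

#' DetectorSpec: charge-integrating detector characteristics
#'
#' @slot fullWell maximum accumulable charge per integration, pC.
#' @slot rmsNoise RMS charge noise, fC.
#' @slot responsivity photodiode responsivity, A/W.
#' @exportClass DetectorSpec
setClass("DetectorSpec",
  representation(
    fullWell = "numeric",
    rmsNoise = "numeric",
    responsivity = "numeric"
  )
)

setValidity("DetectorSpec", function(object) {
  msg <- character()
  if (object@fullWell <= 0) msg <- c(msg, "fullWell must be positive")
  if (object@rmsNoise <= 0) msg <- c(msg, "rmsNoise must be positive")
  if (object@responsivity <= 0 || object@responsivity > 1)
    msg <- c(msg, "responsivity must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' StimulusProtocol: block-design stimulus timing
#'
#' @slot onsets data.frame with columns condition (character), onset (s),
#'   duration (s).
#' @slot leadRest rest before first and after last block, s.
#' @slot isiRange inter-stimulus-interval jitter range, s.
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(
    onsets = "data.frame",
    leadRest = "numeric",
    isiRange = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  on <- object@onsets
  need <- c("condition", "onset", "duration")
  if (!all(need %in% names(on)))
    msg <- c(msg, "onsets must have columns condition, onset, duration")
  else if (nrow(on) > 1L) {
    o <- on[order(on$onset), ]
    ends <- o$onset + o$duration
    if (any(o$onset[-1L] < ends[-nrow(o)] - 1e-9))
      msg <- c(msg, "stimulus blocks must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' FrameSeries: dual-integration raw acquisition
#'
#' Raw per-slot charges from both integrations plus the per-frame dark
#' measurement, with saturation flags. Charges are in pC; saturated samples
#' equal the full-well charge exactly.
#'
#' @slot longCounts,shortCounts channels x frames matrices (pC).
#' @slot darkCounts detectors x frames matrix (pC).
#' @slot satLong,satShort logical matrices matching the count matrices.
#' @slot scheme the \linkS4class{TimingScheme} used.
#' @slot spec the \linkS4class{DetectorSpec} used.
#' @slot channels channel table (one row per channel, single wavelength set
#'   shared by both count matrices is stored per row via wavelength column).
#' @slot times frame mid-times in s.
#' @exportClass FrameSeries
setClass("FrameSeries",
  representation(
    longCounts = "matrix",
    shortCounts = "matrix",
    darkCounts = "matrix",
    satLong = "matrix",
    satShort = "matrix",
    scheme = "TimingScheme",
    spec = "DetectorSpec",
    channels = "data.frame",
    times = "numeric"
  )
)

setValidity("FrameSeries", function(object) {
  msg <- character()
  fw <- object@spec@fullWell
  if (any(object@longCounts < -1e-12) || any(object@longCounts > fw + 1e-9))
    msg <- c(msg, "longCounts must lie in [0, fullWell]")
  if (any(object@shortCounts < -1e-12) || any(object@shortCounts > fw + 1e-9))
    msg <- c(msg, "shortCounts must lie in [0, fullWell]")
  if (any(abs(object@longCounts[object@satLong] - fw) > 1e-9))
    msg <- c(msg, "saturated long samples must equal fullWell exactly")
  if (any(abs(object@shortCounts[object@satShort] - fw) > 1e-9))
    msg <- c(msg, "saturated short samples must equal fullWell exactly")
  if (ncol(object@longCounts) != length(object@times))
    msg <- c(msg, "times length must match frame count")
  if (length(msg)) msg else TRUE
})

#' VoxelGrid: regular reconstruction grid
#'
#' Axis-aligned voxel grid with z >= 0 pointing into the medium; optodes sit
#' on the z = 0 plane. Coordinates in mm; voxel centres are reported.
#'
#' @slot shape integer length-3 (nx, ny, nz).
#' @slot spacing voxel edge length, mm.
#' @slot origin coordinates of the centre of voxel (1,1,1), mm.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric")
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
  if (length(msg)) msg else TRUE
})

#' Jacobian: channel-to-voxel sensitivity matrix
#'
#' Continuous-wave absorption Jacobian in the Rytov normalization: entry
#' (channel, voxel) is the optical-density change per unit absorption change
#' (mm^-1) in that voxel. Entries are non-negative and each row's support is
#' concentrated between the channel's optodes.
#'
#' @slot matrix channels x voxels sensitivity matrix.
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot channels channel table the rows refer to.
#' @slot wavelength nm.
#' @exportClass Jacobian
setClass("Jacobian",
  representation(
    matrix = "matrix",
    grid = "VoxelGrid",
    channels = "data.frame",
    wavelength = "numeric"
  )
)

setValidity("Jacobian", function(object) {
  msg <- character()
  if (!all(is.finite(object@matrix))) msg <- c(msg, "matrix must be finite")
  if (any(object@matrix < 0)) msg <- c(msg, "CW absorption Jacobian must be non-negative")
  if (nrow(object@matrix) != nrow(object@channels))
    msg <- c(msg, "row count must match channel table")
  if (ncol(object@matrix) != prod(object@grid@shape))
    msg <- c(msg, "column count must match grid size")
  if (length(msg)) msg else TRUE
})

#' ChannelSeries: channel-wise time series container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one row per
#' (source, detector, wavelength) channel and one column per time sample.
#' Assays hold the stage-appropriate quantity: "intensity" (W) for raw and
#' detector-domain data, "od" for optical-density change, or "HbO"/"HbR"
#' (molar) for chromophore concentration changes. rowData carries the channel
#' table of \code{\link{enumerateChannels}}; colData carries sample times (s);
#' metadata carries the layout, protocol and generator ground truth.
#'
#' @exportClass ChannelSeries
setClass("ChannelSeries", contains = "SummarizedExperiment")

#' Construct a ChannelSeries
#'
#' @param assays named list of channels x time matrices.
#' @param channels channel table (see \code{\link{enumerateChannels}}).
#' @param times sample times in s.
#' @param metadata list (layout, protocol, ...).
#' @return a \linkS4class{ChannelSeries}.
#' @export
channelSeries <- function(assays, channels, times, metadata = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(channels),
    colData = S4Vectors::DataFrame(time = times),
    metadata = metadata)
  new("ChannelSeries", se)
}

#' Accessors for ChannelSeries
#'
#' \code{channelInfo} returns the channel table as a data.frame;
#' \code{sampleTimes} the sample times in s; \code{sampleRate} the sampling
#' rate in Hz.
#'
#' @param x a \linkS4class{ChannelSeries}.
#' @export
channelInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname channelInfo
#' @export
sampleTimes <- function(x) SummarizedExperiment::colData(x)$time

#' @rdname channelInfo
#' @export
sampleRate <- function(x) {
  t <- sampleTimes(x)
  1 / median(diff(t))
}

#' GroundTruth: generator truth for a synthetic run
#'
#' @slot centers nConditions x 3 matrix of activation centres (mm, z into
#'   the head).
#' @slot amplitudes data.frame(condition, hbo, hbr) in molar; hbr defaults
#'   opposite in sign to hbo.
#' @slot blobSigma spatial Gaussian sigma of the activation, mm (0 = single
#'   voxel).
#' @slot hrf list(peak, undershoot, ratio) of the double-gamma kernel (s).
#' @slot superficial data.frame(name, freq, amp): superficial oscillations,
#'   Hz and OD units at a 23 mm channel.
#' @slot nep noise-equivalent power, W.
#' @slot baselinePower optical power of a 23 mm channel at baseline, W.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    centers = "matrix",
    amplitudes = "data.frame",
    blobSigma = "numeric",
    hrf = "list",
    superficial = "data.frame",
    nep = "numeric",
    baselinePower = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@centers) != nrow(object@amplitudes))
    msg <- c(msg, "one centre per condition required")
  if (any(object@superficial$freq <= 0))
    msg <- c(msg, "superficial frequencies must be positive")
  if (object@nep < 0) msg <- c(msg, "nep must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MpuTrace: per-module accelerometer-norm traces
#'
#' @slot data modules x samples matrix of accelerometer norms (g).
#' @slot rate sampling rate, Hz (150 by default).
#' @exportClass MpuTrace
setClass("MpuTrace", representation(data = "matrix", rate = "numeric"))

setValidity("MpuTrace", function(object) {
  if (any(object@data < 0)) "accelerometer norm must be non-negative" else TRUE
})

#' HrfEstimate: deconvolved haemodynamic responses
#'
#' @slot hbo,hbr arrays [pairs x time x conditions], molar.
#' @slot times response window grid, s relative to onset.
#' @slot channels source-detector pair table.
#' @slot conditions condition labels.
#' @slot diagnostics list (design condition number, residual scale, ...).
#' @exportClass HrfEstimate
setClass("HrfEstimate",
  representation(hbo = "array", hbr = "array", times = "numeric",
                 channels = "data.frame", conditions = "character",
                 diagnostics = "list"))

setValidity("HrfEstimate", function(object) {
  msg <- character()
  if (dim(object@hbo)[2] != length(object@times))
    msg <- c(msg, "time dimension must match window grid")
  if (dim(object@hbo)[3] != length(object@conditions))
    msg <- c(msg, "condition dimension must match labels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HrfEstimate", function(object) {
  cat(sprintf("HrfEstimate: %d pairs x %d samples (%.1f..%.1f s) x %d condition(s)\n",
              dim(object@hbo)[1], length(object@times), min(object@times),
              max(object@times), length(object@conditions)))
})

#' VolumeImage: reconstructed chromophore images on a voxel grid
#'
#' @slot hbo,hbr per-voxel fields (molar), zero outside the sensitivity
#'   support.
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot label time (s relative to onset) or window label.
#' @exportClass VolumeImage
setClass("VolumeImage",
  representation(hbo = "numeric", hbr = "numeric", grid = "VoxelGrid",
                 label = "character"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  nv <- prod(object@grid@shape)
  if (length(object@hbo) != nv || length(object@hbr) != nv)
    msg <- c(msg, "field length must match grid")
  if (!all(is.finite(object@hbo)) || !all(is.finite(object@hbr)))
    msg <- c(msg, "fields must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VolumeImage", function(object) {
  cat(sprintf("VolumeImage [%s]: grid %s, HbO range [%.3g, %.3g] M\n",
              object@label, paste(object@grid@shape, collapse = "x"),
              min(object@hbo), max(object@hbo)))
})

#' StatResult: node-wise permutation test result
#'
#' @slot tstat per-node T statistic (NA outside the mask).
#' @slot significant logical per node, family-wise corrected at alpha.
#' @slot pvalue per-node corrected p-value.
#' @slot nPermutations number of sign-flip permutations used.
#' @slot seed integer seed.
#' @slot alpha significance level.
#' @exportClass StatResult
setClass("StatResult",
  representation(tstat = "numeric", significant = "logical",
                 pvalue = "numeric", nPermutations = "integer",
                 seed = "integer", alpha = "numeric"))

setValidity("StatResult", function(object) {
  msg <- character()
  if (any(object@significant & is.na(object@tstat)))
    msg <- c(msg, "significant nodes must lie inside the mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: %d nodes (%d masked), %d significant at alpha=%.2f, %d permutations\n",
              length(object@tstat), sum(!is.na(object@tstat)),
              sum(object@significant), object@alpha, object@nPermutations))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d condition(s), NEP %.3g W, baseline %.3g W @23mm\n",
              nrow(object@centers), object@nep, object@baselinePower))
})

setMethod("show", "MpuTrace", function(object) {
  cat(sprintf("MpuTrace: %d modules x %d samples at %g Hz\n",
              nrow(object@data), ncol(object@data), object@rate))
})

setMethod("show", "ModuleLayout", function(object) {
  cat("ModuleLayout:", object@boardSide, "mm board, 2 sources, 4 detectors\n")
})

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d modules (%d x %d, gap %.1f mm), %d sources, %d detectors\n",
              nrow(object@translations), object@nRows, object@nCols, object@gap,
              2L * nrow(object@translations), 4L * nrow(object@translations)))
})

setMethod("show", "TimingScheme", function(object) {
  cat(sprintf("TimingScheme: %d slots x %.1f ms (A %.1f ms, B %.1f ms, tau_ovp %.2f ms) -> %.2f Hz\n",
              object@slotsPerFrame, object@slot, object@tShort, object@tLong,
              object@tauOvp, frameRate(object)))
})

setMethod("show", "DetectorSpec", function(object) {
  cat(sprintf("DetectorSpec: full well %.3g pC, RMS noise %.3g fC, responsivity %.3f A/W\n",
              object@fullWell, object@rmsNoise, object@responsivity))
})

setMethod("show", "StimulusProtocol", function(object) {
  on <- object@onsets
  cat(sprintf("StimulusProtocol: %d blocks, %d condition(s), duration %.1f s\n",
              nrow(on), length(unique(on$condition)), protocolDuration(object)))
})

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: %d channels x %d frames, %d detectors dark-monitored\n",
              nrow(object@longCounts), ncol(object@longCounts),
              nrow(object@darkCounts)))
  cat(sprintf("  saturated long samples: %d, short: %d\n",
              sum(object@satLong), sum(object@satShort)))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels at %.1f mm\n",
              object@shape[1], object@shape[2], object@shape[3], object@spacing))
})

setMethod("show", "Jacobian", function(object) {
  cat(sprintf("Jacobian: %d channels x %d voxels at %g nm\n",
              nrow(object@matrix), ncol(object@matrix), object@wavelength))
})
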