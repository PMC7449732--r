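#' A planar surface-node sheet under the probe
#'
#' With no subject anatomy in play, the "cortical surface" is a regular
#' node sheet at a fixed depth below the optode plane, spanning the grid's
#' lateral extent.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param depth node depth below the optode plane, mm.
#' @param spacing node spacing, mm (default the grid spacing).
#' @return nNodes x 3 matrix of node positions (mm).
#' @export
surfaceSheet <- function(grid, depth = 12, spacing = grid@spacing) {
  xr <- grid@origin[1] + c(0, (grid@shape[1] - 1) * grid@spacing)
  yr <- grid@origin[2] + c(0, (grid@shape[2] - 1) * grid@spacing)
  g <- expand.grid(x = seq(xr[1], xr[2], by = spacing),
                   y = seq(yr[1], yr[2], by = spacing))
  cbind(x = g$x, y = g$y, z = depth)
}

#' Map a volume image onto surface nodes
#'
#' Each node takes the mean of all voxel values whose centres lie within
#' \code{radius}; nodes with no voxel in range are NA (undefined).
#'
#' @param img a \linkS4class{VolumeImage} or a per-voxel numeric vector.
#' @param nodes nNodes x 3 matrix (mm).
#' @param grid required when \code{img} is a plain vector.
#' @param radius mm (default 3).
#' @param chromophore "hbo" or "hbr" when \code{img} is a VolumeImage.
#' @return numeric per node (NA where undefined).
#' @export
volumeToSurface <- function(img, nodes, grid = NULL, radius = 3,
                            chromophore = "hbo") {
  if (is(img, "VolumeImage")) {
    grid <- img@grid
    vals <- slot(img, chromophore)
  } else vals <- img
  if (is.null(grid)) stop("grid required")
  if (is.null(dim(nodes)) || nrow(nodes) == 0L) stop("empty surface")
  vc <- voxelCenters(grid)
  out <- rep(NA_real_, nrow(nodes))
  r2 <- radius^2
  for (k in seq_len(nrow(nodes))) {
    d2 <- (vc[, 1] - nodes[k, 1])^2 + (vc[, 2] - nodes[k, 2])^2 +
      (vc[, 3] - nodes[k, 3])^2
    sel <- d2 <= r2
    if (any(sel)) out[k] <- mean(vals[sel])
  }
  out
}

#' Window averages of a response time series
#'
#' Mean over the activation window (default 6-16 s post onset) and the
#' baseline window (default -5-0 s) of a time-labelled series of images or
#' node maps.
#'
#' @param series matrix [units x time] or list of \linkS4class{VolumeImage}s.
#' @param times time labels, s relative to onset (taken from image labels
#'   for a list).
#' @param window activation window, s (default c(6, 16)).
#' @param baseline baseline window, s (default c(-5, 0)).
#' @param chromophore used for VolumeImage lists.
#' @return list(activation, baseline): per-unit means.
#' @export
windowAverage <- function(series, times = NULL, window = c(6, 16),
                          baseline = c(-5, 0), chromophore = "hbo") {
  if (is.list(series) && all(vapply(series, is, logical(1), "VolumeImage"))) {
    if (is.null(times))
      times <- as.numeric(vapply(series, slot, character(1), "label"))
    series <- vapply(series, function(im) slot(im, chromophore),
                     numeric(length(slot(series[[1]], chromophore))))
  }
  series <- as.matrix(series)
  if (is.null(times)) stop("times required")
  inWin <- times >= window[1] & times <= window[2]
  inBase <- times >= baseline[1] & times <= baseline[2]
  if (!any(inWin) || !any(inBase)) stop("empty window after discretization")
  list(activation = rowMeans(series[, inWin, drop = FALSE]),
       baseline = rowMeans(series[, inBase, drop = FALSE]))
}

#' Sign-flip permutation one-sample t-test with max-T correction
#'
#' One-sample T statistics per masked node over subjects, with the null
#' built by random sign flips of the subject maps (full enumeration of the
#' 2^n flips when that does not exceed \code{nPerm}); family-wise error is
#' controlled by the permutation distribution of the maximum |T| (max-T)
#' across masked nodes. Two-tailed by default.
#'
#' @param maps subjects x nodes matrix (activation minus baseline per
#'   subject).
#' @param mask logical per node (default all).
#' @param nPerm permutations when sampling (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for sampled flips.
#' @param twoTailed logical (default TRUE).
#' @return a \linkS4class{StatResult}.
#' @export
permutationTtest <- function(maps, mask = NULL, nPerm = 500L, alpha = 0.05,
                             seed = 1L, twoTailed = TRUE) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3L) stop("at least 3 subjects required")
  if (is.null(mask)) mask <- rep(TRUE, ncol(maps))
  if (!any(mask)) stop("empty mask")
  X <- maps[, mask, drop = FALSE]
  tOf <- function(M) {
    mu <- colMeans(M)
    se <- apply(M, 2, sd) / sqrt(n)
    t <- mu / se
    t[se == 0] <- 0
    t
  }
  tObs <- tOf(X)
  stat <- function(t) if (twoTailed) abs(t) else t
  if (2^n <= nPerm) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    nP <- nrow(flips)
  } else {
    flips <- withSeed(seed, matrix(sample(c(-1, 1), nPerm * n, replace = TRUE),
                                   nPerm, n))
    flips[1, ] <- 1   # include the identity so p >= 1/nPerm
    nP <- nPerm
  }
  maxT <- vapply(seq_len(nP), function(p)
    max(stat(tOf(X * flips[p, ]))), numeric(1))
  pCorr <- vapply(stat(tObs), function(t0) mean(maxT >= t0 - 1e-12),
                  numeric(1))
  tFull <- rep(NA_real_, ncol(maps))
  pFull <- rep(NA_real_, ncol(maps))
  sig <- rep(FALSE, ncol(maps))
  tFull[mask] <- tObs
  pFull[mask] <- pCorr
  sig[mask] <- pCorr <= alpha
  new("StatResult", tstat = tFull, significant = sig, pvalue = pFull,
      nPermutations = as.integer(nP), seed = as.integer(seed), alpha = alpha)
}

#' Dice overlap of two thresholded maps
#'
#' Each map is binarized at \code{frac} of its own maximum (default 30\%);
#' Dice = 2|A intersect B| / (|A| + |B|).
#'
#' @param mapA,mapB numeric per node (same node set); NA treated as 0.
#' @param frac threshold fraction (default 0.30).
#' @return Dice coefficient in [0, 1].
#' @export
diceOverlap <- function(mapA, mapB, frac = 0.30) {
  if (length(mapA) != length(mapB)) stop("maps must share the node set")
  mapA[is.na(mapA)] <- 0; mapB[is.na(mapB)] <- 0
  if (max(mapA) <= 0 || max(mapB) <= 0)
    stop("maps must have a positive maximum to threshold")
  a <- mapA >= frac * max(mapA)
  b <- mapB >= frac * max(mapB)
  if (sum(a) + sum(b) == 0L) return(NaN)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Resample an envelope to a target time base by any-within-frame OR
#'
#' @param env logical vector on a fast time base.
#' @param fromRate,toRate Hz.
#' @param nOut target length.
#' @return logical vector of length nOut.
#' @export
resampleEnvelope <- function(env, fromRate, toRate, nOut) {
  out <- logical(nOut)
  for (k in seq_len(nOut)) {
    lo <- floor((k - 1) * fromRate / toRate) + 1
    hi <- min(ceiling(k * fromRate / toRate), length(env))
    if (lo <= hi) out[k] <- any(env[lo:hi])
  }
  out
}

#' Concordance of artifact envelopes
#'
#' Conditional agreement rates between the optically-derived artifact
#' envelope and the accelerometer-derived one, on a common time base:
#' P(mpu | dot), P(no mpu | no dot), plus each envelope's artifact-burden
#' fraction.
#'
#' @param dotEnv,mpuEnv logical vectors of equal length.
#' @return list(pMpuGivenDot, pNoMpuGivenNoDot, dotBurden, mpuBurden).
#' @export
concordance <- function(dotEnv, mpuEnv) {
  if (length(dotEnv) != length(mpuEnv))
    stop("envelopes must share a time base")
  pDot <- mean(dotEnv)
  list(
    pMpuGivenDot = if (any(dotEnv)) mean(mpuEnv[dotEnv]) else NA_real_,
    pNoMpuGivenNoDot = if (any(!dotEnv)) mean(!mpuEnv[!dotEnv]) else NA_real_,
    dotBurden = pDot,
    mpuBurden = mean(mpuEnv))
}
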