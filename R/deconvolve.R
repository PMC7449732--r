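# Gaussian basis matrix on a time grid: one column per centre
gaussBasis <- function(tg, centers, sigma) {
  B <- outer(tg, centers, function(t, c) exp(-(t - c)^2 / (2 * sigma^2)))
  B
}

#' Deconvolve haemodynamic response functions
#'
#' Ordinary-least-squares deconvolution in channel space: for each condition
#' a set of onset-locked Gaussian basis functions (standard deviation and
#' spacing 1.5 s, spanning 5 s before to 30 s after onset) models the HRF;
#' the design additionally contains an intercept and, per channel, the
#' concentration series of the nearest good short-separation (<= 10 mm)
#' source-detector pair as a superficial-physiology nuisance regressor. The
#' fit is per chromophore; the HRF is the basis expansion of the fitted
#' coefficients, yielding a 35 s response per pair and condition.
#'
#' @param cs a \linkS4class{ChannelSeries} with assays "HbO" and "HbR"
#'   (output of \code{\link{mbll}}).
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param basisSigma,basisSpacing s (defaults 1.5).
#' @param window length-2, s relative to onset (default c(-5, 30)).
#' @param ssMaxSeparation mm (default 10): short-separation definition.
#' @param goodMask logical per pair (default: rows without NA).
#' @param useSs include the short-separation regressor (default TRUE); with
#'   no usable short-separation pair and \code{useSs = TRUE} an error is
#'   raised.
#' @return an \linkS4class{HrfEstimate}; diagnostics hold the design
#'   condition number and per-pair residual standard deviations.
#' @export
deconvolveHrf <- function(cs, protocol, basisSigma = 1.5, basisSpacing = 1.5,
                          window = c(-5, 30), ssMaxSeparation = 10,
                          goodMask = NULL, useSs = TRUE) {
  stopifnot(basisSpacing > 0, window[1] < 0, window[2] > 0)
  hboAll <- SummarizedExperiment::assay(cs, "HbO")
  hbrAll <- SummarizedExperiment::assay(cs, "HbR")
  ch <- channelInfo(cs)
  times <- sampleTimes(cs)
  rate <- sampleRate(cs)
  valid <- !apply(is.na(hboAll), 1, any)
  if (is.null(goodMask)) goodMask <- valid else goodMask <- goodMask & valid

  conds <- sort(unique(protocol@onsets$condition))
  centers <- seq(window[1], window[2], by = basisSpacing)
  nb <- length(centers)

  # stimulus-convolved design columns, shared by all channels
  Xstim <- matrix(0, length(times), nb * length(conds))
  for (ci in seq_along(conds)) {
    on <- protocol@onsets$onset[protocol@onsets$condition == conds[ci]]
    for (j in seq_len(nb)) {
      col <- numeric(length(times))
      for (o in on)
        col <- col + exp(-(times - o - centers[j])^2 / (2 * basisSigma^2))
      Xstim[, (ci - 1) * nb + j] <- col
    }
  }

  # + 0.5 mm: the short-detector placement tolerance of the module geometry
  ssIdx <- which(ch$separation <= ssMaxSeparation + 0.5 & goodMask)
  if (useSs && length(ssIdx) == 0L)
    stop("no good short-separation channel; set useSs = FALSE to opt out")

  # nearest SS pair per channel, by optode midpoint distance
  nearestSs <- rep(NA_integer_, nrow(ch))
  if (length(ssIdx)) {
    layout <- S4Vectors::metadata(cs)$layout
    if (!is.null(layout)) {
      pos <- optodePositions(layout)
      mid <- cbind((pos$sources$x[ch$source] + pos$detectors$x[ch$detector]) / 2,
                   (pos$sources$y[ch$source] + pos$detectors$y[ch$detector]) / 2)
      for (r in seq_len(nrow(ch))) {
        d2 <- (mid[ssIdx, 1] - mid[r, 1])^2 + (mid[ssIdx, 2] - mid[r, 2])^2
        nearestSs[r] <- ssIdx[which.min(d2)]
      }
    } else nearestSs[] <- ssIdx[1]
  }

  tg <- seq(window[1], window[2], by = 1 / rate)
  B <- gaussBasis(tg, centers, basisSigma)
  hbo <- array(NA_real_, c(nrow(ch), length(tg), length(conds)))
  hbr <- array(NA_real_, c(nrow(ch), length(tg), length(conds)))
  hboSe <- array(NA_real_, c(nrow(ch), length(conds)))
  hbrSe <- array(NA_real_, c(nrow(ch), length(conds)))
  residSd <- matrix(NA_real_, nrow(ch), 2,
                    dimnames = list(NULL, c("HbO", "HbR")))
  kappa <- NA_real_

  fitChrom <- function(Y, chromIdx) {
    # group channels by their SS regressor (or no-SS)
    groups <- split(seq_len(nrow(ch))[goodMask],
                    ifelse(useSs & !is.na(nearestSs[goodMask]) &
                             nearestSs[goodMask] != seq_len(nrow(ch))[goodMask],
                           nearestSs[goodMask], 0L))
    for (g in names(groups)) {
      rows <- groups[[g]]
      X <- cbind(1, Xstim)
      if (g != "0") X <- cbind(X, Y[as.integer(g), ])
      qx <- qr(X)
      if (qx$rank < ncol(X)) {
        sv <- svd(X, nu = 0, nv = 0)$d
        stop(sprintf("rank-deficient design (condition number %.3g)",
                     sv[1] / max(sv[length(sv)], .Machine$double.eps)))
      }
      kappa <<- max(kappa, kappa(qr.R(qx)), na.rm = TRUE)
      beta <- qr.coef(qx, t(Y[rows, , drop = FALSE]))
      fit <- X %*% beta
      res <- t(Y[rows, , drop = FALSE]) - fit
      rsd <- apply(res, 2, sd)
      XtXinv <- chol2inv(qr.R(qx))
      for (ci in seq_along(conds)) {
        cols <- 1L + (ci - 1L) * nb + seq_len(nb)
        hrfs <- t(B %*% beta[cols, , drop = FALSE])  # rows x time
        # standard error of the HRF peak via the basis expansion
        covB <- B %*% XtXinv[cols, cols] %*% t(B)
        seScale <- sqrt(max(diag(covB)))
        for (k in seq_along(rows)) {
          if (chromIdx == 1L) {
            hbo[rows[k], , ci] <<- hrfs[k, ]
            hboSe[rows[k], ci] <<- rsd[k] * seScale
          } else {
            hbr[rows[k], , ci] <<- hrfs[k, ]
            hbrSe[rows[k], ci] <<- rsd[k] * seScale
          }
        }
      }
      residSd[rows, chromIdx] <<- rsd
    }
  }
  fitChrom(hboAll, 1L)
  fitChrom(hbrAll, 2L)

  new("HrfEstimate", hbo = hbo, hbr = hbr, times = tg,
      channels = ch, conditions = conds,
      diagnostics = list(conditionNumber = kappa, residSd = residSd,
                         hboSe = hboSe, hbrSe = hbrSe,
                         nearestSs = nearestSs, goodMask = goodMask))
}

#' Map deconvolved chromophore HRFs back to channel optical density
#'
#' Forward modified Beer-Lambert step: for each good source-detector pair
#' and both wavelengths, dOD = (e_HbO dHbO + e_HbR dHbR) d DPF. This is the
#' attenuation-domain input the multispectral image reconstruction consumes.
#'
#' @param hrf an \linkS4class{HrfEstimate}.
#' @param condition condition label to extract.
#' @param wavelengths the two wavelengths, nm.
#' @param dpf named DPF per wavelength.
#' @param extinction extinction table.
#' @return list(od = matrix [2 nPairs x nTimes] ordered (all pairs at wl1,
#'   all pairs at wl2), channels, times).
#' @export
hrfToOd <- function(hrf, condition, wavelengths = c(740, 855),
                    dpf = c(`740` = 7.5, `855` = 7),
                    extinction = extinctionTable()) {
  ci <- match(condition, hrf@conditions)
  if (is.na(ci)) stop("unknown condition: ", condition)
  ch <- hrf@channels
  blocks <- lapply(wavelengths, function(wl) {
    e <- extinction[match(wl, extinction$wavelength), ]
    (hrf@hbo[, , ci] * e$hbo + hrf@hbr[, , ci] * e$hbr) *
      ch$separation * dpf[[as.character(wl)]]
  })
  list(od = do.call(rbind, blocks), channels = ch, times = hrf@times)
}
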