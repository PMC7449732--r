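# Orthogonal symlet-8 filter bank (16 taps). Standard published
# coefficients; periodized transform below is exactly orthonormal with them.
sym8DecLo <- c(
  -0.0033824159510061, -0.0005421323317911, 0.0316950878114930,
  0.0076074873249176, -0.1432942383508097, -0.0612733590676585,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.0519458381077090, -0.0272190299170560, 0.0491371796736075,
  0.0038087520138906, -0.0149522583370482, -0.0003029205147214,
  0.0018899503327595)
sym8DecHi <- rev(sym8DecLo) * rep_len(c(1, -1), length(sym8DecLo))

dwtStep <- function(x, lo = sym8DecLo, hi = sym8DecHi) {
  n <- length(x)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  k2 <- 2 * (seq_len(half) - 1L)
  for (j in seq_along(lo)) {
    idx <- (k2 + (j - 1L)) %% n + 1L
    a <- a + lo[j] * x[idx]
    d <- d + hi[j] * x[idx]
  }
  list(a = a, d = d)
}

idwtStep <- function(a, d, lo = sym8DecLo, hi = sym8DecHi) {
  n <- 2 * length(a)
  x <- numeric(n)
  k2 <- 2 * (seq_along(a) - 1L)
  for (j in seq_along(lo)) {
    idx <- (k2 + (j - 1L)) %% n + 1L
    contrib <- lo[j] * a + hi[j] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Periodized orthogonal discrete wavelet transform
#'
#' Multi-level pyramid with the symlet-8 filter bank and circular boundary
#' handling; the input is symmetric-padded to a multiple of 2^levels and the
#' padding removed on inversion. \code{dwt} returns the coefficient pyramid,
#' \code{idwt} reconstructs (perfect reconstruction to machine precision).
#'
#' @param x numeric vector.
#' @param levels decomposition depth (default 4).
#' @return list(approx, details = list(level1..levelL), n = original length,
#'   levels).
#' @export
dwt <- function(x, levels = 4L) {
  n <- length(x)
  block <- 2^levels
  if (n < 2 * block) stop("record too short for ", levels, " levels")
  npad <- ceiling(n / block) * block
  if (npad > n) x <- c(x, rev(x)[seq_len(npad - n)])
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwtStep(a)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, n = n, levels = levels)
}

#' @rdname dwt
#' @param coeffs a pyramid from \code{dwt}.
#' @export
idwt <- function(coeffs) {
  a <- coeffs$approx
  for (l in rev(seq_len(coeffs$levels)))
    a <- idwtStep(a, coeffs$details[[l]])
  a[seq_len(coeffs$n)]
}

#' Kurtosis-based wavelet motion correction
#'
#' Per channel: decompose into a 4-level symlet-8 pyramid; at each detail
#' level, while the coefficient kurtosis exceeds \code{kurtosisLevel}
#' (non-excess; 3 for a Gaussian), zero the largest-magnitude coefficient;
#' reconstruct. Motion spikes concentrate in few large detail coefficients
#' and drive kurtosis up, so the loop removes them while leaving
#' Gaussian-like (artifact-free) levels untouched.
#'
#' @param x a \linkS4class{ChannelSeries} with assay "od", or a numeric
#'   matrix (rows = channels), or a vector.
#' @param kurtosisLevel threshold (default 3.3).
#' @param levels decomposition depth (default 4).
#' @return same type as the input, corrected. Because the transform is
#'   orthogonal and the edit leaves every level at or below the kurtosis
#'   threshold, a second pass is a no-op.
#' @export
waveletCorrect <- function(x, kurtosisLevel = 3.3, levels = 4L) {
  correct1 <- function(v) {
    if (anyNA(v)) return(v)
    py <- dwt(v, levels)
    for (l in seq_len(py$levels)) {
      d <- py$details[[l]]
      removed <- 0L
      while (kurtosis(d) > kurtosisLevel && removed < length(d) - 2L) {
        d[which.max(abs(d))] <- 0
        removed <- removed + 1L
      }
      py$details[[l]] <- d
    }
    idwt(py)
  }
  if (is(x, "ChannelSeries")) {
    m <- SummarizedExperiment::assay(x, "od")
    for (r in seq_len(nrow(m))) m[r, ] <- correct1(m[r, ])
    SummarizedExperiment::assay(x, "od") <- m
    x
  } else if (is.matrix(x)) {
    t(apply(x, 1, correct1))
  } else correct1(x)
}
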