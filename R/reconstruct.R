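#' First-order spatial difference operator on a masked voxel grid
#'
#' Stacked forward differences along the three grid axes, restricted to
#' voxel pairs that both lie in the support mask; mask-boundary voxels with
#' no in-mask forward neighbour along an axis simply contribute no row on
#' that axis. Applied to a constant field the result is exactly zero.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param supportMask logical per voxel (default all).
#' @return sparse Matrix of dim (<= 3 nMasked, nMasked), columns indexed by
#'   the masked voxels in mask order.
#' @export
buildGradientOperator <- function(grid, supportMask = NULL) {
  s <- grid@shape
  nv <- prod(s)
  if (is.null(supportMask)) supportMask <- rep(TRUE, nv)
  if (!any(supportMask)) stop("empty support mask")
  idxMap <- integer(nv)
  idxMap[supportMask] <- seq_len(sum(supportMask))
  ind <- arrayInd(which(supportMask), s)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  nRow <- 0L
  stride <- c(1L, s[1], s[1] * s[2])
  lin <- which(supportMask)
  for (ax in 1:3) {
    hasNb <- ind[, ax] < s[ax]
    nb <- lin + stride[ax]
    ok <- hasNb & supportMask[pmin(nb, nv)]
    from <- idxMap[lin[ok]]
    to <- idxMap[nb[ok]]
    k <- sum(ok)
    if (k > 0L) {
      rows <- c(rows, nRow + seq_len(k), nRow + seq_len(k))
      cols <- c(cols, from, to)
      vals <- c(vals, rep(-1, k), rep(1, k))
      nRow <- nRow + k
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nRow, sum(supportMask)))
}

#' LSQR iterative least-squares solver
#'
#' Paige-Saunders bidiagonalization solver for min ||A x - b||_2 with A
#' supplied as a function handle: \code{aprod(x, 1)} returns A x and
#' \code{aprod(y, 2)} returns t(A) y. Iterations stop at \code{maxIter} or
#' when the estimated residual of the (possibly damped/augmented) system
#' falls below \code{tol} relative to ||b||.
#'
#' @param aprod function(v, mode) as above.
#' @param b right-hand side.
#' @param n number of unknowns.
#' @param maxIter iteration cap (default 50).
#' @param tol relative stopping tolerance (default 1e-5).
#' @return list(x, iterations, residualNorm, residualHistory).
#' @export
lsqr <- function(aprod, b, n, maxIter = 50L, tol = 1e-5) {
  x <- numeric(n)
  u <- b
  beta <- sqrt(sum(u^2))
  if (beta == 0) return(list(x = x, iterations = 0L, residualNorm = 0,
                             residualHistory = numeric(0)))
  u <- u / beta
  v <- aprod(u, 2L)
  alpha <- sqrt(sum(v^2))
  if (alpha > 0) v <- v / alpha
  w <- v
  phibar <- beta
  rhobar <- alpha
  hist <- numeric(0)
  iters <- 0L
  for (it in seq_len(maxIter)) {
    u <- aprod(v, 1L) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- aprod(u, 2L) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho
    sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    iters <- it
    hist <- c(hist, phibar)
    if (phibar <= tol * sqrt(sum(b^2))) break
  }
  list(x = x, iterations = iters, residualNorm = phibar,
       residualHistory = hist)
}

#' Reconstruction configuration
#'
#' @param lambda Tikhonov regularization hyperparameter (default 1e-3,
#'   acting on the column-normalized system).
#' @param maxIter LSQR iteration cap (default 50).
#' @param tol LSQR stopping tolerance (default 1e-5).
#' @param normalize column-normalize the system matrix before solving
#'   (default TRUE).
#' @param maskFrac sensitivity-mask fraction used for the default support
#'   (default 0.05).
#' @return list of class "ReconConfig".
#' @export
reconConfig <- function(lambda = 1e-3, maxIter = 50L, tol = 1e-5,
                        normalize = TRUE, maskFrac = 0.05) {
  stopifnot(lambda > 0, maxIter >= 1)
  structure(list(lambda = lambda, maxIter = as.integer(maxIter), tol = tol,
                 normalize = normalize, maskFrac = maskFrac),
            class = "ReconConfig")
}

# Prepare the regularized, column-normalized augmented system once so a
# whole time series can be solved with the same factors.
reconOperator <- function(msj, config, mask = NULL, goodRows = NULL) {
  A <- msj$matrix
  nVox <- msj$nVox
  if (is.null(goodRows)) goodRows <- rep(TRUE, nrow(A))
  if (!any(goodRows)) stop("all channels bad")
  A <- A[goodRows, , drop = FALSE]
  if (is.null(mask)) {
    map <- colSums(abs(A[, seq_len(nVox), drop = FALSE]))
    mask <- sensitivityMask(map, config$maskFrac)
  }
  cols <- c(which(mask), nVox + which(mask))
  Am <- A[, cols, drop = FALSE]
  cn <- sqrt(colSums(Am^2))
  cn[cn == 0] <- 1
  if (config$normalize) Am <- sweep(Am, 2, cn, "/")
  L <- buildGradientOperator(msj$grid, mask)
  nm <- sum(mask)
  wgt <- config$lambda * max(sqrt(rowSums(Am^2)))
  # augmented system [Am; wgt L_HbO; wgt L_HbR]: the L blocks act on the
  # first nm (HbO) and last nm (HbR) columns respectively
  aprod <- function(z, mode) {
    if (mode == 1L) {
      c(as.vector(Am %*% z),
        wgt * as.vector(L %*% z[seq_len(nm)]),
        wgt * as.vector(L %*% z[nm + seq_len(nm)]))
    } else {
      m1 <- nrow(Am); m2 <- nrow(L)
      top <- as.vector(crossprod(Am, z[seq_len(m1)]))
      top[seq_len(nm)] <- top[seq_len(nm)] +
        wgt * as.vector(crossprod(L, z[m1 + seq_len(m2)]))
      top[nm + seq_len(nm)] <- top[nm + seq_len(nm)] +
        wgt * as.vector(crossprod(L, z[m1 + m2 + seq_len(m2)]))
      top
    }
  }
  list(aprod = aprod, mask = mask, cn = cn, nm = nm, nAug = 2L * nrow(L),
       nData = nrow(Am), goodRows = goodRows, grid = msj$grid,
       nVox = nVox, config = config)
}

#' Solve the multispectral inverse problem for one data vector
#'
#' Minimizes ||A x - y||^2 + lambda^2 ||L x||^2 over the sensitivity-mask
#' support via LSQR on the augmented system, where A is the (optionally
#' column-normalized) multispectral Jacobian restricted to good channels and
#' L the first-order spatial difference operator applied to each chromophore
#' block. Voxels outside the mask are exactly zero.
#'
#' @param y optical-density vector ordered like the rows of \code{msj}
#'   (all channels at wavelength 1, then wavelength 2).
#' @param msj a "MultispectralJacobian" (see
#'   \code{\link{multispectralJacobian}}).
#' @param config a \code{\link{reconConfig}}.
#' @param mask optional logical voxel support (default: 5\% sensitivity
#'   mask).
#' @param goodRows logical over the rows of \code{msj} (default all).
#' @return a \linkS4class{VolumeImage}; attribute "solver" carries
#'   iterations and residual history.
#' @export
reconstructImage <- function(y, msj, config = reconConfig(), mask = NULL,
                             goodRows = NULL) {
  op <- reconOperator(msj, config, mask, goodRows)
  solveWithOperator(y, op, label = "t=0")
}

solveWithOperator <- function(y, op, label = "") {
  if (length(y) != length(op$goodRows))
    stop("data vector length must match Jacobian rows")
  if (any(!is.finite(y[op$goodRows]))) stop("data must be finite")
  b <- c(y[op$goodRows], numeric(op$nAug))
  res <- lsqr(op$aprod, b, n = 2L * op$nm,
              maxIter = op$config$maxIter, tol = op$config$tol)
  x <- res$x
  if (op$config$normalize) x <- x / op$cn
  hbo <- numeric(op$nVox); hbr <- numeric(op$nVox)
  hbo[op$mask] <- x[seq_len(op$nm)]
  hbr[op$mask] <- x[op$nm + seq_len(op$nm)]
  img <- new("VolumeImage", hbo = hbo, hbr = hbr, grid = op$grid,
             label = as.character(label))
  attr(img, "solver") <- res[c("iterations", "residualNorm",
                               "residualHistory")]
  img
}

#' Reconstruct a time series of images
#'
#' One image per column of \code{y} (or per HRF time point when an
#' \linkS4class{HrfEstimate} plus condition is given, after mapping the
#' chromophore responses back to attenuation with \code{\link{hrfToOd}}).
#' The regularized operator is prepared once and reused.
#'
#' @param y matrix [2 nChannels x nTimes] of optical density, or an
#'   \linkS4class{HrfEstimate}.
#' @param msj a "MultispectralJacobian".
#' @param config a \code{\link{reconConfig}}.
#' @param mask,goodRows as in \code{\link{reconstructImage}}.
#' @param condition required when \code{y} is an HrfEstimate.
#' @param times optional labels for the columns (s).
#' @return list of \linkS4class{VolumeImage}s.
#' @export
reconstructSeries <- function(y, msj, config = reconConfig(), mask = NULL,
                              goodRows = NULL, condition = NULL,
                              times = NULL) {
  if (is(y, "HrfEstimate")) {
    if (is.null(condition)) stop("condition required for HrfEstimate input")
    conv <- hrfToOd(y, condition)
    times <- conv$times
    y <- conv$od
    y[is.na(y)] <- 0
  }
  y <- as.matrix(y)
  if (is.null(times)) times <- seq_len(ncol(y))
  op <- reconOperator(msj, config, mask, goodRows)
  lapply(seq_len(ncol(y)), function(j)
    solveWithOperator(y[, j], op, label = as.character(times[j])))
}
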