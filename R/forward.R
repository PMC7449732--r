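#' Haemoglobin extinction coefficients at the device wavelengths
#'
#' Molar extinction coefficients for oxy- and deoxy-haemoglobin at 740 and
#' 855 nm, from the standard compiled spectra, converted from base-10
#' cm^-1 M^-1 to the natural-log mm^-1 M^-1 convention used throughout this
#' package (optical density is natural-log based here). The table is plain
#' data so analyses can pin or substitute their own version.
#'
#' @return data.frame(wavelength (nm), hbo, hbr) in mm^-1 M^-1 (natural log).
#' @export
extinctionTable <- function() {
  # base-10, cm^-1 M^-1
  e10 <- data.frame(wavelength = c(740, 855),
                    hbo = c(446, 1065),
                    hbr = c(1115.88, 700))
  data.frame(wavelength = e10$wavelength,
             hbo = e10$hbo * log(10) / 10,
             hbr = e10$hbr * log(10) / 10)
}

#' Baseline tissue optical properties
#'
#' Homogeneous scalp-like absorption and reduced scattering per wavelength,
#' with the tissue refractive index; literature-scale values, exposed as
#' configuration.
#'
#' @param mua740,mua855 absorption, mm^-1.
#' @param musp740,musp855 reduced scattering, mm^-1.
#' @param n refractive index.
#' @return named list: one list(mua, musp) per wavelength plus \code{n}.
#' @export
opticalProperties <- function(mua740 = 0.0164, musp740 = 0.74,
                              mua855 = 0.0190, musp855 = 0.64, n = 1.4) {
  stopifnot(mua740 > 0, mua855 > 0, musp740 > 0, musp855 > 0)
  if (musp740 < 10 * mua740 || musp855 < 10 * mua855)
    warning("mu_s' is not >> mu_a; diffusion approximation may be invalid")
  list(`740` = list(mua = mua740, musp = musp740),
       `855` = list(mua = mua855, musp = musp855),
       n = n)
}

#' Construct a regular reconstruction voxel grid
#'
#' @param shape length-3 integer (default 50 x 60 x 50).
#' @param spacing voxel edge, mm.
#' @param origin centre of voxel (1,1,1), mm (default puts the first voxel
#'   centre half a voxel below the z = 0 optode plane).
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(shape = c(50L, 60L, 50L), spacing = 2,
                      origin = c(0, 0, spacing / 2)) {
  new("VoxelGrid", shape = as.integer(shape), spacing = spacing,
      origin = origin)
}

#' Voxel centre coordinates
#'
#' Voxels are ordered with x fastest, then y, then z (R array order for an
#' array of dim \code{shape}).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return nVoxels x 3 matrix (mm).
#' @export
voxelCenters <- function(grid) {
  s <- grid@shape
  idx <- arrayInd(seq_len(prod(s)), s)
  sweep((idx - 1) * grid@spacing, 2, grid@origin, "+")
}

# (1 + Reff) / (1 - Reff) with Reff from the standard refractive-index
# mismatch polynomial Reff = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n
boundaryA <- function(n) {
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + reff) / (1 - reff)
}

#' Continuous-wave Green's function for a semi-infinite medium
#'
#' Fluence at \code{rObs} from an isotropic point source placed one
#' transport mean free path (1/mu_s') below the surface entry point
#' \code{rSrc}, with the extrapolated-boundary image source enforcing the
#' zero-fluence condition above the tissue. Optionally the source is given a
#' lateral Gaussian profile by averaging over a 9-point stencil of standard
#' deviation \code{blurSigma}.
#'
#' @param rSrc length-2 or -3 surface position (mm; z taken as 0).
#' @param rObs n x 3 matrix (or length-3 vector) of observation points,
#'   z >= 0.
#' @param props \code{\link{opticalProperties}} list.
#' @param wavelength nm (must index \code{props}).
#' @param rmin minimum source-observer distance, mm (regularizes coincident
#'   points; default half a 2 mm voxel).
#' @param blurSigma lateral source blur sigma in mm (0 = point source).
#' @return fluence per unit source power, mm^-2 (vector of length n).
#' @export
greenCw <- function(rSrc, rObs, props = opticalProperties(),
                    wavelength = 740, rmin = 1, blurSigma = 0) {
  if (is.null(dim(rObs))) rObs <- matrix(rObs, 1)
  if (any(rObs[, 3] < -1e-9)) stop("observation points must have z >= 0")
  p <- props[[as.character(wavelength)]]
  if (is.null(p)) stop("no optical properties for wavelength ", wavelength)
  mut <- p$mua + p$musp
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * p$mua * mut)
  z0 <- 1 / p$musp
  zb <- 2 * boundaryA(props$n) * D
  xy <- c(rSrc[1], rSrc[2])
  offs <- if (blurSigma > 0) {
    s <- blurSigma
    cbind(x = c(0, -s, s, 0, 0, -s, -s, s, s),
          y = c(0, 0, 0, -s, s, -s, s, -s, s))
  } else cbind(x = 0, y = 0)
  w <- exp(-(offs[, 1]^2 + offs[, 2]^2) / (2 * max(blurSigma, 1)^2))
  w <- w / sum(w)
  phi <- numeric(nrow(rObs))
  for (k in seq_len(nrow(offs))) {
    sx <- xy[1] + offs[k, 1]; sy <- xy[2] + offs[k, 2]
    d1 <- sqrt((rObs[, 1] - sx)^2 + (rObs[, 2] - sy)^2 + (rObs[, 3] - z0)^2)
    d2 <- sqrt((rObs[, 1] - sx)^2 + (rObs[, 2] - sy)^2 +
                 (rObs[, 3] + z0 + 2 * zb)^2)
    d1 <- pmax(d1, rmin); d2 <- pmax(d2, rmin)
    phi <- phi + w[k] *
      (exp(-mueff * d1) / d1 - exp(-mueff * d2) / d2) / (4 * pi * D)
  }
  unname(pmax(phi, .Machine$double.xmin))
}

#' Build the absorption sensitivity matrix for one wavelength
#'
#' Adjoint (Rytov-normalized) construction on the voxel grid:
#' J[channel, voxel] = G(src, voxel) G(voxel, det) / G(src, det) x voxel
#' volume, the optical-density change per unit absorption change (mm^-1) in
#' the voxel.
#'
#' @param layout an \linkS4class{ArrayLayout}.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param props \code{\link{opticalProperties}} list.
#' @param wavelength nm.
#' @param channels optional channel table (default enumerates the layout at
#'   this wavelength).
#' @param blurSigma lateral source blur, mm (default 2).
#' @return a \linkS4class{Jacobian}.
#' @export
buildJacobian <- function(layout, grid, props = opticalProperties(),
                          wavelength = 740,
                          channels = enumerateChannels(layout, wavelength),
                          blurSigma = 2) {
  if (prod(grid@shape) < 1L) stop("empty grid")
  pos <- optodePositions(layout)
  vc <- voxelCenters(grid)
  rmin <- grid@spacing / 2
  fl <- function(p2d) greenCw(p2d, vc, props, wavelength, rmin = rmin,
                              blurSigma = blurSigma)
  srcPhi <- lapply(seq_len(nrow(pos$sources)), function(i)
    fl(c(pos$sources$x[i], pos$sources$y[i])))
  detPhi <- lapply(seq_len(nrow(pos$detectors)), function(i)
    fl(c(pos$detectors$x[i], pos$detectors$y[i])))
  vol <- grid@spacing^3
  J <- matrix(0, nrow(channels), nrow(vc))
  for (r in seq_len(nrow(channels))) {
    si <- channels$source[r]; di <- channels$detector[r]
    gsd <- greenCw(c(pos$sources$x[si], pos$sources$y[si]),
                   c(pos$detectors$x[di], pos$detectors$y[di], 0),
                   props, wavelength, rmin = rmin, blurSigma = blurSigma)
    J[r, ] <- srcPhi[[si]] * detPhi[[di]] / gsd * vol
  }
  new("Jacobian", matrix = J, grid = grid, channels = channels,
      wavelength = wavelength)
}

#' Stack wavelength Jacobians into the multispectral system
#'
#' Maps voxel-wise (dHbO, dHbR) fields directly to dual-wavelength
#' optical-density changes:
#' rows are (channels at wl1, channels at wl2), columns are
#' (HbO voxels, HbR voxels), with each block e_chromophore,wl * J_wl.
#'
#' @param j1,j2 \linkS4class{Jacobian}s at the two wavelengths (matched
#'   channel lists and grids).
#' @param extinction \code{\link{extinctionTable}}-style data.frame.
#' @return list(matrix, grid, channels, wavelengths, nVox) of class
#'   "MultispectralJacobian".
#' @export
multispectralJacobian <- function(j1, j2, extinction = extinctionTable()) {
  if (!identical(j1@grid@shape, j2@grid@shape) ||
      nrow(j1@channels) != nrow(j2@channels) ||
      !all(j1@channels$source == j2@channels$source) ||
      !all(j1@channels$detector == j2@channels$detector))
    stop("Jacobians must share grid and channel list")
  eps <- function(wl, chrom)
    extinction[[chrom]][match(wl, extinction$wavelength)]
  A <- rbind(
    cbind(eps(j1@wavelength, "hbo") * j1@matrix,
          eps(j1@wavelength, "hbr") * j1@matrix),
    cbind(eps(j2@wavelength, "hbo") * j2@matrix,
          eps(j2@wavelength, "hbr") * j2@matrix))
  ch <- rbind(cbind(j1@channels, wavelength = j1@wavelength),
              cbind(j2@channels, wavelength = j2@wavelength))
  structure(list(matrix = A, grid = j1@grid,
                 channels = ch,
                 wavelengths = c(j1@wavelength, j2@wavelength),
                 nVox = prod(j1@grid@shape)),
            class = "MultispectralJacobian")
}

#' Array sensitivity map and support mask
#'
#' The sensitivity map sums |J| over the good channels per voxel; the mask
#' keeps voxels whose sensitivity reaches \code{frac} of the maximum
#' (default 5\%).
#'
#' @param jacobian a \linkS4class{Jacobian}.
#' @param goodMask logical per channel (default all good).
#' @return numeric per-voxel map.
#' @export
sensitivityMap <- function(jacobian, goodMask = NULL) {
  J <- jacobian@matrix
  if (is.null(goodMask)) goodMask <- rep(TRUE, nrow(J))
  if (!any(goodMask)) stop("all channels bad")
  colSums(abs(J[goodMask, , drop = FALSE]))
}

#' @rdname sensitivityMap
#' @param map per-voxel sensitivity map.
#' @param frac fraction of the maximum (default 0.05).
#' @export
sensitivityMask <- function(map, frac = 0.05) {
  if (frac == 0) return(map > 0)
  map >= frac * max(map)
}
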