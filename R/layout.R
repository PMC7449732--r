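#' Build the default optode geometry of one module
#'
#' Places the two dual-wavelength source sites at opposite corners of the
#' board (inset \code{cornerInset} mm), the two corner detectors at the
#' remaining corners, and the two short-separation detectors exactly 10 mm
#' from their paired source and 28 mm from the opposite source, so the
#' within-board source-detector separation multiset is
#' {10, 10, 23, 23, 23, 23, 28, 28} mm. Coordinates are configuration; the
#' separation multiset is the contract.
#'
#' @param boardSide board edge length in mm (default 30).
#' @param cornerInset corner inset in mm (default 3.5, giving exact 23 mm
#'   corner channels on a 30 mm board).
#' @return a \linkS4class{ModuleLayout}.
#' @export
moduleLayout <- function(boardSide = 30, cornerInset = 3.5) {
  s1 <- c(cornerInset, cornerInset)
  s2 <- c(boardSide - cornerInset, boardSide - cornerInset)
  d1 <- c(boardSide - cornerInset, cornerInset)
  d2 <- c(cornerInset, boardSide - cornerInset)
  # short detector: distance 10 from own source, 28 from the other source
  d12 <- sqrt(sum((s2 - s1)^2))
  along <- (d12^2 + 10^2 - 28^2) / (2 * d12)
  perp <- sqrt(10^2 - along^2)
  u <- (s2 - s1) / d12
  v <- c(u[2], -u[1])
  sd1 <- s1 + along * u + perp * v
  sd2 <- s2 - along * u - perp * v
  new("ModuleLayout",
      boardSide = boardSide,
      sourcePositions = rbind(s1, s2, deparse.level = 0),
      cornerDetectorPositions = rbind(d1, d2, deparse.level = 0),
      shortDetectorPositions = rbind(sd1, sd2, deparse.level = 0))
}

#' Build a probe array of modules
#'
#' Lays \code{nRows * nCols} identical modules on a planar raster with a
#' uniform inter-module gap (default 2 mm, the thickness of the elastic
#' strapping that holds the modules in formation).
#'
#' @param nRows,nCols raster dimensions (default 2 x 6, the 12-module probe).
#' @param gap inter-module gap in mm (default 2).
#' @param module a \linkS4class{ModuleLayout} (default \code{moduleLayout()}).
#' @return an \linkS4class{ArrayLayout}.
#' @export
arrayLayout <- function(nRows = 2L, nCols = 6L, gap = 2, module = moduleLayout()) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  stopifnot(nRows >= 1L, nCols >= 1L, gap >= 0)
  pitch <- module@boardSide + gap
  grid <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
  tr <- cbind((grid$col - 1L) * pitch, (grid$row - 1L) * pitch)
  new("ArrayLayout", module = module, translations = tr,
      rotations = rep(0, nrow(tr)), nRows = nRows, nCols = nCols, gap = gap)
}

#' Number of modules in an array
#' @param layout an \linkS4class{ArrayLayout}.
#' @export
nModules <- function(layout) nrow(layout@translations)

rotMat <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Probe-frame optode positions
#'
#' @param layout an \linkS4class{ArrayLayout}.
#' @return list with data.frames \code{sources} (x, y, module, localIndex)
#'   and \code{detectors} (x, y, module, localIndex, type); detector type is
#'   "corner" or "short". Global indices are row numbers.
#' @export
optodePositions <- function(layout) {
  m <- layout@module
  placeOne <- function(i) {
    R <- rotMat(layout@rotations[i])
    tr <- layout@translations[i, ]
    place <- function(p) sweep(p %*% t(R), 2, -tr)
    list(src = place(m@sourcePositions),
         det = place(rbind(m@cornerDetectorPositions, m@shortDetectorPositions)))
  }
  placed <- lapply(seq_len(nModules(layout)), placeOne)
  src <- do.call(rbind, lapply(seq_along(placed), function(i)
    data.frame(x = placed[[i]]$src[, 1], y = placed[[i]]$src[, 2],
               module = i, localIndex = 1:2)))
  det <- do.call(rbind, lapply(seq_along(placed), function(i)
    data.frame(x = placed[[i]]$det[, 1], y = placed[[i]]$det[, 2],
               module = i, localIndex = 1:4,
               type = c("corner", "corner", "short", "short"))))
  rownames(src) <- NULL; rownames(det) <- NULL
  list(sources = src, detectors = det)
}

#' Enumerate all source-detector-wavelength channels of a probe
#'
#' Every (source, detector) pair across all modules forms a logical channel
#' at every wavelength, cross-module channels included; a 12-module probe
#' yields 24 x 48 = 1152 channels per wavelength. No distance cutoff is
#' applied here; unusable long channels are removed downstream by the
#' quality-control pruning step.
#'
#' @param layout an \linkS4class{ArrayLayout}.
#' @param wavelengths numeric vector of wavelengths in nm
#'   (default \code{c(740, 855)}).
#' @return data.frame with one row per channel: source, detector (global
#'   0-based in the JSON export, 1-based here), wavelength (nm), separation
#'   (mm), source/detector module, shortSeparation flag.
#' @export
enumerateChannels <- function(layout, wavelengths = c(740, 855)) {
  if (nModules(layout) < 1L) stop("empty layout")
  if (length(wavelengths) < 1L) stop("at least one wavelength required")
  pos <- optodePositions(layout)
  ns <- nrow(pos$sources); nd <- nrow(pos$detectors)
  pairs <- expand.grid(detector = seq_len(nd), source = seq_len(ns))
  sep <- sqrt((pos$sources$x[pairs$source] - pos$detectors$x[pairs$detector])^2 +
              (pos$sources$y[pairs$source] - pos$detectors$y[pairs$detector])^2)
  one <- data.frame(
    source = pairs$source,
    detector = pairs$detector,
    separation = sep,
    sourceModule = pos$sources$module[pairs$source],
    detectorModule = pos$detectors$module[pairs$detector],
    detectorType = pos$detectors$type[pairs$detector]
  )
  out <- do.call(rbind, lapply(wavelengths, function(w)
    cbind(one, wavelength = w)))
  out$shortSeparation <- out$separation <= 10 + 0.5
  out$channel <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("channel", "source", "detector", "wavelength", "separation",
          "sourceModule", "detectorModule", "detectorType", "shortSeparation")]
}

#' Serialize / restore a probe layout as JSON
#'
#' Positions in mm in the probe frame, 0-based optode indices, following the
#' probe-group conventions of the SNIRF container family.
#'
#' @param layout an \linkS4class{ArrayLayout}.
#' @param path file to write / read.
#' @return \code{writeLayout} returns \code{path} invisibly;
#'   \code{readLayout} returns the \linkS4class{ArrayLayout}.
#' @export
writeLayout <- function(layout, path) {
  pos <- optodePositions(layout)
  obj <- list(
    probe = list(
      sourcePos2D = as.matrix(pos$sources[, c("x", "y")]),
      detectorPos2D = as.matrix(pos$detectors[, c("x", "y")]),
      sourceModule = pos$sources$module - 1L,
      detectorModule = pos$detectors$module - 1L,
      detectorType = pos$detectors$type,
      lengthUnit = "mm"
    ),
    array = list(
      nRows = layout@nRows, nCols = layout@nCols, gap = layout@gap,
      translations = layout@translations, rotations = layout@rotations,
      module = list(
        boardSide = layout@module@boardSide,
        sourcePositions = layout@module@sourcePositions,
        cornerDetectorPositions = layout@module@cornerDetectorPositions,
        shortDetectorPositions = layout@module@shortDetectorPositions
      )
    )
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$array$module
  mod <- new("ModuleLayout",
             boardSide = m$boardSide,
             sourcePositions = matrix(unlist(m$sourcePositions), ncol = 2),
             cornerDetectorPositions = matrix(unlist(m$cornerDetectorPositions), ncol = 2),
             shortDetectorPositions = matrix(unlist(m$shortDetectorPositions), ncol = 2))
  new("ArrayLayout", module = mod,
      translations = matrix(unlist(obj$array$translations), ncol = 2),
      rotations = as.numeric(obj$array$rotations),
      nRows = as.integer(obj$array$nRows), nCols = as.integer(obj$array$nCols),
      gap = as.numeric(obj$array$gap))
}
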