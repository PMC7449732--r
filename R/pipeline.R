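#' Default pipeline configuration
#'
#' Desk-scale defaults: the full 12-module probe, a shortened block design,
#' a coarse reconstruction grid and a small synthetic cohort, chosen so the
#' complete pipeline runs end to end on one CPU in minutes. All randomness
#' derives from \code{seed}.
#'
#' @param seed master seed.
#' @param nSubjects synthetic subjects (>= 3 for group statistics).
#' @param layoutRows,layoutCols probe raster (default the 2 x 6, 12-module
#'   array).
#' @param nBlocks,blockDuration,isiRange,leadRest stimulus design.
#' @param conditions condition labels.
#' @param gridSpacing reconstruction voxel size, mm.
#' @param gridMargin lateral margin around the probe, mm.
#' @param gridDepth grid depth, mm.
#' @param lambda,maxIter,tol reconstruction settings.
#' @param nPerm,alpha group-statistics settings.
#' @param surfaceDepth surface-sheet depth, mm.
#' @param motionEvents events per subject passed to
#'   \code{\link{injectMotion}} (0 disables).
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 1L, nSubjects = 7L,
                           layoutRows = 2L, layoutCols = 6L, nBlocks = 4L,
                           blockDuration = 17.5, isiRange = c(17.5, 22.5),
                           leadRest = 30, conditions = c("left", "right"),
                           gridSpacing = 8, gridMargin = 16, gridDepth = 40,
                           lambda = 1e-3, maxIter = 50L, tol = 1e-5,
                           nPerm = 500L, alpha = 0.05, surfaceDepth = 12,
                           motionEvents = 2L) {
  if (nSubjects < 1L) stop("nSubjects must be positive")
  structure(as.list(environment()), class = "PipelineConfig")
}

hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: probe layout, forward model, per-subject simulation
#' (stimulus protocol, channel intensities, dual-integration frames, motion
#' injection), preprocessing (pruning, optical density, artifact detection
#' before and after wavelet correction, band-pass, Beer-Lambert conversion,
#' short-separation-regressed HRF deconvolution), window-average
#' multispectral reconstruction, surface mapping, and the group sign-flip
#' permutation test. Returns a manifest with per-stage summaries and
#' content hashes; reruns with the same configuration are identical up to
#' the timestamp.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list manifest: config, seeds, stage summaries, group result,
#'   hash (over everything but the timestamp), timestamp.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (config$nSubjects < 3L)
    stop("group statistics require at least 3 subjects")
  stage <- "layout"
  manifest <- list(config = config[setdiff(names(config), "")],
                   stages = list())
  done <- function(name, summary) {
    manifest$stages[[name]] <<- summary
  }
  tryCatch({
    layout <- arrayLayout(config$layoutRows, config$layoutCols)
    channels <- enumerateChannels(layout)
    done("layout", list(nModules = nModules(layout),
                        nChannels = nrow(channels)))

    stage <- "forward"
    extent <- c(max(optodePositions(layout)$sources$x,
                    optodePositions(layout)$detectors$x),
                max(optodePositions(layout)$sources$y,
                    optodePositions(layout)$detectors$y))
    shape <- c(ceiling((extent[1] + 2 * config$gridMargin) / config$gridSpacing),
               ceiling((extent[2] + 2 * config$gridMargin) / config$gridSpacing),
               ceiling(config$gridDepth / config$gridSpacing))
    grid <- voxelGrid(shape, config$gridSpacing,
                      origin = c(-config$gridMargin, -config$gridMargin,
                                 config$gridSpacing / 2))
    j740 <- buildJacobian(layout, grid, wavelength = 740)
    j855 <- buildJacobian(layout, grid, wavelength = 855)
    msj <- multispectralJacobian(j740, j855)
    done("forward", list(grid = shape, nVox = prod(shape)))

    stage <- "subjects"
    nodes <- surfaceSheet(grid, depth = config$surfaceDepth)
    nc <- length(config$conditions)
    truth <- groundTruth(
      conditions = config$conditions,
      centers = cbind(seq(0.25, 0.75, length.out = max(nc, 2))[seq_len(nc)] *
                        extent[1],
                      rep(extent[2] / 2, nc), rep(12, nc)))
    subjMaps <- list()
    summaries <- list()
    scheme <- timingScheme()
    for (s in seq_len(config$nSubjects)) {
      sseed <- config$seed * 1000L + s
      protocol <- makeProtocol(nBlocks = config$nBlocks,
                               conditions = config$conditions,
                               blockDuration = config$blockDuration,
                               isiRange = config$isiRange,
                               leadRest = config$leadRest, seed = sseed)
      cs <- simulateChannels(layout, protocol, truth,
                             list(`740` = j740, `855` = j855), seed = sseed)
      if (config$motionEvents > 0L) {
        ev <- withSeed(sseed + 7L, data.frame(
          time = runif(config$motionEvents, 20,
                       protocolDuration(protocol) - 20),
          kind = sample(c("spike", "shift"), config$motionEvents,
                        replace = TRUE),
          magnitude = runif(config$motionEvents, 0.3, 1.0),
          module = sample(nModules(layout), config$motionEvents,
                          replace = TRUE)))
        cs <- injectMotion(cs, ev, seed = sseed + 8L)
      }
      frames <- toFrames(cs, scheme = scheme, seed = sseed + 1L)
      sel <- selectIntegration(frames)
      csI <- framesToIntensity(frames, sel)
      S4Vectors::metadata(csI) <- S4Vectors::metadata(cs)

      good <- pruneChannels(csI)
      od <- intensityToOd(csI)
      rate <- sampleRate(od)
      odGood <- SummarizedExperiment::assay(od, "od")[good, , drop = FALSE]
      pre <- detectMotion(odGood, rate = rate)
      odC <- waveletCorrect(od)
      post <- detectMotion(
        SummarizedExperiment::assay(odC, "od")[good, , drop = FALSE],
        rate = rate)
      odF <- bandpassFilter(odC)
      conc <- mbll(odF)
      goodPairs <- good[channelInfo(csI)$wavelength == 740]
      hrf <- deconvolveHrf(conc, protocol, goodMask = goodPairs)

      goodRows <- rep(goodPairs, 2L)
      for (cond in config$conditions) {
        odHrf <- hrfToOd(hrf, cond)
        odHrf$od[is.na(odHrf$od)] <- 0
        wins <- windowAverage(odHrf$od, odHrf$times)
        imgs <- reconstructSeries(cbind(wins$activation, wins$baseline), msj,
                                  reconConfig(config$lambda, config$maxIter,
                                              config$tol),
                                  goodRows = goodRows,
                                  times = c("activation", "baseline"))
        act <- volumeToSurface(imgs[[1]], nodes)
        bas <- volumeToSurface(imgs[[2]], nodes)
        key <- cond
        m <- act - bas
        m[is.na(m)] <- 0
        subjMaps[[key]] <- rbind(subjMaps[[key]], m)
      }
      short <- channelInfo(csI)$separation <= 35
      summaries[[s]] <- list(
        subject = s, seed = sseed,
        goodChannelFrac = mean(good),
        goodFrac035 = mean(good[short]),
        artifactBurdenPre = pre$burden,
        artifactBurdenPost = post$burden,
        nGoodPairs = sum(goodPairs))
    }
    done("subjects", summaries)

    stage <- "stats"
    sens <- volumeToSurface(sensitivityMap(j740), nodes, grid = grid,
                            radius = config$gridSpacing)
    sens[is.na(sens)] <- 0
    mask <- sens >= 0.05 * max(sens)
    results <- lapply(config$conditions, function(cond)
      permutationTtest(subjMaps[[cond]], mask = mask, nPerm = config$nPerm,
                       alpha = config$alpha, seed = config$seed))
    names(results) <- config$conditions
    done("stats", lapply(results, function(r)
      list(nSignificant = sum(r@significant),
           nPermutations = r@nPermutations)))

    manifest$results <- results
    manifest$hash <- hashObject(manifest[c("config", "stages")])
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
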