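#' Write / read a run container
#'
#' A run is serialized as a directory of plain JSON files whose grouping
#' follows the shared fNIRS container conventions: \code{probe.json}
#' (optode geometry), \code{data.json} (channel table, sample times and all
#' assay matrices at full precision), \code{stim.json} (stimulus timing),
#' \code{aux.json} (accelerometer traces) and \code{meta.json} (format
#' version plus any unknown fields, preserved verbatim). The round trip is
#' lossless.
#'
#' @param cs a \linkS4class{ChannelSeries}.
#' @param dir directory to create/overwrite.
#' @param mpu optional \linkS4class{MpuTrace}.
#' @param extra list of additional fields preserved in meta.json.
#' @return \code{writeRun}: \code{dir}, invisibly. \code{readRun}: list
#'   (cs, mpu, extra).
#' @export
writeRun <- function(cs, dir, mpu = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- S4Vectors::metadata(cs)
  if (!is.null(md$layout))
    writeLayout(md$layout, file.path(dir, "probe.json"))
  asy <- SummarizedExperiment::assays(cs)
  jsonlite::write_json(
    list(assays = lapply(as.list(asy), unclass),
         channels = channelInfo(cs),
         time = sampleTimes(cs)),
    file.path(dir, "data.json"), digits = I(17), auto_unbox = TRUE)
  if (!is.null(md$protocol)) {
    p <- md$protocol
    jsonlite::write_json(
      list(onsets = p@onsets, leadRest = p@leadRest, isiRange = p@isiRange),
      file.path(dir, "stim.json"), digits = I(17), auto_unbox = TRUE)
  }
  if (!is.null(mpu))
    jsonlite::write_json(list(rate = mpu@rate, data = unclass(mpu@data)),
                         file.path(dir, "aux.json"), digits = I(17),
                         auto_unbox = TRUE)
  jsonlite::write_json(list(format = "hddot-run", version = 1L,
                            extra = extra),
                       file.path(dir, "meta.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeRun
#' @export
readRun <- function(dir) {
  need <- c("probe.json", "data.json", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("malformed run container: missing ", paste(missing, collapse = ", "))
  layout <- readLayout(file.path(dir, "probe.json"))
  d <- jsonlite::read_json(file.path(dir, "data.json"), simplifyVector = TRUE)
  assays <- lapply(d$assays, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  protocol <- NULL
  if (file.exists(file.path(dir, "stim.json"))) {
    s <- jsonlite::read_json(file.path(dir, "stim.json"), simplifyVector = TRUE)
    onsets <- as.data.frame(s$onsets)
    if (nrow(onsets) == 0L)
      onsets <- data.frame(condition = character(), onset = numeric(),
                           duration = numeric())
    protocol <- new("StimulusProtocol", onsets = onsets,
                    leadRest = s$leadRest, isiRange = s$isiRange)
  }
  mpu <- NULL
  if (file.exists(file.path(dir, "aux.json"))) {
    a <- jsonlite::read_json(file.path(dir, "aux.json"), simplifyVector = TRUE)
    m <- as.matrix(a$data); dimnames(m) <- NULL
    mpu <- new("MpuTrace", data = m, rate = a$rate)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cs <- channelSeries(assays, as.data.frame(d$channels), as.numeric(d$time),
                      metadata = list(layout = layout, protocol = protocol))
  list(cs = cs, mpu = mpu, extra = meta$extra)
}

#' Export channel data as long-format CSV
#'
#' One row per (channel, frame): channel, wavelength, time, value of the
#' first assay.
#'
#' @param cs a \linkS4class{ChannelSeries}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportCsv <- function(cs, path) {
  m <- SummarizedExperiment::assay(cs, 1)
  ch <- channelInfo(cs)
  times <- sampleTimes(cs)
  df <- data.frame(
    channel = rep(ch$channel, times = ncol(m)),
    wavelength = rep(if (is.null(ch$wavelength)) NA else ch$wavelength,
                     times = ncol(m)),
    time = rep(times, each = nrow(m)),
    value = as.vector(m))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
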