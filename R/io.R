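frameFileName <- function(drain, batch, frame, ext = "png") {
  sprintf("d%02d_b%03d_f%d.%s", drain, batch, frame, ext)
}

#' Write a FrameBatch as 8-bit grayscale PNG files
#'
#' Files are named \code{dDD_bBBB_fF.png} (drain, batch, frame indices).
#'
#' @param batch a [FrameBatch-class].
#' @param dir output directory (created if missing).
#' @param drain,batchIndex 1-based indices used in the filenames.
#' @return character vector of file paths (invisibly).
#' @export
writeFrameBatch <- function(batch, dir, drain = 1L, batchIndex = 1L) {
  stopifnot(is(batch, "FrameBatch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(5)
  for (i in 1:5) {
    paths[i] <- file.path(dir, frameFileName(drain, batchIndex, i))
    png::writePNG(batch@frames[, , i] / 255, paths[i])
  }
  invisible(paths)
}

readFrameFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]  # grayscale channel
  round(img * 255)
}

#' Read five frame files into a FrameBatch
#'
#' @param paths five PNG (or TIFF) file paths in frame order.
#' @return a [FrameBatch-class].
#' @export
readFrameBatch <- function(paths) {
  if (length(paths) != 5L) stop("a batch consists of exactly 5 frames")
  mats <- lapply(paths, readFrameFile)
  d <- dim(mats[[1]])
  a <- array(0, dim = c(d[1], d[2], 5))
  for (i in 1:5) a[, , i] <- mats[[i]]
  new("FrameBatch", frames = a)
}

#' Write a drain (or whole session) of simulated batches to disk
#'
#' Writes every frame as PNG plus a \code{manifest.csv} (columns drain,
#' batch, frame, path) and, when truths are supplied, a
#' \code{truth.csv} with per-frame true counts.
#'
#' @param batches list of [FrameBatch-class].
#' @param dir output directory.
#' @param drain drain index for filenames.
#' @param truths optional list of [SceneTruth-class] matching
#'   \code{batches}.
#' @return path of the manifest file (invisibly).
#' @export
writeDrain <- function(batches, dir, drain = 1L, truths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truthRows <- list()
  for (b in seq_along(batches)) {
    paths <- writeFrameBatch(batches[[b]], dir, drain, b)
    rows[[b]] <- data.frame(
      drain = drain, batch = b, frame = 1:5, path = basename(paths)
    )
    if (!is.null(truths)) {
      truthRows[[b]] <- data.frame(
        drain = drain, batch = b, frame = 1:5,
        true_count = truths[[b]]@counts,
        true_concentration = truths[[b]]@trueConcentration
      )
    }
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  if (!is.null(truths)) {
    utils::write.csv(
      do.call(rbind, truthRows), file.path(dir, "truth.csv"),
      row.names = FALSE
    )
  }
  invisible(manifestPath)
}

#' Read batches listed in a manifest CSV
#'
#' @param manifestPath CSV with columns \code{drain, batch, frame, path}
#'   (paths relative to the manifest's directory).
#' @return list with \code{batches} (list of [FrameBatch-class]) and
#'   \code{index} (data.frame of drain/batch ids, one row per batch).
#' @export
readManifest <- function(manifestPath) {
  man <- utils::read.csv(manifestPath)
  need <- c("drain", "batch", "frame", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(man) %% 5L != 0L) {
    stop("manifest rows must be a multiple of the batch size (5)")
  }
  dir <- dirname(manifestPath)
  man <- man[order(man$drain, man$batch, man$frame), ]
  key <- interaction(man$drain, man$batch, drop = TRUE)
  groups <- split(man, key)
  batches <- lapply(groups, function(g) {
    if (nrow(g) != 5L || !identical(sort(g$frame), 1:5)) {
      stop("each (drain, batch) group must have frames 1..5")
    }
    readFrameBatch(file.path(dir, g$path[order(g$frame)]))
  })
  index <- do.call(rbind, lapply(groups, function(g) {
    data.frame(drain = g$drain[1], batch = g$batch[1])
  }))
  o <- order(index$drain, index$batch)
  list(batches = batches[o], index = index[o, ])
}

#' Serialise a CalibrationModel to JSON
#'
#' @param model a [CalibrationModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCalibrationModel <- function(model, path) {
  stopifnot(is(model, "CalibrationModel"))
  obj <- list(
    slope = model@slope, intercept = model@intercept,
    weighted_r2 = model@weightedR2,
    slope_sd = model@slopeSD, intercept_sd = model@interceptSD,
    r2_sd = model@r2SD, k = model@k, seed = model@seed,
    folds = model@foldTable
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CalibrationModel from JSON
#'
#' @param path file written by [writeCalibrationModel()].
#' @return a [CalibrationModel-class].
#' @export
readCalibrationModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationModel",
    slope = obj$slope, intercept = obj$intercept,
    weightedR2 = obj$weighted_r2,
    slopeSD = obj$slope_sd, interceptSD = obj$intercept_sd,
    r2SD = obj$r2_sd, k = as.integer(obj$k),
    foldTable = as.data.frame(obj$folds), seed = as.integer(obj$seed)
  )
}

#' Serialise a ParameterSet to JSON
#'
#' @param params a [ParameterSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeParameterSet <- function(params, path) {
  stopifnot(is(params, "ParameterSet"))
  vals <- lapply(slotNames("ParameterSet"), function(s) slot(params, s))
  names(vals) <- slotNames("ParameterSet")
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ParameterSet from JSON
#'
#' @param path file written by [writeParameterSet()].
#' @return a [ParameterSet-class].
#' @export
readParameterSet <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(defaultParameters, vals)
}

#' Write a SessionReport as JSON
#'
#' @param report a [SessionReport-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSessionReport <- function(report, path) {
  stopifnot(is(report, "SessionReport"))
  obj <- list(
    drain_means = report@drainMeans,
    session_mean = report@sessionMean,
    session_min = report@sessionMin,
    session_max = report@sessionMax,
    zone = report@zone,
    recommendation = report@recommendation
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
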