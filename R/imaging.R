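#' Default image batch analysis parameters
#'
#' The shipped defaults were derived on the synthetic scene simulator by
#' running the grid-search tuner against simulator ground truth; they are
#' a starting point, and [gridSearch()] re-derives them for any new
#' optical setup or reference count set. Notable choices: no crop (the
#' synthetic scenes are in focus to the edge; real optics with blurry
#' borders should set \code{cropFraction < 1}), downscale 2 to suppress
#' pixel noise, and a cell difference threshold (50) sitting between the
#' "ghost" deviation a moving object induces at its position in the
#' \emph{other} frames (about a quarter of its contrast) and its
#' full contrast in its own frame.
#'
#' @param ... named [ParameterSet-class] slot overrides.
#' @return a validated [ParameterSet-class].
#' @examples
#' defaultParameters()
#' defaultParameters(cellBatchDiffThreshold = 60)
#' @export
defaultParameters <- function(...) {
  p <- list(
    cropFraction = 1.0,
    downscaleFactor = 2L,
    contrastLowPct = 0.5,
    contrastHighPct = 99.5,
    cellBatchDiffThreshold = 50,
    cellBlurSigma = 1.5,
    cellMinArea = 3,
    cellMaxArea = 300,
    artifactDownscaleFactor = 4L,
    artifactBatchDiffThreshold = 25,
    artifactMinArea = 400,
    artifactDilation = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p$downscaleFactor <- as.integer(p$downscaleFactor)
  p$artifactDownscaleFactor <- as.integer(p$artifactDownscaleFactor)
  do.call(new, c(list("ParameterSet"), p))
}

## Block-mean downscale of a matrix by an integer factor; trailing rows /
## columns that do not fill a block are discarded.
blockMean <- function(m, f) {
  if (f == 1L) return(m)
  h <- (nrow(m) %/% f) * f
  w <- (ncol(m) %/% f) * f
  if (h < f || w < f) stop("downscale factor leaves an empty image")
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  # average f x f blocks: fold rows, then columns
  dim(m) <- c(f, h %/% f, w)
  m <- colMeans(m)              # (h/f) x w
  m <- t(m)
  dim(m) <- c(f, w %/% f, h %/% f)
  t(colMeans(m))                # (h/f) x (w/f)
}

## Robust stretch anchors from an intensity sample: the low anchor is
## the contrastLowPct percentile; the high anchor is the
## contrastHighPct percentile, capped at the reflection of the low
## anchor about the median. The cap keeps the background mapped
## mid-range even when a bright bubble occupies a sizeable fraction of
## the frame (a plain upper percentile would land inside the bubble and
## compress the background towards black).
stretchAnchors <- function(values, params) {
  q <- stats::quantile(
    values, c(params@contrastLowPct, params@contrastHighPct) / 100,
    names = FALSE, type = 7
  )
  med <- stats::median(values)
  sym <- 2 * med - q[1]
  # a degenerate upper percentile (at or below the median, e.g. in a
  # noiseless scene) cannot serve as an anchor; fall back to the
  # symmetric reflection alone
  hi <- if (q[2] <= med) sym else min(q[2], sym)
  c(q[1], hi)
}

#' Preprocess one frame
#'
#' Central crop to \code{cropFraction} of each dimension, block-mean
#' downscale by \code{downscaleFactor}, then a linear contrast stretch
#' onto 0..255 (clipped). The stretch anchors are the
#' \code{contrastLowPct} percentile and the \code{contrastHighPct}
#' percentile capped at the low anchor's reflection about the median,
#' which pins the background near mid-range regardless of how much
#' bright bubble area the frame contains. A constant frame passes
#' through unchanged.
#'
#' @param frame numeric matrix, grayscale intensities.
#' @param params a [ParameterSet-class].
#' @param anchors optional numeric(2): fixed low/high stretch anchors in
#'   input grayscale units. When processing a whole batch the anchors
#'   are computed once from the pooled five frames and shared, so all
#'   frames see the same linear map and the static background still
#'   cancels exactly in the batch differencing. \code{NULL} (default)
#'   computes the percentiles from this frame alone.
#' @return numeric matrix at working resolution.
#' @export
preprocessFrame <- function(frame, params, anchors = NULL) {
  stopifnot(is.matrix(frame))
  if (nrow(frame) < 1L || ncol(frame) < 1L) stop("frame is empty")
  ch <- floor(nrow(frame) * params@cropFraction)
  cw <- floor(ncol(frame) * params@cropFraction)
  if (ch < 1L || cw < 1L) stop("crop produces an empty image")
  r0 <- floor((nrow(frame) - ch) / 2)
  c0 <- floor((ncol(frame) - cw) / 2)
  m <- frame[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE]
  m <- blockMean(m, params@downscaleFactor)
  q <- if (is.null(anchors)) stretchAnchors(m, params) else anchors
  if (q[2] - q[1] <= 0) return(m)  # constant (or near-constant) image
  # pmin/pmax take attributes from their first argument: keep the matrix
  pmin(pmax((m - q[1]) / (q[2] - q[1]) * 255, 0), 255)
}

## 8-connected component labelling of a logical matrix via a pixel
## adjacency graph (EBImage::bwlabel is 4-connected, the contract here
## is 8-connected). Returns an integer matrix of labels, 0 = background.
labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  inside <- matrix(FALSE, nrow(mask), ncol(mask))
  inside[fg] <- TRUE
  edges <- list()
  rowOf <- ((fg - 1L) %% nr) + 1L
  colOf <- ((fg - 1L) %/% nr) + 1L
  addEdge <- function(ok, offset) {
    from <- fg[ok]
    to <- from + offset
    keep <- inside[to]
    cbind(from[keep], to[keep])
  }
  edges[[1]] <- addEdge(rowOf < nr, 1L)                      # down
  edges[[2]] <- addEdge(colOf < ncol(mask), nr)              # right
  edges[[3]] <- addEdge(rowOf < nr & colOf < ncol(mask), nr + 1L)  # dr
  edges[[4]] <- addEdge(rowOf > 1L & colOf < ncol(mask), nr - 1L)  # ur
  ed <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(ed) > 0L) {
    g <- igraph::add_edges(g, rbind(match(ed[, 1], fg), match(ed[, 2], fg)))
  }
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

## Per-frame absolute deviation from the pooled mean of the other four
## frames; `a` is an h x w x 5 array. Returns an array of deviations.
batchDeviation <- function(a) {
  s <- a[, , 1] + a[, , 2] + a[, , 3] + a[, , 4] + a[, , 5]
  dev <- array(0, dim = dim(a))
  for (i in 1:5) {
    othersMean <- (s - a[, , i]) / 4
    dev[, , i] <- abs(a[, , i] - othersMean)
  }
  dev
}

checkBatch <- function(batch) {
  if (!is(batch, "FrameBatch")) stop("batch must be a FrameBatch")
  if (dim(batch@frames)[3] != 5L) {
    stop("image batch analysis requires exactly 5 frames")
  }
  invisible(TRUE)
}

## Preprocess all five frames with contrast anchors pooled over the
## batch (computed on the cropped, downscaled stack): per-frame
## percentiles would give each frame its own gain when a bright bubble
## enters or leaves, breaking the cancellation of the static background
## in the differencing step.
preprocessBatch <- function(batch, params) {
  geo <- vector("list", 5)
  for (i in 1:5) {
    m <- batch@frames[, , i]
    ch <- floor(nrow(m) * params@cropFraction)
    cw <- floor(ncol(m) * params@cropFraction)
    r0 <- floor((nrow(m) - ch) / 2)
    c0 <- floor((ncol(m) - cw) / 2)
    geo[[i]] <- blockMean(
      m[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE],
      params@downscaleFactor
    )
  }
  anchors <- stretchAnchors(unlist(geo), params)
  a <- array(0, dim = c(nrow(geo[[1]]), ncol(geo[[1]]), 5))
  for (i in 1:5) {
    m <- geo[[i]]
    if (anchors[2] - anchors[1] > 0) {
      m <- pmin(pmax((m - anchors[1]) / (anchors[2] - anchors[1]) * 255, 0),
                255)
    }
    a[, , i] <- m
  }
  a
}

## Shared mask machinery: threshold the batch deviation, optionally blur
## and re-binarise at a fixed level, then filter components by area. Returns list(masks = logical array, labels = list of label
## matrices restricted to retained components).
deviationMasks <- function(a, threshold, blurSigma, minArea, maxArea) {
  dev <- batchDeviation(a)
  h <- dim(a)[1]; w <- dim(a)[2]
  masks <- array(FALSE, dim = dim(a))
  labels <- vector("list", 5)
  for (i in 1:5) {
    raw <- dev[, , i] > threshold
    if (blurSigma > 0 && any(raw)) {
      # blur the 0/1 mask and re-binarise at a fixed level: the kernel is
      # normalised, so solid regions stay near 1 while isolated noise
      # pixels peak at ~1/(2*pi*sigma^2) and drop out
      # replicate boundary: the default circular convolution would wrap
      # mask content across opposite frame edges
      bl <- EBImage::imageData(
        EBImage::gblur(raw * 1, sigma = blurSigma, boundary = "replicate")
      )
      raw <- bl > 0.25
    }
    lab <- labelComponents(raw)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      keep <- which(areas >= minArea & areas <= maxArea)
      lab[!(lab %in% keep)] <- 0L
    }
    labels[[i]] <- lab
    masks[, , i] <- lab > 0L
  }
  list(masks = masks, labels = labels)
}

#' Per-frame moving-cell masks by temporal batch differencing
#'
#' For each frame i and pixel (x, y), the pixel is positive when its
#' value deviates from the mean of the pooled pixels at the same
#' coordinates in the other four frames by more than
#' \code{cellBatchDiffThreshold}. The deviation is taken as an absolute
#' difference since a moving cell can be darker or brighter than the
#' pooled mean after contrast stretching. The raw mask is Gaussian
#' blurred (\code{cellBlurSigma}) and re-binarised (at a fixed 0.25
#' level) to merge the turbulence trail around each cell, and connected
#' components (8-connectivity) outside
#' \code{[cellMinArea, cellMaxArea]} are removed. Anything static across
#' the burst - the background, fixed-pattern sensor noise, stuck debris -
#' cancels in the differencing and never enters the mask.
#'
#' @param batch a [FrameBatch-class] of already-preprocessed frames, or
#'   an \code{h x w x 5} numeric array.
#' @param params a [ParameterSet-class].
#' @return logical array \code{h x w x 5} of cell masks.
#' @export
cellMask <- function(batch, params) {
  a <- if (is(batch, "FrameBatch")) {
    checkBatch(batch)
    batch@frames
  } else {
    batch
  }
  if (dim(a)[3] != 5L) stop("image batch analysis requires exactly 5 frames")
  deviationMasks(
    a, params@cellBatchDiffThreshold, params@cellBlurSigma,
    params@cellMinArea, params@cellMaxArea
  )$masks
}

#' Per-frame bubble/artifact masks
#'
#' The same batch differencing as [cellMask()], but run at a coarser
#' resolution (an additional block-mean downscale by
#' \code{artifactDownscaleFactor}) and thresholded at
#' \code{artifactBatchDiffThreshold}. Components whose area at working
#' scale is at least \code{artifactMinArea} px^2 are kept, the masks of
#' the five frames are pooled (union), dilated by
#' \code{artifactDilation} px, and upscaled back to working resolution.
#' The union is deliberate: a bubble present anywhere in the burst
#' perturbs the pooled-pixel mean at its position in \emph{every} frame
#' of the batch, so the region it occupied in any frame is unreliable
#' for cell detection in all of them. Cell centroids falling inside the
#' artifact mask are discarded downstream.
#'
#' @inheritParams cellMask
#' @return logical array \code{h x w x 5} of artifact masks at working
#'   resolution.
#' @export
artifactMask <- function(batch, params) {
  a <- if (is(batch, "FrameBatch")) {
    checkBatch(batch)
    batch@frames
  } else {
    batch
  }
  if (dim(a)[3] != 5L) stop("image batch analysis requires exactly 5 frames")
  h <- dim(a)[1]; w <- dim(a)[2]
  fa <- params@artifactDownscaleFactor
  coarse <- array(0, dim = c(h %/% fa, w %/% fa, 5))
  for (i in 1:5) coarse[, , i] <- blockMean(a[, , i], fa)
  dev <- batchDeviation(coarse)
  minAreaCoarse <- params@artifactMinArea / fa^2
  dil <- ceiling(params@artifactDilation / fa)
  brush <- if (dil > 0) EBImage::makeBrush(2L * dil + 1L, shape = "disc")
  pooled <- matrix(FALSE, dim(coarse)[1], dim(coarse)[2])
  for (i in 1:5) {
    m <- dev[, , i] > params@artifactBatchDiffThreshold
    lab <- labelComponents(m)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      keep <- which(areas >= minAreaCoarse)
      m <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    }
    pooled <- pooled | m
  }
  if (any(pooled) && dil > 0) {
    pooled <- EBImage::imageData(EBImage::dilate(pooled * 1, brush)) > 0
  }
  # upscale to working resolution; rows/columns beyond the coarse grid
  # (when dimensions are not multiples of fa) replicate the nearest
  # coarse block rather than staying unmasked
  ri <- pmin(rep(seq_len(h), length.out = h), nrow(pooled) * fa)
  ci <- pmin(rep(seq_len(w), length.out = w), ncol(pooled) * fa)
  full <- pooled[(ri - 1L) %/% fa + 1L, (ci - 1L) %/% fa + 1L, drop = FALSE]
  out <- array(FALSE, dim = c(h, w, 5))
  for (i in 1:5) out[, , i] <- full
  out
}

#' Count moving cells in a five-frame batch
#'
#' The full image batch analysis: each frame is preprocessed
#' ([preprocessFrame()]), cell and artifact masks are computed
#' ([cellMask()], [artifactMask()]), centroids of the surviving cell
#' components are taken as the unweighted mean of component pixel
#' coordinates (0-based, working resolution), and any centroid whose
#' pixel lies inside that frame's artifact mask is removed. The result
#' is deterministic for fixed input and parameters.
#'
#' @param batch a raw [FrameBatch-class].
#' @param params a [ParameterSet-class]; default [defaultParameters()].
#' @return a [FrameDetections-class].
#' @examples
#' sim <- makeFrameBatch(sceneConfig(trueConcentration = 50, seed = 11))
#' det <- countCells(sim$batch)
#' cellCounts(det)
#' cellCounts(sim$truth)
#' @export
countCells <- function(batch, params = defaultParameters()) {
  checkBatch(batch)
  validObject(params)
  a <- preprocessBatch(batch, params)
  cm <- deviationMasks(
    a, params@cellBatchDiffThreshold, params@cellBlurSigma,
    params@cellMinArea, params@cellMaxArea
  )
  am <- artifactMask(a, params)
  centroids <- vector("list", 5)
  counts <- integer(5)
  for (i in 1:5) {
    lab <- cm$labels[[i]]
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0L) {
      centroids[[i]] <- cbind(x = numeric(0), y = numeric(0))
      counts[i] <- 0L
      next
    }
    idx <- which(lab > 0L)
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    labv <- lab[idx]
    cy <- tapply(rows, labv, mean) - 1   # 0-based
    cx <- tapply(cols, labv, mean) - 1
    keep <- !am[cbind(round(cy) + 1, round(cx) + 1, i)]
    centroids[[i]] <- cbind(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]))
    counts[i] <- sum(keep)
  }
  new("FrameDetections",
    cellMasks = cm$masks, artifactMasks = am,
    centroids = centroids, counts = counts
  )
}
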