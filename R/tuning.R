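#' Paired Wilcoxon signed-rank test
#'
#' Paired differences \code{x - y} are computed, zeros dropped, the
#' absolute differences ranked (average ranks on ties), and the
#' statistic taken as \code{W = min(sum of positive ranks, sum of
#' negative ranks)}. The two-sided p-value uses the normal approximation
#' with continuity correction and tie-corrected variance (the same
#' approximation as \code{stats::wilcox.test(..., paired = TRUE,
#' exact = FALSE, correct = TRUE)}, which supplies the p-value). When
#' every paired difference is zero the test is degenerate and p = 1.
#'
#' @param x,y equal-length numeric vectors (e.g. algorithm and reference
#'   counts of the same images).
#' @return list: \code{statistic} (W), \code{p.value}, \code{degenerate}.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 5), c(1, 3, 2, 9))
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  }
  r <- rank(abs(d))
  wPos <- sum(r[d > 0])
  wNeg <- sum(r[d < 0])
  p <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, exact = FALSE, correct = TRUE,
    alternative = "two.sided"
  ))$p.value
  list(statistic = min(wPos, wNeg), p.value = p, degenerate = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3), neither
#'   constant.
#' @return correlation in \code{[-1, 1]}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("pearsonR needs at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Candidate parameter grid
#'
#' A named list of candidate values per [ParameterSet-class] slot; the
#' search space is their cartesian product. The default grid spans 96
#' combinations (4 cell thresholds x 3 blur sigmas x 4 maximum cell
#' areas x 2 artifact thresholds) around the shipped defaults.
#'
#' @param ... named character-slot overrides, each a vector of candidate
#'   values. Unnamed slots stay at their [defaultParameters()] value.
#' @return list of class \code{parameterGrid} with the per-slot value
#'   lists and the cartesian \code{size}.
#' @examples
#' g <- parameterGrid()
#' g$size  # 96
#' @export
parameterGrid <- function(...) {
  values <- list(...)
  if (length(values) == 0L) {
    values <- list(
      cellBatchDiffThreshold = c(35, 50, 65, 80),
      cellBlurSigma = c(1, 1.5, 2),
      cellMaxArea = c(150, 225, 300, 375),
      artifactBatchDiffThreshold = c(30, 45)
    )
  }
  ok <- slotNames("ParameterSet")
  bad <- setdiff(names(values), ok)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (any(lengths(values) < 1L)) stop("empty candidate list")
  structure(
    list(values = values, size = prod(lengths(values))),
    class = "parameterGrid"
  )
}

#' Grid-search the image batch analysis parameters
#'
#' Runs [countCells()] on every batch for every combination in the grid
#' and scores the per-image algorithm counts against the reference
#' counts: the combination with the \emph{largest} Wilcoxon signed-rank
#' p-value (the least significant difference from the reference) wins,
#' ties broken by largest Pearson correlation, then by smallest mean
#' absolute error. Reference counts may come from a manual rater or from
#' simulator ground truth; the contract is the same.
#'
#' @param batches list of [FrameBatch-class].
#' @param referenceCounts numeric vector of per-image reference counts,
#'   length \code{5 * length(batches)}, in batch-then-frame order.
#' @param grid a [parameterGrid()].
#' @param base a [ParameterSet-class] supplying the slots not searched.
#' @return a [TuningResult-class].
#' @export
gridSearch <- function(batches, referenceCounts, grid = parameterGrid(),
                       base = defaultParameters()) {
  if (length(batches) == 0L) stop("empty image set")
  stopifnot(inherits(grid, "parameterGrid"))
  if (length(referenceCounts) != 5L * length(batches)) {
    stop("need one reference count per image (5 per batch)")
  }
  combos <- expand.grid(grid$values, KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    over <- as.list(combos[ci, , drop = FALSE])
    params <- base
    for (nm in names(over)) {
      slot(params, nm) <- if (is.integer(slot(base, nm))) {
        as.integer(over[[nm]])
      } else {
        as.numeric(over[[nm]])
      }
    }
    validObject(params)
    algo <- unlist(lapply(batches, function(b) {
      cellCounts(countCells(b, params))
    }))
    wt <- wilcoxonSignedRank(algo, referenceCounts)
    r <- if (stats::var(algo) == 0 || stats::var(referenceCounts) == 0) {
      NA_real_
    } else {
      pearsonR(algo, referenceCounts)
    }
    records[[ci]] <- cbind(
      combos[ci, , drop = FALSE],
      data.frame(
        wilcoxon_statistic = wt$statistic,
        wilcoxon_p = wt$p.value,
        pearson_r = r,
        mae = mean(abs(algo - referenceCounts))
      )
    )
  }
  tab <- do.call(rbind, records)
  rownames(tab) <- NULL
  # lexicographic selection: max p, then max r (NA ranks last), min MAE
  rFill <- ifelse(is.na(tab$pearson_r), -Inf, tab$pearson_r)
  best <- order(-tab$wilcoxon_p, -rFill, tab$mae)[1]
  sel <- base
  for (nm in names(grid$values)) {
    slot(sel, nm) <- if (is.integer(slot(base, nm))) {
      as.integer(tab[best, nm])
    } else {
      as.numeric(tab[best, nm])
    }
  }
  new("TuningResult", table = tab, selected = sel)
}
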