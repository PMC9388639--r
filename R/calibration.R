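#' Interquartile-range outlier filter
#'
#' Keeps the middle 50\% of the values by rank: the input is sorted by
#' value (stable on ties, by original order), the lowest
#' \code{ceiling(n/4)} ranks are dropped and the next \code{floor(n/2)}
#' ranks are retained. The rank rule guarantees that 100 per-drain
#' counts always retain exactly 50 and a training aggregate of 1800
#' always retains exactly 900, regardless of ties.
#'
#' @param counts numeric vector, length >= 4.
#' @return the retained values in ascending rank order.
#' @examples
#' iqrFilter(1:8)          # 3 4 5 6
#' length(iqrFilter(rpois(100, 10)))  # 50
#' @export
iqrFilter <- function(counts) {
  n <- length(counts)
  if (n < 4L) stop("iqrFilter needs at least 4 values, got ", n)
  o <- order(counts)  # stable: ties keep original order
  lo <- ceiling(n / 4)
  counts[o[(lo + 1L):(lo + floor(n / 2))]]
}

#' Ordinary least squares calibration line
#'
#' Fits concentration (response) on count (predictor) by least squares.
#'
#' @param counts numeric predictor (per-image cell counts).
#' @param concentrations numeric response (known WBCs/mm^3).
#' @return named numeric: \code{slope}, \code{intercept}.
#' @export
fitOLS <- function(counts, concentrations) {
  if (length(counts) != length(concentrations)) {
    stop("counts and concentrations must have equal length")
  }
  if (length(unique(counts)) < 2L) {
    stop("degenerate design: all counts identical")
  }
  fit <- stats::lm(concentrations ~ counts)
  cf <- stats::coef(fit)
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

## Per-observation inverse-variance weights on the prediction scale:
## observations are grouped by concentration label, the weight of group g
## is 1 / (Var(count | g) * slope^2). Zero-variance groups borrow the
## smallest positive group variance; if every group is degenerate (or the
## slope is 0) the weights are uniform, i.e. the R^2 is unweighted.
predictionWeights <- function(counts, concentrations, slope) {
  groups <- factor(concentrations)
  v <- tapply(counts, groups, function(g) {
    if (length(g) < 2L) return(0) else stats::var(g)
  })
  if (all(v == 0) || slope == 0) {
    return(rep(1, length(counts)))
  }
  v[v == 0] <- min(v[v > 0])
  1 / (v[groups] * slope^2)
}

#' Heteroskedasticity-weighted R-squared
#'
#' \deqn{R^2_w = 1 - \sum_i w_i (y_i - \hat y_i)^2 /
#'              \sum_i w_i (y_i - \bar y_w)^2}
#' with \eqn{w_i} the inverse of the conditional variance of the
#' predicted concentration for observation i's concentration group (the
#' empirical count variance of the group scaled through the squared
#' slope) and \eqn{\bar y_w} the weighted mean of y. Groups with zero
#' count variance are assigned the smallest positive group variance; if
#' all groups are degenerate the unweighted R^2 is returned.
#'
#' @param counts,concentrations paired observations grouped by
#'   concentration label.
#' @param slope,intercept the calibration line evaluated.
#' @return numeric <= 1.
#' @export
weightedR2 <- function(counts, concentrations, slope, intercept) {
  if (length(counts) != length(concentrations)) {
    stop("counts and concentrations must have equal length")
  }
  w <- predictionWeights(counts, concentrations, slope)
  yhat <- slope * counts + intercept
  ybarw <- sum(w * concentrations) / sum(w)
  sst <- sum(w * (concentrations - ybarw)^2)
  sse <- sum(w * (concentrations - yhat)^2)
  if (sst == 0) {
    return(if (sse == 0) 1 else -Inf)
  }
  1 - sse / sst
}

#' Predict a WBC concentration from a cell count
#'
#' Applies the calibration line and clamps negative predictions to zero
#' (a count below the intercept crossing cannot indicate a negative
#' concentration).
#'
#' @param count numeric vector of per-image cell counts.
#' @param model a [CalibrationModel-class], or any list/object with
#'   \code{slope} and \code{intercept}.
#' @return non-negative WBCs/mm^3, same length as \code{count}.
#' @examples
#' m <- list(slope = 10, intercept = -50)
#' predictConcentration(2, m)  # raw -30, clamped to 0
#' @export
predictConcentration <- function(count, model) {
  if (is(model, "CalibrationModel")) {
    s <- model@slope; b <- model@intercept
  } else {
    s <- model$slope; b <- model$intercept
  }
  pmax(0, s * count + b)
}

#' Train the calibration by k-fold cross validation
#'
#' Records (already IQR-filtered per concentration, see [iqrFilter()])
#' are shuffled with \code{seed}, split into k near-equal contiguous
#' folds, and for each fold an OLS line is fitted on the other k - 1
#' folds. Per fold, the slope, intercept, training-set weighted R^2
#' ([weightedR2()]), and zero-clamped test-fold RMSE are recorded. The
#' returned model carries the parameters averaged over the k folds and
#' the standard deviation of each across folds.
#'
#' @param dataset data.frame with columns \code{concentration} and
#'   \code{count} (extra columns ignored).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the shuffle.
#' @return a [CalibrationModel-class].
#' @examples
#' ds <- makeCountDataset(countDatasetConfig(nSamples = 2, seed = 4))
#' filt <- do.call(rbind, lapply(split(ds, ds$concentration), function(g) {
#'   data.frame(concentration = g$concentration[1],
#'              count = iqrFilter(g$count))
#' }))
#' kfoldTrain(filt, k = 10, seed = 1)
#' @export
kfoldTrain <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(
    is.data.frame(dataset),
    all(c("concentration", "count") %in% names(dataset))
  )
  k <- as.integer(k)
  n <- nrow(dataset)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k = ", k, " records, got ", n)
  if (length(unique(dataset$concentration)) < 2L) {
    stop("training needs at least 2 distinct concentrations")
  }
  set.seed(seed)
  perm <- sample.int(n)
  # contiguous near-equal split of the shuffled order
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  foldId <- integer(n)
  foldId[perm] <- rep(seq_len(k), times = sizes)
  rows <- lapply(seq_len(k), function(f) {
    train <- dataset[foldId != f, ]
    test <- dataset[foldId == f, ]
    cf <- fitOLS(train$count, train$concentration)
    r2 <- weightedR2(
      train$count, train$concentration, cf["slope"], cf["intercept"]
    )
    pred <- pmax(0, cf["slope"] * test$count + cf["intercept"])
    rmse <- sqrt(mean((pred - test$concentration)^2))
    data.frame(
      fold = f, slope = cf[["slope"]], intercept = cf[["intercept"]],
      weighted_r2 = r2, test_rmse = rmse, n_test = nrow(test)
    )
  })
  tab <- do.call(rbind, rows)
  sdv <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  new("CalibrationModel",
    slope = mean(tab$slope), intercept = mean(tab$intercept),
    weightedR2 = mean(tab$weighted_r2),
    slopeSD = sdv(tab$slope), interceptSD = sdv(tab$intercept),
    r2SD = sdv(tab$weighted_r2),
    k = k, foldTable = tab, seed = as.integer(seed)
  )
}

#' IQR-filter a training dataset per concentration
#'
#' Convenience for the training path: applies [iqrFilter()] to the
#' aggregate counts of each concentration label (e.g. 18 samples x 100
#' images = 1800 counts reduce to 900 per concentration).
#'
#' @param dataset data.frame with columns \code{concentration, count}.
#' @return data.frame with columns \code{concentration, count}.
#' @export
iqrFilterDataset <- function(dataset) {
  stopifnot(all(c("concentration", "count") %in% names(dataset)))
  parts <- lapply(split(dataset, dataset$concentration), function(g) {
    data.frame(
      concentration = g$concentration[1],
      count = iqrFilter(g$count)
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Mean WBC concentration of one drain
#'
#' The per-drain counts (nominally 100, one per image) are IQR-filtered
#' to their middle 50, each retained count is converted to a
#' concentration with the calibration model (zero-clamped), and the
#' retained concentrations are averaged.
#'
#' @param counts integer vector of per-image cell counts for one drain
#'   (length >= 4).
#' @param model a [CalibrationModel-class] (or slope/intercept list).
#' @return list with \code{mean} (WBCs/mm^3) and \code{concentrations}
#'   (the retained per-image concentrations).
#' @examples
#' m <- list(slope = 10, intercept = 0)
#' drainConcentration(1:8, m)$mean  # retained 3,4,5,6 -> mean 45
#' @export
drainConcentration <- function(counts, model) {
  kept <- iqrFilter(counts)
  conc <- predictConcentration(kept, model)
  list(mean = mean(conc), concentrations = conc)
}
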