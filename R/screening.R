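zoneRecommendation <- c(
  healthy = "No follow-up needed; continue performing PD as usual.",
  caution = paste(
    "Monitor symptoms closely and contact your care team if the",
    "concentration stays in this range for more than a few days."
  ),
  risk = paste(
    "Contact your care team immediately for follow-up diagnostic",
    "testing."
  )
)

#' Classify a mean WBC concentration into a screening zone
#'
#' Healthy on \code{[0, 50)}, caution on \code{[50, 100)}, risk on
#' \code{[100, Inf)} WBCs/mm^3. The boundary at exactly 50 belongs to
#' the caution zone - 50 is the threshold at which screening turns
#' positive - and exactly 100 is at risk.
#'
#' @param meanConcentration WBCs/mm^3, >= 0 (vectorised).
#' @return ordered factor with levels healthy < caution < risk.
#' @examples
#' classifyZone(c(25, 50, 99.9, 100))
#' @export
classifyZone <- function(meanConcentration) {
  if (any(meanConcentration < 0)) {
    stop("concentration must be >= 0 (predictions are zero-clamped)")
  }
  z <- cut(meanConcentration,
    breaks = c(-Inf, 50, 100, Inf),
    labels = c("healthy", "caution", "risk"),
    right = FALSE
  )
  factor(z, levels = c("healthy", "caution", "risk"), ordered = TRUE)
}

#' Summarise a PD session from its per-drain mean concentrations
#'
#' The session mean is the arithmetic mean of the drain means; the zone
#' and patient-facing recommendation follow from [classifyZone()] on the
#' session mean.
#'
#' @param drainMeans numeric vector of per-drain mean WBC concentrations
#'   (>= 1 drain).
#' @return a [SessionReport-class].
#' @examples
#' sessionReport(c(40, 60))
#' @export
sessionReport <- function(drainMeans) {
  if (length(drainMeans) < 1L) stop("need at least one drain mean")
  if (any(!is.finite(drainMeans))) stop("drain means must be finite")
  m <- mean(drainMeans)
  zone <- as.character(classifyZone(m))
  new("SessionReport",
    drainMeans = drainMeans,
    sessionMean = m,
    sessionMin = min(drainMeans),
    sessionMax = max(drainMeans),
    zone = zone,
    recommendation = unname(zoneRecommendation[zone])
  )
}

#' Render a session report as the end-of-session text block
#'
#' @param report a [SessionReport-class].
#' @return a single string.
#' @export
formatSessionReport <- function(report) {
  sprintf(
    paste0(
      "PD session screening report\n",
      "  drains analysed : %d\n",
      "  mean WBC conc.  : %.1f WBCs/mm^3\n",
      "  min / max drain : %.1f / %.1f WBCs/mm^3\n",
      "  zone            : %s\n",
      "  recommendation  : %s\n"
    ),
    length(report@drainMeans), report@sessionMean,
    report@sessionMin, report@sessionMax,
    toupper(report@zone), report@recommendation
  )
}

#' Binary infection-concern call
#'
#' Positive when the session mean is at or above the threshold
#' (default 50 WBCs/mm^3, the screening cutoff chosen to prioritise
#' sensitivity).
#'
#' @param sessionMean WBCs/mm^3 (vectorised), >= 0.
#' @param threshold WBCs/mm^3.
#' @return character vector, \code{"positive"} or \code{"negative"}.
#' @examples
#' binaryClassify(c(49.9, 50))
#' @export
binaryClassify <- function(sessionMean, threshold = 50) {
  if (any(sessionMean < 0)) stop("sessionMean must be >= 0")
  ifelse(sessionMean >= threshold, "positive", "negative")
}

normalizeLabels <- function(labels) {
  if (is.logical(labels)) {
    return(ifelse(labels, "positive", "negative"))
  }
  l <- tolower(as.character(labels))
  if (!all(l %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative' (or logical)")
  }
  l
}

#' Area under the ROC curve of concentration predictions
#'
#' The ROC is traced by applying "positive iff prediction >= t" for
#' every distinct prediction value (plus below-minimum and above-maximum
#' anchors) and integrating the (FPR, TPR) polyline with the trapezoid
#' rule; this equals the probability that a random positive outranks a
#' random negative, counting ties as one half.
#'
#' @param predictions numeric scores (predicted WBCs/mm^3).
#' @param labels \code{"positive"}/\code{"negative"} (or logical), same
#'   length.
#' @return numeric in \code{[0, 1]}.
#' @export
auroc <- function(predictions, labels) {
  labels <- normalizeLabels(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  pos <- labels == "positive"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) {
    stop("auroc needs at least one positive and one negative label")
  }
  thresholds <- c(sort(unique(predictions)), max(predictions) + 1)
  tpr <- vapply(thresholds, function(t) sum(predictions[pos] >= t) / nP,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(predictions[!pos] >= t) / nN,
                numeric(1))
  # anchor at (1, 1): threshold below every prediction
  fpr <- c(1, fpr); tpr <- c(1, tpr)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate binary screening against known labels
#'
#' Applies [binaryClassify()] at \code{threshold} to each predicted
#' concentration and tabulates the confusion matrix against the given
#' labels. Sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) are
#' \code{NA} when their denominator is zero. AUROC is computed when both
#' classes are present.
#'
#' @param predictions predicted mean WBC concentrations, one per sample.
#' @param labels true \code{"positive"}/\code{"negative"} labels.
#' @param threshold screening cutoff, WBCs/mm^3 (default 50).
#' @return a [ScreeningEvaluation-class].
#' @examples
#' evaluateScreening(c(10, 60, 70, 20),
#'                   c("negative", "positive", "negative", "negative"))
#' @export
evaluateScreening <- function(predictions, labels, threshold = 50) {
  if (length(predictions) == 0L) stop("empty evaluation set")
  labels <- normalizeLabels(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  calls <- binaryClassify(predictions, threshold)
  tp <- sum(calls == "positive" & labels == "positive")
  fp <- sum(calls == "positive" & labels == "negative")
  tn <- sum(calls == "negative" & labels == "negative")
  fn <- sum(calls == "negative" & labels == "positive")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if ((tp + fn) > 0 && (tn + fp) > 0) {
    auroc(predictions, labels)
  } else {
    NA_real_
  }
  new("ScreeningEvaluation",
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec,
    auroc = auc, threshold = threshold
  )
}
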