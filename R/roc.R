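#' ROC curve by threshold sweep
#'
#' A sample is called positive when its score is at or above the threshold;
#' the sweep visits every unique score (equal scores collapse into one
#' threshold) plus the two degenerate endpoints. AUC is the trapezoidal
#' area under the (1 - specificity, sensitivity) curve, which equals the
#' Mann-Whitney U statistic of the positive-class scores divided by
#' `n1 * n0`.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Binary 0/1 vector (both classes present).
#' @return List of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must be binary with both classes present")
  }
  stopifnot(length(scores) == length(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(th) mean(scores[labels == 1] >= th), 0)
  spec <- vapply(thr, function(th) mean(scores[labels == 0] < th), 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' @param scores Numeric scores; positive call is `score >= cutoff`.
#' @param labels Binary 0/1 vector (both classes present).
#' @param cutoff Finite decision threshold.
#' @return List with `sensitivity` and `specificity`.
#' @export
classify_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  list(sensitivity = mean(scores[labels == 1] >= cutoff),
       specificity = mean(scores[labels == 0] < cutoff))
}

#' Cutoff maximizing Youden's J
#'
#' Scans the finite thresholds of the ROC sweep and returns the one
#' maximizing `J = sensitivity + specificity - 1`; ties are broken in
#' favour of higher sensitivity, then the lower threshold.
#'
#' @inheritParams classify_at_cutoff
#' @return List with `cutoff`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(scores, labels) {
  rc <- roc(scores, labels)
  finite <- is.finite(rc$thresholds)
  thr <- rc$thresholds[finite]
  sens <- rc$sensitivity[finite]
  spec <- rc$specificity[finite]
  J <- sens + spec - 1
  ord <- order(-J, -sens, thr)
  i <- ord[1]
  list(cutoff = thr[i], sensitivity = sens[i], specificity = spec[i],
       J = J[i])
}
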