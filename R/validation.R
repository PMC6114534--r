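#' Match detections to ground truth by bounding-box overlap
#'
#' Greedy matching by descending intersection-over-union (ties broken by
#' lower detection index, then lower truth index). The first detection
#' matched to a truth box is its correct positive; every further detection
#' overlapping an already-matched truth box counts as a double detection;
#' detections overlapping no truth box are false positives; unmatched truth
#' boxes are false negatives. Rates: correct positive and false negative
#' rates are per truth box (they sum to one), the double detection rate is
#' doubles per truth box, the false positive rate is false positives per
#' detection, and precision is matched detections over all detections.
#'
#' @param detections,truth data.frames with half-open boxes `bbox_r0`,
#'   `bbox_c0`, `bbox_r1`, `bbox_c1` (one row per box, same frame).
#' @param minOverlap IoU acceptance threshold (default 0.25).
#' @return a [MatchReport-class]. With empty truth and empty detections all
#'   rates are 0 except precision = 1 by convention, and the report is
#'   flagged degenerate.
#' @export
matchDetections <- function(detections, truth, minOverlap = 0.25) {
  boxes <- function(df) {
    if (!nrow(df)) return(matrix(numeric(), 0, 4))
    as.matrix(df[, c("bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1")])
  }
  D <- boxes(detections); TT <- boxes(truth)
  nD <- nrow(D); nT <- nrow(TT)
  emptyPairs <- data.frame(detection = integer(), truth = integer(),
                           iou = numeric(), type = character())
  if (nD == 0L && nT == 0L) {
    return(new("MatchReport", pairs = emptyPairs,
               rates = c(correct_positive_rate = 0, false_positive_rate = 0,
                         false_negative_rate = 0, double_detection_rate = 0,
                         precision = 1),
               counts = c(n_truth = 0, n_detections = 0, n_matched = 0,
                          n_false_positive = 0, n_double = 0),
               minOverlap = minOverlap, degenerate = TRUE))
  }
  ious <- matrix(0, nD, nT)
  if (nD && nT)
    for (i in seq_len(nD)) for (j in seq_len(nT))
      ious[i, j] <- boxIoU(D[i, ], TT[j, ])
  cand <- which(ious >= minOverlap & ious > 0, arr.ind = TRUE)
  pairs <- emptyPairs
  matchedT <- logical(nT); usedD <- logical(nD)
  doubles <- 0L
  if (length(cand)) {
    ord <- order(-ious[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (usedD[i]) next
      usedD[i] <- TRUE
      if (!matchedT[j]) {
        matchedT[j] <- TRUE
        pairs <- rbind(pairs, data.frame(detection = i, truth = j,
                                         iou = ious[i, j], type = "correct"))
      } else {
        doubles <- doubles + 1L
        pairs <- rbind(pairs, data.frame(detection = i, truth = j,
                                         iou = ious[i, j], type = "double"))
      }
    }
  }
  nMatched <- sum(matchedT)
  nFP <- nD - sum(usedD)
  rates <- c(
    correct_positive_rate = if (nT) nMatched / nT else 0,
    false_positive_rate = if (nD) nFP / nD else 0,
    false_negative_rate = if (nT) 1 - nMatched / nT else 0,
    double_detection_rate = if (nT) doubles / nT else 0,
    precision = if (nD) nMatched / nD else 1)
  new("MatchReport", pairs = pairs, rates = rates,
      counts = c(n_truth = nT, n_detections = nD, n_matched = nMatched,
                 n_false_positive = nFP, n_double = doubles),
      minOverlap = minOverlap, degenerate = FALSE)
}

#' Concordance of detected and true bud counts per core
#'
#' Ordinary least-squares regression of the detected counts on the truth.
#'
#' @param detected,truth numeric vectors (>= 3 cores).
#' @return list with `r_squared`, `slope`, `intercept` and `flagged`
#'   (TRUE with an `NA` R-squared when the truth has zero variance).
#' @export
countConcordance <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  if (length(truth) < 3L) stop("need at least three cores")
  if (stats::var(truth) == 0) {
    warning("zero variance in the truth counts; R-squared undefined")
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = mean(detected), flagged = TRUE))
  }
  fit <- stats::lm(detected ~ truth)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), flagged = FALSE)
}

#' Concordance of detected and true budding grades
#'
#' @param detected,truth integer grade vectors.
#' @return list with `accuracy` (exact agreement) and `r_squared` (OLS,
#'   `NA` when the truth grades have zero variance).
#' @export
gradeConcordance <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  acc <- mean(detected == truth)
  r2 <- if (length(truth) >= 3L && stats::var(truth) > 0)
    summary(stats::lm(detected ~ truth))$r.squared else NA_real_
  list(accuracy = acc, r_squared = r2)
}
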