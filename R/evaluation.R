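# Evaluation statistics: pixel-wise confusion counts and the derived
# sensitivity/specificity/accuracy, scanning-plane and target-point errors,
# tracked-stream stability, boxplot five-number summaries with Tukey
# outliers, and plain mean errors.

#' Pixel-wise confusion counts between two binary masks
#'
#' @param predicted,label binary arrays of identical shape.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, label) {
  if (!identical(dim2(predicted), dim2(label))) {
    stop("incompatible masks: shapes differ")
  }
  p <- as.vector(predicted); g <- as.vector(label)
  if (!all(p %in% c(0, 1, TRUE, FALSE)) || !all(g %in% c(0, 1, TRUE, FALSE))) {
    stop("masks must be binary")
  }
  p <- p != 0; g <- g != 0
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, each expressed as a
#' percentage. A metric with zero denominator is undefined and reported as
#' `NA`, never as 0, so averages cannot be silently biased.
#'
#' @param counts a [confusion_counts()] result (or a list with `TP`, `TN`,
#'   `FP`, `FN`).
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`
#'   in percent.
#' @examples
#' pixel_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
#' @export
pixel_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn))
}

#' Automatic-scanning plane error
#'
#' Physical distance between the predicted axis plane (the slice index the
#' system selected) and the actual axis plane (the slice containing the
#' marked target): `|predicted - actual| * thickness`.
#'
#' @param predicted_index,actual_index 1-based slice indices.
#' @param thickness_mm slice thickness on the stacking axis (mm).
#' @return Error in mm.
#' @export
scanning_plane_error <- function(predicted_index, actual_index, thickness_mm) {
  stopifnot(all(predicted_index >= 1), all(actual_index >= 1),
            thickness_mm >= 0)
  abs(predicted_index - actual_index) * thickness_mm
}

#' Target point error
#'
#' Euclidean distance between the real and virtual target points.
#'
#' @param real_target,virtual_target length-3 points (mm).
#' @return Distance in mm.
#' @export
target_point_error <- function(real_target, virtual_target) {
  a <- as.numeric(real_target); b <- as.numeric(virtual_target)
  stopifnot(length(a) == 3L, length(b) == 3L)
  sqrt(sum((a - b)^2))
}

#' Stability statistics of a tracked pose stream
#'
#' Positions are centred on their mean (the "normalization" step); each
#' sample's deviation is its Euclidean distance from that mean. Returns the
#' mean and standard deviation of the deviations, plus the raw per-axis
#' standard deviations for transparency.
#'
#' @param stream a `pose_stream` (columns `x`, `y`, `z`; >= 2 samples).
#' @return List: `mean_deviation_mm`, `sd_deviation_mm`, `per_axis_sd_mm`.
#' @export
stability_stats <- function(stream) {
  pos <- as.matrix(stream[, c("x", "y", "z")])
  if (nrow(pos) < 2L) stop("insufficient samples: need at least 2")
  centered <- sweep(pos, 2, colMeans(pos))
  dev <- sqrt(rowSums(centered^2))
  list(mean_deviation_mm = mean(dev),
       sd_deviation_mm = sd(dev),
       per_axis_sd_mm = apply(pos, 2, sd))
}

#' Boxplot five-number summary with Tukey outliers
#'
#' Quartiles use linear interpolation between order statistics; outliers
#' are points beyond `Q1 - 1.5 IQR` or `Q3 + 1.5 IQR`. The mean and SD are
#' included alongside the five-number summary.
#'
#' @param errors non-empty numeric vector (mm).
#' @return A `boxplot_summary` list: `minimum`, `lower_quartile`, `median`,
#'   `upper_quartile`, `maximum`, `outliers`, `mean`, `sd`.
#' @export
boxplot_summary <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("no data")
  q <- unname(quantile(errors, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  out <- errors[errors < q[1] - 1.5 * iqr | errors > q[3] + 1.5 * iqr]
  structure(list(minimum = min(errors), lower_quartile = q[1],
                 median = q[2], upper_quartile = q[3],
                 maximum = max(errors), outliers = out,
                 mean = mean(errors),
                 sd = if (length(errors) > 1L) sd(errors) else 0),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "<boxplot_summary> min %.3f | Q1 %.3f | med %.3f | Q3 %.3f | max %.3f (mean %.3f, sd %.3f, %d outliers)\n",
    x$minimum, x$lower_quartile, x$median, x$upper_quartile, x$maximum,
    x$mean, x$sd, length(x$outliers)))
  invisible(x)
}

#' Mean error
#'
#' Arithmetic mean of a non-empty error list, e.g. the per-experimenter
#' insertion errors of a phantom accuracy study.
#'
#' @param errors non-empty numeric vector (mm).
#' @return Mean in mm.
#' @examples
#' mean_error(c(5, 3, 7, 2, 13))
#' @export
mean_error <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("no data")
  mean(errors)
}
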