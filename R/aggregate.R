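# Fold-ensemble averaging, hierarchical patch -> image -> patient
# aggregation, confusion-matrix metrics, percentile bootstrap confidence
# intervals, and the paired fold comparison.

.check_prob_table <- function(tab) {
  req <- c("patient_id", "image_id", "patch_index", "p_benign", "p_malignant")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("probability table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  s <- tab$p_benign + tab$p_malignant
  if (any(tab$p_benign < 0 | tab$p_malignant < 0) ||
      any(abs(s - 1) > 1e-6))
    stop("probability rows must be non-negative and sum to 1", call. = FALSE)
  invisible(tab)
}

.key <- function(tab) paste(tab$patient_id, tab$image_id, tab$patch_index,
                            sep = "\r")

#' Average probability tables across fold models
#'
#' Per-key arithmetic mean of the class probabilities predicted by the K
#' fold models of the cross-validation ensemble. All tables must cover
#' exactly the same (patient, image, patch) keys.
#'
#' @param tables List of `prob_table` data frames over identical keys.
#' @return One averaged `prob_table`.
#' @export
ensemble_average <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (t in tables) .check_prob_table(t)
  ref <- tables[[1]]
  ref <- ref[order(.key(ref)), ]
  kref <- .key(ref)
  pb <- matrix(NA_real_, nrow(ref), length(tables))
  pm <- matrix(NA_real_, nrow(ref), length(tables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (nrow(t) != nrow(ref)) stop("table ", i, " has a different key set",
                                   call. = FALSE)
    t <- t[order(.key(t)), ]
    if (!identical(.key(t), kref))
      stop("table ", i, " has a different key set", call. = FALSE)
    pb[, i] <- t$p_benign
    pm[, i] <- t$p_malignant
  }
  out <- ref
  out$p_benign <- rowMeans(pb)
  out$p_malignant <- rowMeans(pm)
  rownames(out) <- NULL
  class(out) <- unique(c("prob_table", class(out)))
  out
}

#' Aggregate patch probabilities to image predictions
#'
#' One prediction per image: the mean of the probability vectors of its
#' patches, labelled by the maximum class probability (ties go to
#' malignant).
#'
#' @param table A `prob_table`.
#' @return Data frame with `patient_id`, `image_id`, `p_benign`,
#'   `p_malignant`, `n_patches`, `label_pred`.
#' @export
aggregate_image <- function(table) {
  .check_prob_table(table)
  if (nrow(table) == 0L) stop("no patch rows to aggregate", call. = FALSE)
  ag <- stats::aggregate(cbind(p_benign, p_malignant) ~ patient_id + image_id,
                         data = table, FUN = mean)
  cnt <- stats::aggregate(patch_index ~ patient_id + image_id, data = table,
                          FUN = length)
  names(cnt)[3] <- "n_patches"
  out <- merge(ag, cnt, by = c("patient_id", "image_id"))
  out$label_pred <- ifelse(out$p_malignant >= out$p_benign,
                           "malignant", "benign")
  out[order(out$patient_id, out$image_id), ]
}

#' Aggregate image predictions to patient predictions
#'
#' One prediction per patient: the mean of the probability vectors of their
#' images, labelled malignant iff the malignant probability reaches the 0.5
#' decision threshold (the boundary goes to malignant, favouring
#' sensitivity).
#'
#' @param images Image predictions from [aggregate_image()].
#' @return Data frame with `patient_id`, `p_benign`, `p_malignant`,
#'   `n_images`, `label_pred`.
#' @export
aggregate_patient <- function(images) {
  stopifnot(all(c("patient_id", "p_benign", "p_malignant") %in% names(images)))
  if (nrow(images) == 0L) stop("no image rows to aggregate", call. = FALSE)
  ag <- stats::aggregate(cbind(p_benign, p_malignant) ~ patient_id,
                         data = images, FUN = mean)
  cnt <- stats::aggregate(image_id ~ patient_id, data = images, FUN = length)
  names(cnt)[2] <- "n_images"
  out <- merge(ag, cnt, by = "patient_id")
  out$label_pred <- ifelse(out$p_malignant >= 0.5, "malignant", "benign")
  out[order(out$patient_id), ]
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from the
#' four confusion counts, with malignant as the positive class. A metric
#' whose denominator is zero is reported as `NA` (an explicit undefined
#' marker), never silently as 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return An object of class `metrics_report`: list with the counts and
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`.
#' @examples
#' confusion_metrics(17, 1, 0, 7)  # accuracy 0.96, F1 0.9714
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative",
                            call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / total,
                 precision = precision, recall = recall,
                 specificity = sdiv(tn, tn + fp), f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: acc %.4f | prec %s | rec %s | spec %s | f1 %s (tp %d fp %d fn %d tn %d)\n",
    x$accuracy, format(round(x$precision, 4)), format(round(x$recall, 4)),
    format(round(x$specificity, 4)), format(round(x$f1, 4)),
    x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Percentile bootstrap confidence interval for accuracy
#'
#' Resamples the per-patient correctness indicators with replacement at
#' patient granularity and returns the percentile-method interval of the
#' resampled accuracies.
#'
#' @param correct Binary (0/1 or logical) vector, one entry per patient.
#' @param iterations Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling draws.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(correct, iterations = 1000L, level = 0.95,
                         seed = 1L) {
  correct <- as.numeric(correct)
  n <- length(correct)
  if (n < 2L) stop("need at least 2 patients for a bootstrap interval",
                   call. = FALSE)
  set.seed(seed)
  draws <- matrix(correct[sample.int(n, n * iterations, replace = TRUE)],
                  nrow = iterations)
  acc <- rowMeans(draws)
  a <- (1 - level) / 2
  q <- stats::quantile(acc, c(a, 1 - a), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Paired comparison of per-fold metrics
#'
#' Standard paired t-test on the per-fold differences of a metric between
#' two models. Zero-variance differences are flagged as degenerate rather
#' than producing an error or an infinite statistic.
#'
#' @param metric_a,metric_b Numeric vectors of equal length (one value per
#'   fold).
#' @return List with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_fold_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("metric vectors must have equal length", call. = FALSE)
  if (length(metric_a) < 2L)
    stop("need at least 2 folds", call. = FALSE)
  d <- metric_a - metric_b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d),
                degenerate = TRUE))
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}

#' Evaluate patient predictions against truth
#'
#' Builds the confusion counts of patient-level predictions, computes the
#' metrics and attaches the percentile bootstrap interval on accuracy.
#'
#' @param patients Patient predictions from [aggregate_patient()].
#' @param truth Data frame with `patient_id` and true `label`.
#' @param iterations,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return A `metrics_report` with `ci_low`, `ci_high`, `ci_seed` added.
#' @export
evaluate_patients <- function(patients, truth, iterations = 1000L,
                              level = 0.95, seed = 1L) {
  m <- merge(patients, unique(truth[, c("patient_id", "label")]),
             by = "patient_id")
  tp <- sum(m$label == "malignant" & m$label_pred == "malignant")
  fp <- sum(m$label == "benign" & m$label_pred == "malignant")
  fn <- sum(m$label == "malignant" & m$label_pred == "benign")
  tn <- sum(m$label == "benign" & m$label_pred == "benign")
  rep <- confusion_metrics(tp, fp, fn, tn)
  ci <- bootstrap_ci(as.numeric(m$label == m$label_pred), iterations, level,
                     seed)
  rep$ci_low <- ci[["low"]]
  rep$ci_high <- ci[["high"]]
  rep$ci_seed <- seed
  rep
}
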