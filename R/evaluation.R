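# Pixel-level segmentation metrics. Clean is the positive class throughout,
# matching the white-equals-clean mask convention. Metrics whose defining
# ratio is 0/0 are reported as NA ("undefined") and excluded from aggregation
# rather than coerced to 0 or 1.

METRIC_NAMES <- c(
  "accuracy", "precision", "specificity", "sensitivity",
  "auroc", "dsc", "iou", "clean_fraction_pred", "clean_fraction_gt"
)

#' Pixel confusion counts
#'
#' @param pred,gt predicted and ground-truth [binary_mask]s of equal shape
#'   (`TRUE` = clean, the positive class).
#' @param fov optional logical FOV matrix restricting the counted pixels.
#' @return a named list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt, fov = NULL) {
  if (!all(dim(pred) == dim(gt))) {
    stopf("prediction and ground truth have different shapes")
  }
  f <- resolve_fov(fov, nrow(gt), ncol(gt))
  p <- pred[f]
  g <- gt[f]
  list(
    tp = sum(p & g), fp = sum(p & !g),
    fn = sum(!p & g), tn = sum(!p & !g)
  )
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy, precision (positive predictive value), specificity
#' (true negative rate), sensitivity (recall of the clean class), Dice
#' similarity coefficient (pixel F1) and intersection-over-union. Any metric
#' whose denominator is zero is returned as `NA`.
#'
#' @param counts a list with `tp`, `fp`, `fn`, `tn` as from
#'   [confusion_counts()].
#' @return a named numeric vector of the six metrics.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  if (min(tp, fp, fn, tn) < 0) stopf("confusion counts must be non-negative")
  c(
    accuracy = safe_ratio(tp + tn, tp + fp + fn + tn),
    precision = safe_ratio(tp, tp + fp),
    specificity = safe_ratio(tn, tn + fp),
    sensitivity = safe_ratio(tp, tp + fn),
    dsc = safe_ratio(2 * tp, 2 * tp + fp + fn),
    iou = safe_ratio(tp, tp + fp + fn)
  )
}

#' Area under the ROC curve of the clean-class posterior
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling: the probability
#' that a randomly chosen clean pixel receives a higher posterior than a
#' randomly chosen contaminated one, counting ties as one half.
#'
#' @param p_clean numeric matrix (or vector) of clean-class posterior
#'   probabilities.
#' @param gt ground-truth [binary_mask] (or logical vector) of the same shape.
#' @param fov optional logical FOV matrix.
#' @return AUROC in `[0, 1]`, or `NA` if the ground truth is single-class.
#' @export
auroc <- function(p_clean, gt, fov = NULL) {
  if (is.matrix(p_clean)) {
    if (!all(dim(p_clean) == dim(gt))) stopf("p_clean and gt shapes differ")
    f <- resolve_fov(fov, nrow(gt), ncol(gt))
    p <- p_clean[f]
    g <- gt[f]
  } else {
    if (length(p_clean) != length(gt)) stopf("p_clean and gt lengths differ")
    p <- as.double(p_clean)
    g <- as.logical(gt)
  }
  n_pos <- sum(g)
  n_neg <- sum(!g)
  if (n_pos == 0 || n_neg == 0) {
    return(NA_real_)
  }
  r <- rank(p) # midranks for ties
  (sum(r[g]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' All per-image metrics for one prediction
#'
#' @param pred predicted [binary_mask].
#' @param p_clean clean-class posterior matrix (from [gbc_segment()]); pass
#'   `NULL` to skip AUROC.
#' @param gt ground-truth [binary_mask].
#' @param fov optional logical FOV matrix.
#' @return a one-row data.frame with columns `accuracy`, `precision`,
#'   `specificity`, `sensitivity`, `auroc`, `dsc`, `iou`,
#'   `clean_fraction_pred`, `clean_fraction_gt`.
#' @export
segmentation_metrics <- function(pred, p_clean, gt, fov = NULL) {
  m <- metrics_from_confusion(confusion_counts(pred, gt, fov))
  a <- if (is.null(p_clean)) NA_real_ else auroc(p_clean, gt, fov)
  out <- as.data.frame(as.list(m))
  out$auroc <- a
  out$clean_fraction_pred <- clean_fraction(pred, fov)
  out$clean_fraction_gt <- clean_fraction(gt, fov)
  out[, METRIC_NAMES]
}

#' Segment and score a set of annotated frames
#'
#' @param model a `"gbc_model"`.
#' @param images list of [rgb_image]s.
#' @param masks list of paired ground-truth [binary_mask]s.
#' @param fov optional logical FOV matrix applied to every frame.
#' @return a data.frame with one row of [segmentation_metrics()] per frame.
#' @export
evaluate_images <- function(model, images, masks, fov = NULL) {
  if (length(images) != length(masks)) stopf("images and masks differ in length")
  rows <- lapply(seq_along(images), function(i) {
    check_pair(as_rgb_image(images[[i]]), masks[[i]])
    seg <- gbc_segment(images[[i]], model, fov)
    segmentation_metrics(seg$mask, seg$p_clean, masks[[i]], fov)
  })
  do.call(rbind, rows)
}

#' Aggregate per-image metrics into a trial report
#'
#' Mean and sample (n-1) standard deviation of every metric over the images
#' on which it is defined; undefined (NA) values are excluded and their count
#' reported.
#'
#' @param per_image data.frame of per-image metrics ([evaluate_images()]).
#' @param seed optional trial seed recorded as metadata.
#' @param dataset optional dataset identifier recorded as metadata.
#' @return an object of class `"trial_report"`: list with `per_image`,
#'   `mean`, `sd`, `n_undefined`, `n_images`, `seed`, `dataset`.
#' @export
aggregate_metrics <- function(per_image, seed = NA_integer_, dataset = NA_character_) {
  if (!is.data.frame(per_image) || nrow(per_image) == 0) {
    stopf("per_image must be a non-empty data.frame of metrics")
  }
  cols <- intersect(METRIC_NAMES, names(per_image))
  structure(
    list(
      per_image = per_image,
      mean = vapply(per_image[cols], mean, double(1), na.rm = TRUE),
      sd = vapply(per_image[cols], stats::sd, double(1), na.rm = TRUE),
      n_undefined = vapply(per_image[cols], function(v) sum(is.na(v)), integer(1)),
      n_images = nrow(per_image),
      seed = seed, dataset = dataset
    ),
    class = "trial_report"
  )
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %d images\n", x$n_images))
  for (m in names(x$mean)) {
    cat(sprintf(
      "  %-20s %.4f +/- %.4f%s\n", m, x$mean[m], x$sd[m],
      if (x$n_undefined[m] > 0) sprintf("  (%d undefined)", x$n_undefined[m]) else ""
    ))
  }
  invisible(x)
}

#' Clean-fraction agreement between prediction and annotation
#'
#' Pearson correlation of predicted versus ground-truth clean-pixel fractions
#' across frames — the inter-observer agreement statistic for visualization-
#' quality scoring.
#'
#' @param pred_fraction,gt_fraction numeric vectors of per-frame clean
#'   fractions (at least 3 frames).
#' @return Pearson's r, or `NA` with a warning if either input is constant.
#' @export
clean_fraction_correlation <- function(pred_fraction, gt_fraction) {
  if (length(pred_fraction) != length(gt_fraction)) stopf("input lengths differ")
  if (length(pred_fraction) < 3) stopf("need at least 3 frame pairs")
  if (stats::sd(pred_fraction) == 0 || stats::sd(gt_fraction) == 0) {
    warning("clean fractions are constant; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred_fraction, gt_fraction)
}

#' Repeated fit/evaluate trials over a corpus
#'
#' Runs the full selection-and-evaluation protocol `n_trials` times: each
#' round re-clusters the corpus by CIELAB histogram features with a fresh
#' derived seed, selects one representative frame per cluster, fits the
#' classifier on those `k` frames, segments the remaining frames and
#' aggregates their metrics. With the same master seed the reports are
#' reproduced exactly.
#'
#' @param images list of [rgb_image]s (at least `k`).
#' @param masks list of paired ground-truth [binary_mask]s.
#' @param n_trials number of repeated rounds (default 5).
#' @param k number of clusters / fitting frames per round (default 20).
#' @param bins_per_channel histogram bins per Lab channel (default 8).
#' @param seed master integer seed; per-round seeds are derived from it.
#' @param fov optional logical FOV matrix applied everywhere.
#' @param epsilon covariance ridge passed to [gbc_fit()].
#' @return a list of `n_trials` `"trial_report"` objects; each carries the
#'   selected fitting indices as attribute `"fit_indices"`.
#' @export
run_trials <- function(images, masks, n_trials = 5, k = 20, bins_per_channel = 8,
                       seed = 1L, fov = NULL, epsilon = 1e-3) {
  if (length(images) != length(masks)) stopf("images and masks differ in length")
  if (length(images) < k + 1) stopf("need more than k = %d frames", k)
  features <- lapply(images, frame_feature,
    bins_per_channel = bins_per_channel, fov = fov
  )
  lapply(seq_len(n_trials), function(t) {
    st <- derive_seed(seed, t)
    assignment <- cluster_frames(features, k = k, seed = st)
    fit_idx <- select_representatives(assignment, seed = derive_seed(st, 1L))
    eval_idx <- setdiff(seq_along(images), fit_idx)
    model <- gbc_fit(images[fit_idx], masks[fit_idx], epsilon = epsilon, fov = fov)
    report <- aggregate_metrics(
      evaluate_images(model, images[eval_idx], masks[eval_idx], fov),
      seed = st
    )
    attr(report, "fit_indices") <- fit_idx
    report
  })
}
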