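#' Pixelwise metrics over a probability-threshold sweep
#'
#' Binarizes a model's probability map at ten equally spaced probability
#' thresholds (bin centres 0.05, 0.15, ..., 0.95 by default, avoiding the
#' degenerate endpoints 0 and 1) and computes Dice and HD95 against the
#' ground truth at each threshold. HD95 is `NA` when either mask is empty
#' at a threshold.
#'
#' @param pred a `probability_map`.
#' @param gt a `binary_mask` on the same geometry.
#' @param thresholds numeric vector of probability thresholds.
#' @return data frame with columns `threshold`, `dice`, `hd95_mm`.
#' @export
threshold_sweep <- function(pred, gt, thresholds = seq(0.05, 0.95, by = 0.1)) {
  stop_if_geometry_mismatch(pred, gt)
  rows <- lapply(thresholds, function(pt) {
    bin <- binarize(pred, pt)
    data.frame(threshold = pt, dice = dice(bin, gt), hd95_mm = hd95(bin, gt))
  })
  do.call(rbind, rows)
}

#' Patientwise detection metrics
#'
#' Object-level evaluation of one predicted segmentation against one
#' ground truth. Connected components (26-connectivity) smaller than
#' `min_voxels` (50) are discarded on both sides. Ground-truth tumors are
#' paired to overlapping predicted components greedily by descending
#' intersection size (one-to-one; ties broken by component label order).
#' A ground-truth tumor is a true positive iff its pairing Dice reaches
#' `dice_threshold` (0.25). Predicted components left unpaired are false
#' positives.
#'
#' @param pred,gt `binary_mask` objects on the same geometry.
#' @param dice_threshold patient-level Dice score threshold (default 0.25).
#' @param min_voxels minimum object size kept, voxels (default 50).
#' @param connectivity component connectivity (default 26).
#' @return an object of class `patientwise_result`: list with `n_gt`,
#'   `n_pred`, `tp` (logical per gt tumor), `fp_count`, `recall`,
#'   `precision`, `f1`, `fppp`, `dice_tp` (mean Dice over detected
#'   tumors; `NA` if none) and the pairing table `pairs`.
#' @export
patientwise_detection <- function(pred, gt, dice_threshold = 0.25,
                                  min_voxels = 50, connectivity = 26) {
  stop_if_geometry_mismatch(pred, gt)
  keep_big <- function(mask) {
    comps <- connected_components(mask, connectivity)
    keep <- which(comps$sizes >= min_voxels)
    list(labels = array(ifelse(comps$labels %in% keep, comps$labels, 0L),
                        dim = mask$geometry$shape),
         keep = keep, sizes = comps$sizes)
  }
  g <- keep_big(gt)
  p <- keep_big(pred)
  n_gt <- length(g$keep)
  n_pred <- length(p$keep)

  # Intersection voxel counts between every kept gt and pred component.
  overlaps <- NULL
  if (n_gt > 0L && n_pred > 0L) {
    both <- g$labels > 0L & p$labels > 0L
    if (any(both)) {
      tab <- table(gt_label = g$labels[both], pred_label = p$labels[both])
      overlaps <- as.data.frame(tab, stringsAsFactors = FALSE)
      overlaps <- overlaps[overlaps$Freq > 0L, , drop = FALSE]
      overlaps$gt_label <- as.integer(overlaps$gt_label)
      overlaps$pred_label <- as.integer(overlaps$pred_label)
    }
  }

  pairs <- data.frame(gt_label = integer(0), pred_label = integer(0),
                      dice = numeric(0))
  if (!is.null(overlaps) && nrow(overlaps)) {
    ord <- order(-overlaps$Freq, overlaps$gt_label, overlaps$pred_label)
    overlaps <- overlaps[ord, , drop = FALSE]
    used_gt <- integer(0); used_pred <- integer(0)
    for (i in seq_len(nrow(overlaps))) {
      gl <- overlaps$gt_label[i]; pl <- overlaps$pred_label[i]
      if (gl %in% used_gt || pl %in% used_pred) next
      d <- 2 * overlaps$Freq[i] / (g$sizes[gl] + p$sizes[pl])
      pairs <- rbind(pairs, data.frame(gt_label = gl, pred_label = pl, dice = d))
      used_gt <- c(used_gt, gl); used_pred <- c(used_pred, pl)
    }
  }

  tp_flags <- stats::setNames(logical(n_gt), g$keep)
  for (i in seq_len(nrow(pairs)))
    tp_flags[as.character(pairs$gt_label[i])] <-
      pairs$dice[i] >= dice_threshold
  n_tp <- sum(tp_flags)
  fp_count <- n_pred - length(unique(pairs$pred_label))
  recall <- if (n_gt > 0L) n_tp / n_gt else NA_real_
  precision <- if (n_tp + fp_count > 0L) n_tp / (n_tp + fp_count) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision)
  else if (!is.na(recall) && !is.na(precision)) 0 else NA_real_
  dice_tp <- if (n_tp > 0L)
    mean(pairs$dice[pairs$dice >= dice_threshold]) else NA_real_

  structure(list(n_gt = n_gt, n_pred = n_pred, tp = tp_flags,
                 fp_count = fp_count, recall = recall, precision = precision,
                 f1 = f1, fppp = fp_count, dice_tp = dice_tp, pairs = pairs),
            class = "patientwise_result")
}

#' @export
print.patientwise_result <- function(x, ...) {
  cat(sprintf("<patientwise_result> %d gt tumor(s), %d prediction(s): %d TP, %d FP\n",
              x$n_gt, x$n_pred, sum(x$tp), x$fp_count))
  cat(sprintf("  recall %.3f, precision %.3f, F1 %.3f, FPPP %.2f, Dice-TP %.3f\n",
              x$recall, x$precision, x$f1, x$fppp, x$dice_tp))
  invisible(x)
}

#' Pooled estimates across cross-validation folds
#'
#' Combines per-fold means and standard deviations into cohort-level
#' pooled statistics, weighting each fold by its size. The pooled mean is
#' the size-weighted mean. The pooled variance combines within-fold
#' variance and between-fold dispersion:
#'
#'   pooled_var = ( sum_i [ (n_i - 1) s_i^2 + n_i (m_i - m)^2 ] ) / (N - 1)
#'
#' with m the pooled mean and N the total size; this equals the sample
#' variance of the concatenated per-patient values.
#'
#' @param means per-fold means.
#' @param sds per-fold sample standard deviations (`NA` allowed for
#'   single-observation folds).
#' @param sizes per-fold sizes (positive integers).
#' @return list with `mean`, `sd`, `n` and the per-fold inputs in `folds`.
#' @export
pooled_estimates <- function(means, sds, sizes) {
  if (length(means) == 0L) stop("at least one fold is required")
  if (length(means) != length(sds) || length(means) != length(sizes))
    stop("'means', 'sds' and 'sizes' must have equal length")
  sizes <- as.numeric(sizes)
  if (any(sizes <= 0)) stop("fold sizes must be positive")
  n_total <- sum(sizes)
  m <- sum(sizes * means) / n_total
  within <- ifelse(sizes > 1, (sizes - 1) * sds^2, 0)
  between <- sizes * (means - m)^2
  pooled_sd <- if (n_total > 1) sqrt(sum(within + between) / (n_total - 1))
               else NA_real_
  list(mean = m, sd = pooled_sd, n = n_total,
       folds = data.frame(mean = means, sd = sds, n = sizes))
}

#' Majority-vote consensus mask
#'
#' A voxel belongs to the consensus ground truth iff at least half of the
#' raters annotated it (count >= R/2, so 4 of 8 raters suffice).
#'
#' @param rater_masks list of two or more `binary_mask` objects on the
#'   same geometry.
#' @return a `binary_mask`.
#' @export
consensus_mask <- function(rater_masks) {
  if (length(rater_masks) < 2L) stop("at least two raters are required")
  geom <- rater_masks[[1]]$geometry
  counts <- array(0L, dim = geom$shape)
  for (m in rater_masks) {
    if (!same_geometry(m$geometry, geom))
      stop("all rater masks must share the same geometry")
    counts <- counts + m$voxels
  }
  binary_mask(counts >= length(rater_masks) / 2, geom)
}

#' Aggregate a cohort's HD95 values
#'
#' Undefined (empty-mask) cases are skipped; the number skipped is
#' reported alongside the mean and SD of the defined values.
#'
#' @param values numeric vector of HD95 values, `NA` where undefined.
#' @return list with `mean`, `sd`, `n_defined`, `n_skipped`.
#' @export
aggregate_hd95 <- function(values) {
  def <- values[!is.na(values)]
  list(mean = if (length(def)) mean(def) else NA_real_,
       sd = if (length(def) > 1) stats::sd(def) else NA_real_,
       n_defined = length(def), n_skipped = sum(is.na(values)))
}
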