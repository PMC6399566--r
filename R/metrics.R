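#' Segmentation evaluation metrics for a mask pair
#'
#' Computes the six standard pixel-overlap metrics between a ground-truth
#' mask GT and a segmentation result SR: accuracy (TP+TN)/(TP+TN+FP+FN),
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), Dice similarity
#' coefficient 2|GT n SR|/(|GT|+|SR|), Jaccard similarity
#' |GT n SR|/|GT u SR| and the per-pixel mean square error.
#'
#' Zero-denominator conventions (documented, the degenerate cases carry no
#' information): when both masks are empty DSC = JS = 1 and MSE = 0; a
#' sensitivity (specificity) with no positive (negative) reference pixels
#' is 1.
#'
#' @param gt,sr binary matrices of equal shape.
#' @return named list with `dsc`, `js`, `accuracy`, `sensitivity`,
#'   `specificity`, `mse` and the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_masks <- function(gt, sr) {
  if (!all(dim(gt) == dim(sr)))
    stop("mask shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(sr), collapse = "x"))
  g <- gt != 0; s <- sr != 0
  tp <- sum(g & s); tn <- sum(!g & !s)
  fp <- sum(!g & s); fn <- sum(g & !s)
  total <- tp + tn + fp + fn
  inter <- tp
  union <- tp + fp + fn
  dsc <- if (sum(g) + sum(s) == 0) 1 else 2 * inter / (sum(g) + sum(s))
  js <- if (union == 0) 1 else inter / union
  list(dsc = dsc, js = js,
       accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
       specificity = if (tn + fp == 0) 1 else tn / (tn + fp),
       mse = (fp + fn) / total,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Batch segmentation evaluation
#'
#' Applies [evaluate_masks()] to a list (or array) of mask pairs and
#' reports per-image rows plus a mean and standard deviation summary; the
#' batch MSE is the average of the per-image mean square errors.
#'
#' @param gts,srs lists of binary matrices, or 3-d arrays with images
#'   stacked along the third dimension.
#' @return list with `per_image` (data frame) and `summary` (mean and sd
#'   per metric).
#' @export
evaluate_batch <- function(gts, srs) {
  as_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 3)
      lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    else x
  }
  gts <- as_list(gts); srs <- as_list(srs)
  if (length(gts) != length(srs)) stop("batch lengths differ")
  rows <- lapply(seq_along(gts), function(i) {
    m <- evaluate_masks(gts[[i]], srs[[i]])
    data.frame(image = i, dsc = m$dsc, js = m$js, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               mse = m$mse)
  })
  per <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per), "image")
  list(per_image = per,
       summary = data.frame(metric = metric_cols,
                            mean = vapply(per[metric_cols], mean,
                                          numeric(1)),
                            sd = vapply(per[metric_cols], stats::sd,
                                        numeric(1))))
}
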