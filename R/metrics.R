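#' Pixelwise segmentation metrics
#'
#' Compares a predicted binary mask against ground truth and reports TP, FP,
#' FN counts along with precision, recall, F-measure, Dice and Jaccard. For
#' binary masks the F-measure and the Dice coefficient are the same
#' quantity (`2TP / (2TP + FP + FN)`), and `jaccard = dice / (2 - dice)`.
#' Two empty masks score 1 on every ratio metric; an empty prediction
#' against a non-empty truth (or vice versa) scores 0.
#'
#' @param pred,gt Logical matrices of identical shape.
#' @return List of class `eval_report` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, `dice`, `jaccard`.
#' @export
segmentation_metrics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  pred <- pred > 0; gt <- gt > 0
  tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
  if (tp + fp + fn == 0L) {
    pr <- re <- f <- dice <- jac <- 1
  } else {
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    re <- if (tp + fn > 0) tp / (tp + fn) else 0
    # F1 = 2PR/(P+R) simplifies to 2TP/(2TP+FP+FN) on counts; computing it
    # that way keeps the Dice identity exact in floating point
    dice <- 2 * tp / (2 * tp + fp + fn)
    f <- dice
    jac <- tp / (tp + fp + fn)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = pr, recall = re,
         f_measure = f, dice = dice, jaccard = jac),
    class = "eval_report"
  )
}

#' Centre-level detection metrics
#'
#' Evaluates detection of cell centres (e.g. lymphocytes): predicted
#' centres are the centroids of the 8-connected components of `pred`; each
#' ground-truth centre is greedily matched, in order of increasing
#' distance, to the nearest unmatched prediction within `match_radius`.
#' Matches are TPs, unmatched predictions FPs, unmatched truth centres FNs.
#'
#' @param pred Logical mask of detected regions.
#' @param gt_centres Two-column matrix (or data frame) of ground-truth
#'   centre coordinates (row, col).
#' @param match_radius Maximum centre-to-centroid distance (pixels) for a
#'   match. Default 8.
#' @return An `eval_report` (dice/jaccard computed from the same counts).
#' @export
detection_metrics <- function(pred, gt_centres, match_radius = 8) {
  stopifnot(match_radius > 0)
  gt_centres <- as.matrix(gt_centres)
  lab <- label_components(pred > 0)
  ncomp <- max(lab)
  if (ncomp > 0L) {
    idx <- which(lab > 0L)
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    cent <- cbind(rowsum(rr, lab[idx]), rowsum(cc, lab[idx])) /
      as.vector(table(lab[idx]))
  } else {
    cent <- matrix(numeric(0), 0L, 2L)
  }
  ng <- nrow(gt_centres); np <- nrow(cent)
  if (ng == 0L && np == 0L) {
    return(structure(list(tp = 0L, fp = 0L, fn = 0L, precision = 1,
                          recall = 1, f_measure = 1, dice = 1, jaccard = 1),
                     class = "eval_report"))
  }
  tp <- 0L
  if (ng > 0L && np > 0L) {
    D <- outer(gt_centres[, 1L], cent[, 1L], "-")^2 +
         outer(gt_centres[, 2L], cent[, 2L], "-")^2
    D <- sqrt(D)
    D[D > match_radius] <- Inf
    # greedy one-to-one matching by increasing distance
    while (any(is.finite(D))) {
      i <- which.min(D)
      g <- (i - 1L) %% ng + 1L; p <- (i - 1L) %/% ng + 1L
      tp <- tp + 1L
      D[g, ] <- Inf; D[, p] <- Inf
    }
  }
  fp <- np - tp; fn <- ng - tp
  pr <- if (np > 0) tp / np else 0
  re <- if (ng > 0) tp / ng else 0
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  f <- dice
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = pr, recall = re,
         f_measure = f, dice = dice, jaccard = if (2 - dice > 0) dice / (2 - dice) else 1),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("precision %.4f  recall %.4f  F %.4f  Dice %.4f  Jaccard %.4f\n",
              x$precision, x$recall, x$f_measure, x$dice, x$jaccard))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
             recall = x$recall, f_measure = x$f_measure, dice = x$dice,
             jaccard = x$jaccard)
}
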