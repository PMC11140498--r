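#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability: the fraction of
#' positive-negative pairs where the positive scores higher, counting ties
#' as one half.
#'
#' @param scores numeric vector in [0, 1].
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stop("no positive labels; AUC undefined")
  if (n_neg == 0L) stop("no negative labels; AUC undefined")
  # midranks give the pairwise count with half credit for ties
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` between a binarized prediction and a reference
#' mask. If both masks are empty the coefficient is 1 by convention
#' (a correct all-negative prediction); this matters for pooled scores only
#' when a bootstrap set has no positive pixels.
#'
#' @param pred numeric matrix/array of probabilities (binarized at
#'   `threshold`) or an already binary mask.
#' @param ref binary reference of the same shape.
#' @param threshold binarization threshold for probabilistic predictions.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, ref, threshold = 0.5) {
  if (!all(dim(pred) == dim(ref)) || length(pred) != length(ref))
    stop("prediction and reference shapes differ")
  a <- as.numeric(pred) >= threshold
  b <- as.numeric(ref) > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Pixel-level average precision
#'
#' Pixels are pooled across all images and ranked by descending score; AP is
#' the mean of the precision at each positive's rank (the non-interpolated
#' form).
#'
#' @param probs numeric vector (or list of matrices, pooled) of pixel scores.
#' @param refs binary references matching `probs`.
#' @return AP in [0, 1].
#' @export
pixel_average_precision <- function(probs, refs) {
  if (is.list(probs)) probs <- unlist(lapply(probs, as.numeric))
  if (is.list(refs)) refs <- unlist(lapply(refs, as.numeric))
  probs <- as.numeric(probs); refs <- as.integer(as.numeric(refs) > 0.5)
  stopifnot(length(probs) == length(refs))
  n_pos <- sum(refs)
  if (n_pos == 0L) stop("no positive pixels; average precision undefined")
  ord <- order(-probs)
  y <- refs[ord]
  cum_tp <- cumsum(y)
  prec_at_pos <- (cum_tp / seq_along(y))[y == 1L]
  sum(prec_at_pos) / n_pos
}

#' Specificity at a target sensitivity
#'
#' Chooses the highest decision threshold whose sensitivity is at least the
#' target (scores `>= threshold` are called positive) and reports that
#' threshold with its specificity: the clinically reported operating point
#' on the ROC curve.
#'
#' @param scores numeric vector.
#' @param labels binary vector.
#' @param target_sens target sensitivity in (0, 1].
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
specificity_at_sensitivity <- function(scores, labels, target_sens) {
  labels <- as.integer(labels)
  if (target_sens <= 0 || target_sens > 1)
    stop("'target_sens' must be in (0, 1]")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  for (t in thr) {
    called <- scores >= t
    sens <- sum(called & labels == 1L) / sum(labels == 1L)
    if (sens >= target_sens) {
      spec <- sum(!called & labels == 0L) / sum(labels == 0L)
      return(list(threshold = t, sensitivity = sens, specificity = spec))
    }
  }
  stop("target sensitivity unreachable")  # cannot happen for target <= 1
}

#' Majority vote over an odd number of reads
#'
#' Fuses repeated binary reads (e.g. three radiologists' examination-level
#' calls) into one reference label: the label appearing in more than half of
#' the reads.
#'
#' @param reads binary vector of odd length.
#' @return 0 or 1.
#' @export
majority_vote <- function(reads) {
  reads <- as.integer(reads)
  stopifnot(all(reads %in% 0:1))
  if (length(reads) %% 2L == 0L)
    stop("majority vote requires an odd number of reads")
  as.integer(sum(reads) > length(reads) / 2)
}

#' Evaluate a model on a labeled split
#'
#' Predicts every examination and computes examination-level AUC, pooled
#' Dice (over all pixels of the split, one global coefficient), and pooled
#' pixel average precision.
#'
#' @param model a trained `patchnet`.
#' @param exams list of labeled `exam_record`s.
#' @param dice_threshold binarization threshold for the Dice coefficient.
#' @return List with `exam_auc`, `dice`, `pixel_ap`, `exam_scores`,
#'   `exam_labels`, and the predictions.
#' @export
evaluate_model <- function(model, exams, dice_threshold = 0.5) {
  preds <- lapply(exams, function(ex) predict_exam(model, ex))
  scores <- vapply(preds, `[[`, 0, "exam_score")
  labels <- vapply(exams, function(ex) {
    if (is.na(ex$exam_label)) private_reference(ex)$exam_label else ex$exam_label
  }, logical(1))
  all_probs <- unlist(lapply(preds, function(p)
    lapply(p$prob_maps, as.numeric)))
  all_refs <- unlist(lapply(exams, function(ex)
    lapply(private_reference(ex)$masks, as.numeric)))
  pred_bin <- all_probs >= dice_threshold
  denom <- sum(pred_bin) + sum(all_refs > 0.5)
  dsc <- if (denom == 0) 1 else 2 * sum(pred_bin & all_refs > 0.5) / denom
  list(exam_auc = roc_auc(scores, labels),
       dice = dsc,
       pixel_ap = if (any(all_refs > 0.5))
         pixel_average_precision(all_probs, all_refs) else NA_real_,
       exam_scores = scores, exam_labels = as.integer(labels),
       predictions = preds)
}
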