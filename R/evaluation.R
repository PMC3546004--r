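# Confusion-count scoring of predicted multiple alignments against
# ground-truth peak group tables, and the precision/recall/F1 metrics.

#' Pair predicted alignment rows with ground-truth groups
#'
#' Each truth row is paired with at most one predicted row: the one sharing
#' the most per-chromatogram entries within `tolerance` scans. Pairing is
#' greedy by descending overlap, ties broken by the smaller median
#' retention-time gap; each predicted row is used at most once, and rows with
#' no shared entry stay unpaired.
#'
#' @param predicted,truth [alignment_table()]s over the same chromatograms.
#' @param tolerance Scan tolerance for two entries to agree.
#' @return Data frame with columns `truth_row`, `pred_row` (`NA` when
#'   unpaired) and `overlap`.
#' @export
match_groups <- function(predicted, truth, tolerance = 0L) {
  if (!identical(at_ids(predicted), at_ids(truth)))
    stop("predicted and truth tables must cover the same chromatograms")
  tc <- at_cells(truth); pc <- at_cells(predicted)
  nt <- nrow(tc); np <- nrow(pc)
  out <- data.frame(truth_row = seq_len(nt), pred_row = NA_integer_,
                    overlap = 0L)
  if (!nt || !np) return(out)
  ov <- matrix(0L, nt, np)
  for (t in seq_len(nt))
    for (p in seq_len(np))
      ov[t, p] <- sum(!is.na(tc[t, ]) & !is.na(pc[p, ]) &
                        abs(tc[t, ] - pc[p, ]) <= tolerance)
  gap <- abs(outer(truth$median_rt, predicted$median_rt, "-"))
  cand <- which(ov > 0L, arr.ind = TRUE)
  if (!nrow(cand)) return(out)
  ord <- order(-ov[cand], gap[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(nt); used_p <- logical(np)
  for (r in seq_len(nrow(cand))) {
    t <- cand[r, 1L]; p <- cand[r, 2L]
    if (!used_t[t] && !used_p[p]) {
      used_t[t] <- TRUE; used_p[p] <- TRUE
      out$pred_row[t] <- p
      out$overlap[t] <- ov[t, p]
    }
  }
  out
}

#' Confusion counts for a predicted alignment against ground truth
#'
#' For every paired row and every chromatogram: both present and agreeing
#' within tolerance is a true positive; both present but disagreeing counts
#' one false positive and one false negative; absent in both is a true
#' negative; present only in the prediction is a false positive; present only
#' in the truth is a false negative. Present entries of unpaired truth rows
#' are false negatives. Predicted rows matching no truth group are not
#' scored; their count is reported as `unassignable`.
#'
#' @param pairings Output of [match_groups()].
#' @param predicted,truth The tables given to [match_groups()].
#' @param tolerance Scan tolerance for agreement.
#' @return An object of class `"confusion_counts"`: list with `TP`, `FP`,
#'   `FN`, `TN`, `unassignable`.
#' @export
score_counts <- function(pairings, predicted, truth, tolerance = 0L) {
  tc <- at_cells(truth); pc <- at_cells(predicted)
  TP <- FP <- FN <- TN <- 0L
  for (r in seq_len(nrow(pairings))) {
    t <- pairings$truth_row[r]; p <- pairings$pred_row[r]
    if (is.na(p)) {
      FN <- FN + sum(!is.na(tc[t, ]))
      next
    }
    for (k in seq_len(ncol(tc))) {
      tpres <- !is.na(tc[t, k]); ppres <- !is.na(pc[p, k])
      if (tpres && ppres) {
        if (abs(tc[t, k] - pc[p, k]) <= tolerance) TP <- TP + 1L
        else { FP <- FP + 1L; FN <- FN + 1L }
      } else if (!tpres && !ppres) TN <- TN + 1L
      else if (!tpres && ppres) FP <- FP + 1L
      else FN <- FN + 1L
    }
  }
  unass <- nrow(pc) - sum(!is.na(pairings$pred_row))
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, unassignable = unass),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2 * Precision * Recall / (Precision + Recall). A metric with a zero
#' denominator is reported as `NA` (undefined), except that F1 is 0 by
#' convention when precision and recall are both 0.
#'
#' @param counts A `"confusion_counts"` object, or a list with `TP`, `FP`,
#'   `FN` entries (e.g. counts read from a published table).
#' @return List with `precision`, `recall`, `f1`.
#' @export
alignment_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a peak alignment table against ground truth
#'
#' Convenience wrapper: [match_groups()], [score_counts()] and
#' [alignment_metrics()] in one call.
#'
#' @param predicted,truth [alignment_table()]s over the same chromatograms.
#' @param tolerance Scan tolerance for agreement.
#' @return List with `counts`, `precision`, `recall`, `f1`, `pairings`.
#' @export
evaluate_alignment <- function(predicted, truth, tolerance = 0L) {
  pr <- match_groups(predicted, truth, tolerance)
  counts <- score_counts(pr, predicted, truth, tolerance)
  c(list(counts = counts), alignment_metrics(counts), list(pairings = pr))
}

#' Evaluate a profile (DTW) alignment against ground-truth peak groups
#'
#' A profile alignment assigns every scan, so true negatives and false
#' negatives are not available; only TP and FP are counted. For each truth
#' group, the profile row at the group's center-chromatogram scan is looked
#' up; a non-center entry within `tolerance` scans of the truth entry is a
#' true positive, otherwise (or when the truth marks the peak absent) it is a
#' false positive.
#'
#' @param predicted Profile [alignment_table()] from [cemapp_dtw_align()]
#'   (must carry the `center_id` attribute, or pass `center_id`).
#' @param truth Ground-truth peak [alignment_table()].
#' @param tolerance Scan tolerance for agreement.
#' @param center_id Optional center chromatogram id override.
#' @return List with `TP`, `FP` and the number of truth rows skipped because
#'   the truth lacks a center entry.
#' @export
evaluate_profile <- function(predicted, truth, tolerance = 2L,
                             center_id = NULL) {
  if (is.null(center_id)) center_id <- attr(predicted, "center_id")
  if (is.null(center_id)) stop("center_id required")
  ids <- at_ids(predicted)
  if (!identical(sort(ids), sort(at_ids(truth))))
    stop("predicted and truth tables must cover the same chromatograms")
  pc <- at_cells(predicted); tc <- at_cells(truth)[, ids, drop = FALSE]
  ctr <- match(center_id, ids)
  TP <- FP <- 0L; skipped <- 0L
  for (t in seq_len(nrow(tc))) {
    s <- tc[t, ctr]
    if (is.na(s) || s < 1L || s > nrow(pc)) { skipped <- skipped + 1L; next }
    row <- pc[s, ]
    for (k in seq_len(length(ids))[-ctr]) {
      if (is.na(tc[t, k])) FP <- FP + 1L
      else if (abs(row[k] - tc[t, k]) <= tolerance) TP <- TP + 1L
      else FP <- FP + 1L
    }
  }
  list(TP = TP, FP = FP, skipped = skipped)
}
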