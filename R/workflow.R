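# Orchestration of the three evaluation configurations: peak alignment
# alone, profile alignment alone, and the hybrid in which the best peak
# alignment (by F1) supplies anchors that constrain the profile alignment.

#' Sweep peak-alignment parameters and pick the best table by F1
#'
#' Runs [bipace_align()] for every row of a parameter grid, scores each
#' multiple alignment against the ground truth, and returns the result table
#' together with the alignment achieving the highest F1 (the natural anchor
#' source for the hybrid profile alignment).
#'
#' @param chroms List of [chromatogram()]s with peaks.
#' @param truth Ground-truth [alignment_table()].
#' @param grid Data frame of parameterizations; recognized columns: `kind`,
#'   `use_rt_penalty`, `D`, `T`, `mcs` (missing columns fall back to the
#'   defaults of [sim_config()] / [bipace_align()]).
#' @param tolerance Scan tolerance for the evaluation.
#' @return List with `results` (one row per parameterization: parameters,
#'   TP/FP/FN/TN, precision/recall/F1), `best_table`, `best_row`.
#' @export
run_bipace_sweep <- function(chroms, truth, grid, tolerance = 0L) {
  if (!nrow(grid)) stop("parameter grid must be nonempty")
  res <- vector("list", nrow(grid))
  best_f1 <- -Inf; best_table <- NULL; best_row <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, , drop = FALSE]
    cfg <- sim_config(
      kind = if ("kind" %in% names(g)) as.character(g$kind) else "cosine",
      use_rt_penalty = if ("use_rt_penalty" %in% names(g)) g$use_rt_penalty else TRUE,
      D = if ("D" %in% names(g)) g$D else 2.5,
      T = if ("T" %in% names(g)) g$T else 0)
    mcs <- if ("mcs" %in% names(g)) g$mcs else 2L
    tab <- bipace_align(chroms, cfg, mcs)
    ev <- evaluate_alignment(tab, truth, tolerance)
    res[[r]] <- data.frame(
      g, TP = ev$counts$TP, FP = ev$counts$FP, FN = ev$counts$FN,
      TN = ev$counts$TN, unassignable = ev$counts$unassignable,
      precision = ev$precision, recall = ev$recall, f1 = ev$f1,
      rows = nrow(tab))
    f1 <- if (is.na(ev$f1)) -Inf else ev$f1
    if (f1 > best_f1) { best_f1 <- f1; best_table <- tab; best_row <- r }
  }
  list(results = do.call(rbind, res), best_table = best_table,
       best_row = best_row)
}

#' Profile alignment run with optional anchors, scored in profile mode
#'
#' Runs [cemapp_dtw_align()] and, when ground truth is given, scores the
#' result with [evaluate_profile()] (TP/FP only: a profile alignment assigns
#' every scan, so TN/FN are not defined).
#'
#' @param chroms List of [chromatogram()]s with scans.
#' @param cfg A [sim_config()].
#' @param wts A [dtw_weights()].
#' @param band_width,band_scope Sakoe-Chiba band parameters.
#' @param anchors Optional anchor [alignment_table()].
#' @param r Anchor radius in scans.
#' @param truth Optional ground-truth [alignment_table()].
#' @param tolerance Scan tolerance for profile scoring.
#' @return List with `table`, `stored_cells`, and (when truth is given)
#'   `TP`, `FP`.
#' @export
run_cemapp <- function(chroms, cfg = sim_config(), wts = dtw_weights(),
                       band_width = 0.1, band_scope = "local",
                       anchors = NULL, r = 0L, truth = NULL,
                       tolerance = 2L) {
  tab <- cemapp_dtw_align(chroms, cfg, wts, band_width, band_scope,
                          anchors, r)
  out <- list(table = tab, stored_cells = attr(tab, "stored_cells"))
  if (!is.null(truth)) {
    ev <- evaluate_profile(tab, truth, tolerance)
    out$TP <- ev$TP; out$FP <- ev$FP
  }
  out
}

#' Hybrid run: peak-clique anchors constrain the profile alignment
#'
#' Uses a peak alignment table (typically the best-F1 table from
#' [run_bipace_sweep()]) as the anchor set for [cemapp_dtw_align()]: each
#' aligned group contributes an anchor to every chromatogram pair it covers.
#'
#' @inheritParams run_cemapp
#' @param bipace_table Peak [alignment_table()] supplying the anchors.
#' @return As [run_cemapp()].
#' @export
run_hybrid <- function(chroms, bipace_table, cfg = sim_config(),
                       wts = dtw_weights(), band_width = 0.1,
                       band_scope = "local", r = 0L, truth = NULL,
                       tolerance = 2L) {
  run_cemapp(chroms, cfg, wts, band_width, band_scope,
             anchors = bipace_table, r = r, truth = truth,
             tolerance = tolerance)
}
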