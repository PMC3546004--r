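# Profile alignment by center-star multiple alignment with anchor-partitioned
# dynamic time warping. The DP matrix is stored row-compressed: each row keeps
# only an admissible column interval derived from anchor partitions and
# Sakoe-Chiba band constraints; everything outside reads as -Inf.

#' Dynamic time warping step weights
#'
#' Diagonal (match), horizontal (compression) and vertical (expansion) step
#' weights. A match weight above 1 discourages overadaptation of the path;
#' 2.25 with unit compression/expansion weights is a good default for binned
#' GC-MS spectra.
#'
#' @param match,comp,exp Positive step weights.
#' @return An object of class `"dtw_weights"`.
#' @export
dtw_weights <- function(match = 2.25, comp = 1, exp = 1) {
  if (match <= 0 || comp <= 0 || exp <= 0) stop("weights must be > 0")
  structure(list(match = match, comp = comp, exp = exp),
            class = "dtw_weights")
}

#' Filter anchor pairs to a monotone chain
#'
#' Anchors with inverted order are removed by keeping a longest strictly
#' increasing subsequence of the second coordinate (after sorting by the
#' first), so the number of deletions is minimal; then any anchor directly
#' adjacent to its predecessor in both coordinates is dropped.
#'
#' @param pairs Two-column matrix of (scan in A, scan in B) index pairs.
#' @return Two-column integer matrix, strictly increasing in both columns.
#' @export
filter_anchors <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (!nrow(pairs)) return(pairs)
  # sort by first coordinate; equal first coordinates sorted by decreasing
  # second so that at most one of them can survive the strict LIS
  ord <- order(pairs[, 1L], -pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  b <- pairs[, 2L]
  n <- length(b)
  tails <- integer(0)       # index (into b) of smallest tail per LIS length
  prev <- integer(n)
  for (k in seq_len(n)) {
    pos <- findInterval(b[k] - 1L, b[tails]) + 1L  # first tail >= b[k]
    prev[k] <- if (pos > 1L) tails[pos - 1L] else 0L
    tails[pos] <- k
    length(tails) <- max(length(tails), pos)
  }
  keep <- integer(0)
  k <- tails[length(tails)]
  while (k > 0L) { keep <- c(k, keep); k <- prev[k] }
  out <- pairs[keep, , drop = FALSE]
  # drop anchors adjacent to their predecessor in both coordinates
  if (nrow(out) > 1L) {
    ok <- rep(TRUE, nrow(out))
    last <- 1L
    for (k in 2L:nrow(out)) {
      if (out[k, 1L] - out[last, 1L] <= 1L && out[k, 2L] - out[last, 2L] <= 1L)
        ok[k] <- FALSE
      else last <- k
    }
    out <- out[ok, , drop = FALSE]
  }
  colnames(out) <- c("a", "b")
  out
}

#' Build the admissible-cell layout for a constrained DTW alignment
#'
#' The admissible set is the union of the rectangles spanned by successive
#' anchors (rows at an anchor are pinched to the anchor column +/- the
#' radius `r`, so with `r = 0` every path is forced through every anchor),
#' intersected with a Sakoe-Chiba band: `scope = "global"` places one band of
#' half-width `ceil(w * max(M, N))` around the global diagonal,
#' `scope = "local"` places it around each inter-anchor segment. Rows are then
#' minimally widened so consecutive intervals overlap or abut diagonally and
#' a valid warping path from (1,1) to (M,N) exists.
#'
#' @param anchors Optional two-column matrix of anchor scan pairs (filtered
#'   through [filter_anchors()]).
#' @param r Anchor radius in scans (>= 0).
#' @param band_width Band width as a fraction of `max(M, N)` (0 < w <= 1;
#'   1 disables the band).
#' @param band_scope `"global"` or `"local"`.
#' @param M,N Series lengths.
#' @return An object of class `"dtw_layout"` with per-row admissible column
#'   intervals `lo`, `hi` and the stored-cell count `cells`.
#' @export
build_layout <- function(anchors = NULL, r = 0L, band_width = 1,
                         band_scope = c("global", "local"), M, N) {
  band_scope <- match.arg(band_scope)
  if (band_width <= 0 || band_width > 1) stop("band_width must lie in (0, 1]")
  r <- as.integer(r)
  if (!is.null(anchors) && nrow(anchors)) {
    anchors <- filter_anchors(anchors)
    keep <- anchors[, 1L] >= 1L & anchors[, 1L] <= M &
            anchors[, 2L] >= 1L & anchors[, 2L] <= N
    anchors <- anchors[keep, , drop = FALSE]
  } else anchors <- matrix(integer(), ncol = 2L)
  h <- as.integer(ceiling(band_width * max(M, N)))
  use_band <- band_width < 1
  aug <- rbind(c(0L, 0L), anchors, c(M + 1L, N + 1L))
  lo <- integer(M); hi <- integer(M)
  arow <- integer(0)
  if (nrow(anchors)) arow <- anchors[, 1L]
  part <- findInterval(seq_len(M), aug[, 1L])  # partition index per row
  for (i in seq_len(M)) {
    k <- part[i]
    if (i == aug[k, 1L]) { # anchor row: pinch to the anchor column
      lo[i] <- aug[k, 2L] - r
      hi[i] <- aug[k, 2L] + r
      next
    }
    c0 <- aug[k, 2L]; c1 <- aug[k + 1L, 2L]
    l <- max(1L, c0); u <- min(N, c1)
    if (use_band && band_scope == "local") {
      a0 <- aug[k, 1L]; a1 <- aug[k + 1L, 1L]
      ctr <- c0 + (i - a0) * (c1 - c0) / (a1 - a0)
      l <- max(l, as.integer(floor(ctr - h)))
      u <- min(u, as.integer(ceiling(ctr + h)))
    }
    lo[i] <- l; hi[i] <- u
  }
  if (use_band && band_scope == "global") {
    ctr <- seq_len(M) * N / M
    lo <- pmax(lo, as.integer(floor(ctr - h)))
    hi <- pmin(hi, as.integer(ceiling(ctr + h)))
    # anchor cells stay admissible
    if (nrow(anchors)) {
      lo[arow] <- pmin(lo[arow], anchors[, 2L] - r)
      hi[arow] <- pmax(hi[arow], anchors[, 2L] + r)
    }
  }
  # anchor-radius squares widen the neighbouring rows
  if (r > 0L && nrow(anchors)) {
    for (k in seq_len(nrow(anchors))) {
      rows <- max(1L, anchors[k, 1L] - r):min(M, anchors[k, 1L] + r)
      lo[rows] <- pmin(lo[rows], anchors[k, 2L] - r)
      hi[rows] <- pmax(hi[rows], anchors[k, 2L] + r)
    }
  }
  lo <- pmax(lo, 1L); hi <- pmin(hi, N)
  bad <- lo > hi
  if (any(bad)) { # degenerate rows collapse onto their nearest valid column
    mid <- pmin(pmax((lo + hi) %/% 2L, 1L), N)
    lo[bad] <- mid[bad]; hi[bad] <- mid[bad]
  }
  # path endpoints
  if (lo[1L] > 1L) lo[1L] <- 1L
  if (hi[M] < N) hi[M] <- N
  # monotone interval bounds (widening only)
  lo <- rev(cummin(rev(lo)))
  hi <- cummax(hi)
  # consecutive rows must overlap or abut diagonally
  for (i in seq_len(M)[-1L]) {
    if (lo[i] > hi[i - 1L] + 1L) lo[i] <- hi[i - 1L] + 1L
    if (hi[i] < lo[i - 1L]) hi[i] <- lo[i - 1L]
  }
  # when the repair had to widen a pinched anchor row (anchors on nearly
  # adjacent rows with distant columns), later rows may only be entered
  # through the anchor cell: restrict the next partition to columns past the
  # anchor so that zero-radius anchors stay forced
  if (r == 0L && nrow(anchors)) {
    for (k in seq_len(nrow(anchors))) {
      a <- anchors[k, 1L]; b <- anchors[k, 2L]
      if (a < M && lo[a] < b) {
        upto <- if (k < nrow(anchors)) anchors[k + 1L, 1L] else M
        rows <- seq.int(a + 1L, upto)
        rows <- rows[hi[rows] >= b + 1L]
        lo[rows] <- pmax(lo[rows], b + 1L)
      }
    }
  }
  structure(list(M = as.integer(M), N = as.integer(N), lo = lo, hi = hi,
                 anchors = anchors, r = r, band_width = band_width,
                 band_scope = band_scope,
                 cells = sum(hi - lo + 1L)),
            class = "dtw_layout")
}

#' @export
print.dtw_layout <- function(x, ...) {
  cat(sprintf("<dtw_layout %d x %d: %d stored cells (%.1f%%), %d anchors, r=%d, band %s %.2f>\n",
              x$M, x$N, x$cells, 100 * x$cells / (as.double(x$M) * x$N),
              nrow(x$anchors), x$r, x$band_scope, x$band_width))
  invisible(x)
}

# ---- partitioned (row-compressed) array ----------------------------------

#' Row-compressed partitioned array
#'
#' Stores only the admissible cells of a layout in a linear value array `d`,
#' addressed per row through an offset array `idx` and per-row length `len`.
#' Reading a non-stored cell returns `default_value`; writing one has no
#' effect, since the layout is fixed at construction.
#'
#' @param layout A [build_layout()] result.
#' @param default_value Value reported for cells outside the layout.
#' @return An object of class `"partitioned_array"`.
#' @export
partitioned_array <- function(layout, default_value = -Inf) {
  len <- layout$hi - layout$lo + 1L
  idx <- c(0L, cumsum(len))[seq_along(len)]
  structure(list(d = rep(default_value, sum(len)), idx = idx, len = len,
                 lo = layout$lo, M = layout$M, N = layout$N,
                 default_value = default_value),
            class = "partitioned_array")
}

#' Read a cell of a partitioned array
#' @param pa A [partitioned_array()].
#' @param i,j Row and column (1-based).
#' @export
pa_get <- function(pa, i, j) {
  if (i < 1L || i > pa$M || j < pa$lo[i] || j > pa$lo[i] + pa$len[i] - 1L)
    return(pa$default_value)
  pa$d[pa$idx[i] + (j - pa$lo[i]) + 1L]
}

#' Write a cell of a partitioned array
#'
#' Writes outside the stored layout are silent no-ops.
#'
#' @param pa A [partitioned_array()].
#' @param i,j Row and column (1-based).
#' @param x Value to store.
#' @return The updated array.
#' @export
pa_set <- function(pa, i, j, x) {
  if (i < 1L || i > pa$M || j < pa$lo[i] || j > pa$lo[i] + pa$len[i] - 1L)
    return(pa)
  pa$d[pa$idx[i] + (j - pa$lo[i]) + 1L] <- x
  pa
}

# ---- pairwise DTW ---------------------------------------------------------

# Penalized similarity values for the admissible cells of a layout, computed
# blockwise (BLAS on row chunks restricted to the admissible column span) and
# returned flattened in row-compressed order.
.dtw_f_rcs <- function(A, B, rt_a, rt_b, cfg, layout, chunk = 64L) {
  M <- layout$M; N <- layout$N
  kind <- cfg$kind
  fn_kind <- is.function(kind)
  if (!fn_kind) {
    Ap <- .prep_spectra(t(A), kind)
    Bp <- .prep_spectra(t(B), kind)
    if (kind == "euclidean") { na <- colSums(Ap^2); nb <- colSums(Bp^2) }
  }
  out <- numeric(layout$cells)
  len <- layout$hi - layout$lo + 1L
  offs <- c(0L, cumsum(len))
  use_pen <- cfg$use_rt_penalty
  if (use_pen && (is.null(rt_a) || is.null(rt_b)))
    stop("retention times required for the retention-time penalty")
  for (r0 in seq.int(1L, M, by = chunk)) {
    rows <- r0:min(M, r0 + chunk - 1L)
    cmin <- min(layout$lo[rows]); cmax <- max(layout$hi[rows])
    cols <- cmin:cmax
    if (fn_kind) {
      s <- .sim_matrix(t(A[rows, , drop = FALSE]), t(B[cols, , drop = FALSE]), kind)
    } else {
      s <- crossprod(Ap[, rows, drop = FALSE], Bp[, cols, drop = FALSE])
      if (kind == "euclidean")
        s <- -sqrt(pmax(outer(na[rows], nb[cols], "+") - 2 * s, 0))
    }
    if (use_pen)
      s <- s * exp(-outer(rt_a[rows], rt_b[cols], "-")^2 / (2 * cfg$D^2))
    for (i in rows) {
      jj <- (layout$lo[i]:layout$hi[i]) - cmin + 1L
      out[(offs[i] + 1L):offs[i + 1L]] <- s[i - r0 + 1L, jj]
    }
  }
  out
}

.as_scan_series <- function(x) {
  if (inherits(x, "chromatogram")) {
    if (is.null(x$scans)) stop("chromatogram '", x$id, "' has no scan series")
    list(scans = x$scans, rts = x$scan_rts)
  } else list(scans = as.matrix(x), rts = NULL)
}

#' Pairwise constrained dynamic time warping of two scan series
#'
#' Maximizes the sum of step-weighted penalized spectral similarities over
#' all monotone, continuous warping paths from (1,1) to (M,N) restricted to
#' the admissible cells of `layout`. The recursion and traceback run over a
#' row-compressed storage of the admissible region only.
#'
#' @param A,B Scan series: matrices (rows = scans, columns = mass bins) or
#'   [chromatogram()]s with scans.
#' @param cfg A [sim_config()]; the threshold `T` is ignored here (the
#'   admissible region is governed by the layout, not by the penalty cutoff).
#' @param wts A [dtw_weights()].
#' @param layout Optional [build_layout()] result; default is the fully
#'   admissible layout.
#' @param rt_a,rt_b Per-scan retention times (taken from chromatograms when
#'   given there; required when the retention-time penalty is enabled).
#' @return An object of class `"dtw_alignment"`: `path` (K x 2 index pairs),
#'   `moves` (match/compression/expansion), `score` = Q(M,N),
#'   `score_corrected` = score divided by the summed step weights, `f_path`,
#'   and the stored-cell count `cells`.
#' @export
dtw_align <- function(A, B, cfg = sim_config(), wts = dtw_weights(),
                      layout = NULL, rt_a = NULL, rt_b = NULL) {
  sa <- .as_scan_series(A); sb <- .as_scan_series(B)
  if (is.null(rt_a)) rt_a <- sa$rts
  if (is.null(rt_b)) rt_b <- sb$rts
  M <- nrow(sa$scans); N <- nrow(sb$scans)
  if (M < 1L || N < 1L) stop("both series must contain at least one scan")
  if (ncol(sa$scans) != ncol(sb$scans))
    stop("series must share the mass-bin range")
  if (is.null(layout)) layout <- build_layout(M = M, N = N)
  if (layout$M != M || layout$N != N) stop("layout does not match series lengths")
  f <- .dtw_f_rcs(sa$scans, sb$scans, rt_a, rt_b, cfg, layout)
  res <- dtw_dp_rcs(f, layout$lo, layout$hi, N,
                    wts$match, wts$comp, wts$exp)
  .dtw_result(res, f, layout, wts)
}

.dtw_result <- function(res, f, layout, wts) {
  moves <- c("match", "compression", "expansion")[res$move + 1L]
  w <- c(match = wts$match, compression = wts$comp, expansion = wts$exp)[moves]
  len <- layout$hi - layout$lo + 1L
  offs <- c(0L, cumsum(len))
  f_path <- f[offs[res$i] + (res$j - layout$lo[res$i]) + 1L]
  structure(list(path = cbind(i = res$i, j = res$j), moves = moves,
                 score = res$score,
                 score_corrected = res$score / sum(w),
                 f_path = f_path, cells = res$cells,
                 M = layout$M, N = layout$N, layout = layout),
            class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment %d x %d: path length %d, score %.4f (corrected %.4f), %d cells>\n",
              x$M, x$N, nrow(x$path), x$score, x$score_corrected, x$cells))
  invisible(x)
}

#' Run the DTW recursion on a precomputed similarity matrix
#'
#' Lower-level entry point: takes the per-cell similarity values directly,
#' which is useful for custom local similarities and for verifying that the
#' row-compressed machinery reproduces a dense recursion exactly.
#'
#' @param f Numeric M x N matrix of per-cell similarities (only admissible
#'   cells are read).
#' @param wts A [dtw_weights()].
#' @param layout Optional [build_layout()] result (default: all cells).
#' @return A `"dtw_alignment"` as in [dtw_align()].
#' @export
dtw_dp <- function(f, wts = dtw_weights(), layout = NULL) {
  f <- as.matrix(f)
  M <- nrow(f); N <- ncol(f)
  if (is.null(layout)) layout <- build_layout(M = M, N = N)
  flat <- numeric(layout$cells)
  len <- layout$hi - layout$lo + 1L
  offs <- c(0L, cumsum(len))
  for (i in seq_len(M))
    flat[(offs[i] + 1L):offs[i + 1L]] <- f[i, layout$lo[i]:layout$hi[i]]
  if (any(!is.finite(flat))) stop("similarities at admissible cells must be finite")
  res <- dtw_dp_rcs(flat, layout$lo, layout$hi, N, wts$match, wts$comp, wts$exp)
  .dtw_result(res, flat, layout, wts)
}

# Dense reference recursion in plain R over a full (M+1) x (N+1) matrix; used
# as the independent cross-check for the row-compressed implementation.
dtw_dp_dense <- function(f, wts = dtw_weights()) {
  M <- nrow(f); N <- ncol(f)
  Q <- matrix(-Inf, M + 1L, N + 1L)
  mv <- matrix(NA_integer_, M + 1L, N + 1L)
  Q[1L, 1L] <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      fij <- f[i, j]
      cm <- Q[i, j] + wts$match * fij
      cc <- Q[i + 1L, j] + wts$comp * fij
      ce <- Q[i, j + 1L] + wts$exp * fij
      best <- cm; b <- 0L
      if (cc > best) { best <- cc; b <- 1L }
      if (ce > best) { best <- ce; b <- 2L }
      Q[i + 1L, j + 1L] <- best
      mv[i + 1L, j + 1L] <- b
    }
  }
  i <- M; j <- N
  pi <- integer(0); pj <- integer(0); pm <- integer(0)
  while (TRUE) {
    pi <- c(i, pi); pj <- c(j, pj); pm <- c(mv[i + 1L, j + 1L], pm)
    if (i == 1L && j == 1L) break
    switch(mv[i + 1L, j + 1L] + 1L,
           { i <- i - 1L; j <- j - 1L },
           { j <- j - 1L },
           { i <- i - 1L })
  }
  moves <- c("match", "compression", "expansion")[pm + 1L]
  w <- c(match = wts$match, compression = wts$comp, expansion = wts$exp)[moves]
  list(score = Q[M + 1L, N + 1L],
       path = cbind(i = pi, j = pj), moves = moves,
       score_corrected = Q[M + 1L, N + 1L] / sum(w))
}

#' Local maxima of the similarity profile along an alignment path
#'
#' Reports the path positions where the local similarity is strictly greater
#' than at both path neighbours (for a plateau, its first position); these
#' coincide with aligned, highly similar mass spectra.
#'
#' @param x A `"dtw_alignment"`, or a numeric vector of similarities along a
#'   path.
#' @return For an alignment, a matrix of (i, j) index pairs at the maxima;
#'   for a numeric vector, the integer positions of the maxima.
#' @export
extract_similarity_maxima <- function(x) {
  if (inherits(x, "dtw_alignment")) {
    pos <- extract_similarity_maxima(x$f_path)
    return(x$path[pos, , drop = FALSE])
  }
  f <- as.numeric(x)
  if (!length(f)) stop("path must be nonempty")
  runs <- rle(f)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  v <- runs$values
  n <- length(v)
  is_max <- vapply(seq_len(n), function(k) {
    left_ok <- k == 1L || v[k - 1L] < v[k]
    right_ok <- k == n || v[k + 1L] < v[k]
    left_ok && right_ok
  }, logical(1))
  if (n == 1L) is_max <- FALSE  # constant profile has no maximum
  starts[is_max]
}

#' Select the center chromatogram from pairwise alignment scores
#'
#' The chromatogram with the highest sum of weight-corrected pairwise scores
#' to all others becomes the alignment reference (center-star heuristic);
#' ties go to the lowest index.
#'
#' @param scores Symmetric K x K matrix of pairwise scores (diagonal
#'   ignored).
#' @return Integer index of the center chromatogram.
#' @export
select_center <- function(scores) {
  scores <- as.matrix(scores)
  K <- nrow(scores)
  if (K < 2L) stop("need at least 2 chromatograms")
  diag(scores) <- 0
  which.max(rowSums(scores))
}

# anchors for a chromatogram pair from a peak alignment table: rows where
# both chromatograms are present yield one (scan_i, scan_j) anchor
anchors_from_table <- function(tab, i, j) {
  cells <- at_cells(tab)
  ok <- !is.na(cells[, i]) & !is.na(cells[, j])
  cbind(cells[ok, i], cells[ok, j])
}

#' Center-star multiple alignment of chromatograms by constrained DTW
#'
#' Computes all pairwise weight-corrected DTW scores (reusing anchor
#' constraints when given), selects the center chromatogram, aligns every
#' other chromatogram to the center, and assembles a dense profile alignment
#' table with one row per center scan and no absent cells. When several scans
#' of a chromatogram map to one center scan, the cell records the scan with
#' the highest local similarity to the center scan; the full mapped range is
#' kept in the `ranges` attribute.
#'
#' @param chroms List of >= 2 [chromatogram()]s with scan series.
#' @param cfg A [sim_config()].
#' @param wts A [dtw_weights()].
#' @param band_width Sakoe-Chiba band width as a fraction of `max(M, N)`.
#' @param band_scope `"global"` or `"local"`.
#' @param anchors Optional anchor source: a peak [alignment_table()] (e.g.
#'   from [bipace_align()]), whose rows provide anchors for every
#'   chromatogram pair they cover, or `NULL` for unconstrained bands.
#' @param r Anchor radius in scans.
#' @return An [alignment_table()] of scan indices with attributes `center`
#'   (chromatogram index), `center_id`, `scores` (pairwise corrected score
#'   matrix), `stored_cells` (total DP cells across all alignments) and
#'   `ranges`.
#' @export
cemapp_dtw_align <- function(chroms, cfg = sim_config(), wts = dtw_weights(),
                             band_width = 0.1, band_scope = "local",
                             anchors = NULL, r = 0L) {
  K <- length(chroms)
  if (K < 2L) stop("need at least 2 chromatograms")
  for (ch in chroms)
    if (is.null(ch$scans)) stop("all chromatograms need scan series")
  ids <- vapply(chroms, `[[`, character(1), "id")
  pair_layout <- function(i, j) {
    anc <- if (is.null(anchors)) NULL else anchors_from_table(anchors, i, j)
    build_layout(anchors = anc, r = r, band_width = band_width,
                 band_scope = band_scope,
                 M = nrow(chroms[[i]]$scans), N = nrow(chroms[[j]]$scans))
  }
  scores <- matrix(0, K, K)
  aligns <- vector("list", K * K)
  stored <- 0
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      al <- dtw_align(chroms[[i]], chroms[[j]], cfg, wts, pair_layout(i, j))
      scores[i, j] <- scores[j, i] <- al$score_corrected
      aligns[[(i - 1L) * K + j]] <- al
      stored <- stored + al$cells
    }
  }
  ctr <- select_center(scores)
  Mc <- nrow(chroms[[ctr]]$scans)
  cells <- matrix(NA_integer_, Mc, K, dimnames = list(NULL, ids))
  cells[, ctr] <- seq_len(Mc)
  ranges <- vector("list", K)
  for (j in setdiff(seq_len(K), ctr)) {
    # reuse the pairwise alignment; orient it center -> other
    al <- if (ctr < j) aligns[[(ctr - 1L) * K + j]] else aligns[[(j - 1L) * K + ctr]]
    if (ctr < j) { ci <- al$path[, 1L]; oj <- al$path[, 2L] }
    else { ci <- al$path[, 2L]; oj <- al$path[, 1L] }
    best <- integer(Mc); lo <- integer(Mc); hi <- integer(Mc)
    f <- al$f_path
    for (grp in split(seq_along(ci), ci)) {
      i0 <- ci[grp[1L]]
      lo[i0] <- min(oj[grp]); hi[i0] <- max(oj[grp])
      best[i0] <- oj[grp[which.max(f[grp])]]
    }
    cells[, j] <- best
    ranges[[j]] <- cbind(lo = lo, hi = hi)
  }
  rts <- lapply(chroms, `[[`, "scan_rts")
  med <- vapply(seq_len(Mc), function(rr)
    stats::median(vapply(seq_len(K), function(k) rts[[k]][cells[rr, k]],
                         numeric(1))), numeric(1))
  tab <- alignment_table(cells, ids, med)
  attr(tab, "center") <- ctr
  attr(tab, "center_id") <- ids[ctr]
  attr(tab, "scores") <- scores
  attr(tab, "stored_cells") <- stored
  attr(tab, "ranges") <- ranges
  tab
}
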