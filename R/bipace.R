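# Peak-based multiple alignment: all inter-chromatogram peak similarities are
# reduced to per-peak best-hit sets, mutual best hits become the edges of an
# unweighted K-partite graph, and greedy clique merging over that graph yields
# the aligned peak groups.

# intensity matrix (L x n_peaks) and rt/apex vectors of a chromatogram
.peak_matrix <- function(chrom) {
  if (!length(chrom$peaks)) stop("chromatogram '", chrom$id, "' has no peaks")
  list(int = vapply(chrom$peaks, `[[`, numeric(length(chrom$peaks[[1]]$intensities)),
                    "intensities"),
       rt = vapply(chrom$peaks, `[[`, numeric(1), "rt"),
       apex = vapply(chrom$peaks, `[[`, integer(1), "apex_scan"))
}

# Pairwise peak similarity matrix between chromatograms i and j; entries
# whose retention-time penalty falls below T are NA (pruned). Returns the
# matrix plus the pruned count.
.pair_sim_matrix <- function(pmi, pmj, cfg) {
  s <- .sim_matrix(pmi$int, pmj$int, cfg$kind)
  pruned <- 0L
  if (cfg$use_rt_penalty) {
    pen <- exp(-outer(pmi$rt, pmj$rt, "-")^2 / (2 * cfg$D^2))
    below <- pen < cfg$T
    s <- s * pen
    s[below] <- NA_real_
    pruned <- sum(below)
  }
  list(sim = s, pruned = pruned)
}

# argmax over a similarity row with NA = pruned; ties broken by smaller
# |delta rt|, then by lower peak index
.best_hit <- function(simrow, dt) {
  cand <- which(!is.na(simrow))
  if (!length(cand)) return(c(NA_integer_, NA_real_))
  m <- max(simrow[cand])
  top <- cand[simrow[cand] == m]
  if (length(top) > 1L) top <- top[order(abs(dt[top]), top)]
  c(top[1L], m)
}

#' Compute per-peak best-hit sets across chromatograms
#'
#' Evaluates the penalized similarity for all pairs of peaks from distinct
#' chromatograms (self-similarities within a chromatogram are never
#' computed), prunes pairs whose retention-time penalty falls below the
#' threshold `T`, and records for every peak its best hit in every other
#' chromatogram.
#'
#' @param chroms List of >= 2 [chromatogram()]s with peaks, sharing a mass
#'   range.
#' @param cfg A [sim_config()].
#' @return An object of class `"best_hit_store"`: `hits[[i]][[j]]` holds the
#'   best-hit peak index and similarity in chromatogram `j` for every peak of
#'   chromatogram `i`; `pruned` counts the pairs excluded by the threshold.
#' @export
compute_best_hits <- function(chroms, cfg = sim_config()) {
  K <- length(chroms)
  if (K < 2L) stop("need at least 2 chromatograms")
  mr <- chroms[[1]]$mass_range
  for (c in chroms)
    if (!identical(c$mass_range, mr)) stop("chromatograms must share mass_range")
  pm <- lapply(chroms, .peak_matrix)
  hits <- lapply(seq_len(K), function(i) vector("list", K))
  pruned <- 0L
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      ps <- .pair_sim_matrix(pm[[i]], pm[[j]], cfg)
      pruned <- pruned + ps$pruned
      dt <- outer(pm[[i]]$rt, pm[[j]]$rt, "-")
      bi <- t(vapply(seq_len(nrow(ps$sim)), function(r)
        .best_hit(ps$sim[r, ], dt[r, ]), numeric(2)))
      bj <- t(vapply(seq_len(ncol(ps$sim)), function(c)
        .best_hit(ps$sim[, c], dt[, c]), numeric(2)))
      hits[[i]][[j]] <- list(idx = as.integer(bi[, 1]), sim = bi[, 2])
      hits[[j]][[i]] <- list(idx = as.integer(bj[, 1]), sim = bj[, 2])
    }
  }
  structure(list(K = K, hits = hits, pruned = pruned,
                 ids = vapply(chroms, `[[`, character(1), "id")),
            class = "best_hit_store")
}

#' Find bidirectional best hits
#'
#' A peak pair (p in chromatogram i, q in chromatogram j) is a bidirectional
#' best hit (BBH) when q is p's best hit in j and p is q's best hit in i.
#'
#' @param store A `"best_hit_store"` from [compute_best_hits()].
#' @return An object of class `"bbh_graph"`: a data frame of edges
#'   `(ci, pi, cj, pj, sim)` with `ci < cj`, plus `K`.
#' @export
find_bbhs <- function(store) {
  edges <- list()
  for (i in seq_len(store$K - 1L)) {
    for (j in seq.int(i + 1L, store$K)) {
      fij <- store$hits[[i]][[j]]
      fji <- store$hits[[j]][[i]]
      p <- which(!is.na(fij$idx))
      q <- fij$idx[p]
      mutual <- !is.na(fji$idx[q]) & fji$idx[q] == p
      if (any(mutual))
        edges[[length(edges) + 1L]] <- data.frame(
          ci = i, pi = p[mutual], cj = j, pj = q[mutual],
          sim = fij$sim[p[mutual]])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(ci = integer(), pi = integer(), cj = integer(),
                           pj = integer(), sim = numeric())
  structure(list(edges = edges, K = store$K, ids = store$ids),
            class = "bbh_graph")
}

.vkey <- function(c, p) paste0(c, ":", p)
.ekey <- function(c1, p1, c2, p2) {
  sw <- c1 > c2
  paste0(ifelse(sw, c2, c1), ":", ifelse(sw, p2, p1), "|",
         ifelse(sw, c1, c2), ":", ifelse(sw, p1, p2))
}

#' Greedily merge bidirectional best hits into peak cliques
#'
#' Edges are processed in descending order of similarity; each pair of BBHs
#' is merged into a clique only when the result stays a complete subgraph of
#' the BBH graph (every member pair a BBH) with at most one peak per
#' chromatogram. A peak committed to a clique is never reassigned. Passes
#' over the edge list repeat until no assignment changes, so no reported
#' clique can be extended by an unassigned peak.
#'
#' @param g A `"bbh_graph"` from [find_bbhs()].
#' @return List of cliques; each clique is a two-column integer matrix
#'   `(chrom, peak)` with at most one row per chromatogram.
#' @export
merge_cliques <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(list())
  e <- e[order(-e$sim, e$ci, e$pi, e$cj, e$pj), , drop = FALSE]
  eset <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(e)))
    assign(.ekey(e$ci[r], e$pi[r], e$cj[r], e$pj[r]), TRUE, envir = eset)
  has_edge <- function(c1, p1, c2, p2)
    exists(.ekey(c1, p1, c2, p2), envir = eset)
  assign_id <- new.env(hash = TRUE, parent = emptyenv())
  cliques <- list()
  connected_to_all <- function(mem, ch, pk) {
    if (ch %in% mem[, 1L]) return(FALSE)
    all(vapply(seq_len(nrow(mem)), function(r)
      has_edge(mem[r, 1L], mem[r, 2L], ch, pk), logical(1)))
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(e))) {
      k1 <- .vkey(e$ci[r], e$pi[r]); k2 <- .vkey(e$cj[r], e$pj[r])
      a <- if (exists(k1, envir = assign_id)) get(k1, envir = assign_id) else NA
      b <- if (exists(k2, envir = assign_id)) get(k2, envir = assign_id) else NA
      if (is.na(a) && is.na(b)) {
        id <- length(cliques) + 1L
        cliques[[id]] <- rbind(c(e$ci[r], e$pi[r]), c(e$cj[r], e$pj[r]))
        assign(k1, id, envir = assign_id); assign(k2, id, envir = assign_id)
        changed <- TRUE
      } else if (is.na(a) || is.na(b)) {
        id <- if (is.na(a)) b else a
        ch <- if (is.na(a)) e$ci[r] else e$cj[r]
        pk <- if (is.na(a)) e$pi[r] else e$pj[r]
        k <- if (is.na(a)) k1 else k2
        if (connected_to_all(cliques[[id]], ch, pk)) {
          cliques[[id]] <- rbind(cliques[[id]], c(ch, pk))
          assign(k, id, envir = assign_id)
          changed <- TRUE
        }
      } else if (a != b) {
        A <- cliques[[a]]; B <- cliques[[b]]
        if (!any(B[, 1L] %in% A[, 1L]) &&
            all(vapply(seq_len(nrow(B)), function(rb)
              connected_to_all(A, B[rb, 1L], B[rb, 2L]), logical(1)))) {
          lo <- min(a, b); hi <- max(a, b)
          cliques[[lo]] <- rbind(cliques[[lo]],
                                 if (lo == a) B else A)
          moved <- if (lo == a) B else A
          for (rb in seq_len(nrow(moved)))
            assign(.vkey(moved[rb, 1L], moved[rb, 2L]), lo, envir = assign_id)
          cliques[[hi]] <- NULL_CLIQUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- !vapply(cliques, identical, logical(1), NULL_CLIQUE)
  lapply(cliques[keep], function(m) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    storage.mode(m) <- "integer"
    colnames(m) <- c("chrom", "peak")
    m
  })
}

NULL_CLIQUE <- matrix(integer(), ncol = 2L)

#' Peak-based multiple alignment (bidirectional best-hit cliques)
#'
#' Runs the full pipeline: best-hit computation, bidirectional best-hit
#' extraction, greedy clique merging, filtering by the minimum clique size,
#' and assembly of the alignment table ordered by median retention time.
#'
#' @param chroms List of >= 2 [chromatogram()]s with peaks.
#' @param cfg A [sim_config()].
#' @param mcs Minimum clique size (number of chromatograms a group must
#'   span), between 2 and `length(chroms)`.
#' @return An [alignment_table()] whose cells are apex scan indices (`NA` for
#'   chromatograms without a member), with attributes `cliques`,
#'   `pruned_pairs` and `clique_sizes`.
#' @export
bipace_align <- function(chroms, cfg = sim_config(), mcs = 2L) {
  K <- length(chroms)
  if (mcs < 2L || mcs > K) stop("mcs must lie in [2, K]")
  store <- compute_best_hits(chroms, cfg)
  g <- find_bbhs(store)
  cl <- merge_cliques(g)
  sizes <- vapply(cl, nrow, integer(1))
  cl <- cl[sizes >= mcs]
  ids <- vapply(chroms, `[[`, character(1), "id")
  apex <- lapply(chroms, function(c)
    vapply(c$peaks, `[[`, integer(1), "apex_scan"))
  rts <- lapply(chroms, function(c)
    vapply(c$peaks, `[[`, numeric(1), "rt"))
  cells <- matrix(NA_integer_, nrow = length(cl), ncol = K,
                  dimnames = list(NULL, ids))
  med <- numeric(length(cl))
  for (r in seq_along(cl)) {
    m <- cl[[r]]
    cells[r, m[, 1L]] <- vapply(seq_len(nrow(m)), function(q)
      apex[[m[q, 1L]]][m[q, 2L]], integer(1))
    med[r] <- stats::median(vapply(seq_len(nrow(m)), function(q)
      rts[[m[q, 1L]]][m[q, 2L]], numeric(1)))
  }
  ord <- order(med)
  tab <- alignment_table(cells[ord, , drop = FALSE], ids, med[ord])
  attr(tab, "cliques") <- cl[ord]
  attr(tab, "pruned_pairs") <- store$pruned
  attr(tab, "clique_sizes") <- sizes
  tab
}
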