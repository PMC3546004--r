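# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (enumeration, dense matrices, direct formulas) and share
# no code with the implementation paths they check.

# Brute-force DTW: enumerate every monotone continuous path from (1,1) to
# (M,N) over a similarity matrix f and return the maximal weighted path sum.
dtw_brute_force <- function(f, wts) {
  M <- nrow(f); N <- ncol(f)
  best <- -Inf
  rec <- function(i, j, acc) {
    if (i == M && j == N) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < M && j < N) rec(i + 1L, j + 1L, acc + wts$match * f[i + 1L, j + 1L])
    if (j < N) rec(i, j + 1L, acc + wts$comp * f[i, j + 1L])
    if (i < M) rec(i + 1L, j, acc + wts$exp * f[i + 1L, j])
  }
  rec(1L, 1L, wts$match * f[1L, 1L])
  best
}

# Similarity matrix for two scan-series matrices computed cell by cell with
# the scalar public functions (no BLAS shortcuts).
cellwise_f_matrix <- function(A, B, rt_a, rt_b, cfg) {
  M <- nrow(A); N <- nrow(B)
  f <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      s <- spectral_similarity(A[i, ], B[j, ], cfg$kind)
      if (cfg$use_rt_penalty) s <- s * rt_penalty(rt_a[i], rt_b[j], cfg$D)
      f[i, j] <- s
    }
  }
  f
}

# A chromatogram holding peaks with explicit spectra (no scan series).
chrom_from_peaks <- function(id, spectra, rts, mass_range = c(50L, 59L)) {
  bins <- seq.int(mass_range[1], mass_range[2])
  stopifnot(nrow(spectra) == length(bins))
  ord <- order(rts)
  peaks <- lapply(seq_along(ord), function(k)
    peak(id, k, ord[k], bins, spectra[, ord[k]], rts[ord[k]]))
  chromatogram(id, mass_range, peaks = peaks)
}

# Random peak-list instance: K chromatograms with l peaks each, continuous
# random spectra (ties have probability zero) and random retention times.
random_peak_instance <- function(K, l, L = 10L, rt_span = 60) {
  mass_range <- c(50L, 50L + L - 1L)
  lapply(seq_len(K), function(k) {
    spectra <- matrix(stats::runif(L * l), L, l)
    rts <- sort(stats::runif(l, 0, rt_span))
    chrom_from_peaks(sprintf("c%d", k), spectra, rts, mass_range)
  })
}

# Dense all-pairs peak similarity oracle: every inter-chromatogram pair via
# the scalar peak_similarity(); below-threshold pairs become NA.
dense_similarity_oracle <- function(chroms, cfg) {
  K <- length(chroms)
  out <- vector("list", K)
  for (i in seq_len(K)) {
    out[[i]] <- vector("list", K)
    for (j in seq_len(K)) {
      if (i == j) next
      li <- length(chroms[[i]]$peaks); lj <- length(chroms[[j]]$peaks)
      m <- matrix(NA_real_, li, lj)
      for (p in seq_len(li)) {
        for (q in seq_len(lj)) {
          s <- peak_similarity(chroms[[i]]$peaks[[p]], chroms[[j]]$peaks[[q]], cfg)
          if (!is_below_threshold(s)) m[p, q] <- s
        }
      }
      out[[i]][[j]] <- m
    }
  }
  out
}

# Mutual-argmax BBH edges from the dense oracle, as a sorted key vector.
bbh_edges_oracle <- function(sim) {
  K <- length(sim)
  keys <- character(0)
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      m <- sim[[i]][[j]]
      for (p in seq_len(nrow(m))) {
        row <- m[p, ]
        if (all(is.na(row))) next
        q <- which.max(row)
        col <- m[, q]
        if (which.max(col) == p)
          keys <- c(keys, sprintf("%d:%d|%d:%d", i, p, j, q))
      }
    }
  }
  sort(keys)
}

edge_keys <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(character(0))
  sort(sprintf("%d:%d|%d:%d", e$ci, e$pi, e$cj, e$pj))
}

# Completeness + maximality check for reported cliques against a BBH edge
# key set. Maximal: no peak outside any clique can be added to a clique
# while keeping it complete and one-per-chromatogram.
check_cliques <- function(cliques, g, n_peaks) {
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  for (k in edge_keys(g)) assign(k, TRUE, envir = keyset)
  has <- function(c1, p1, c2, p2) {
    if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- p1; p1 <- p2; p2 <- tmp }
    exists(sprintf("%d:%d|%d:%d", c1, p1, c2, p2), envir = keyset)
  }
  assigned <- new.env(hash = TRUE, parent = emptyenv())
  for (cl in cliques)
    for (r in seq_len(nrow(cl)))
      assign(sprintf("%d:%d", cl[r, 1L], cl[r, 2L]), TRUE, envir = assigned)
  for (cl in cliques) {
    if (anyDuplicated(cl[, 1L])) return("duplicate chromatogram in clique")
    n <- nrow(cl)
    for (a in seq_len(n - 1L))
      for (b in seq.int(a + 1L, n))
        if (!has(cl[a, 1L], cl[a, 2L], cl[b, 1L], cl[b, 2L]))
          return("clique not complete")
  }
  for (ci in seq_along(n_peaks)) {
    for (p in seq_len(n_peaks[ci])) {
      if (exists(sprintf("%d:%d", ci, p), envir = assigned)) next
      for (cl in cliques) {
        if (ci %in% cl[, 1L]) next
        ok <- all(vapply(seq_len(nrow(cl)), function(r)
          has(cl[r, 1L], cl[r, 2L], ci, p), logical(1)))
        if (ok && nrow(cl) >= 1L) return("unassigned peak extends a clique")
      }
    }
  }
  "ok"
}

# Hand-rolled bbh_graph for constructed scenarios.
make_bbh_graph <- function(edges, K) {
  structure(list(edges = edges, K = K, ids = sprintf("c%d", seq_len(K))),
            class = "bbh_graph")
}

# Independent confusion-count interpreter working on full logical tables.
confusion_oracle <- function(pairings, predicted, truth, tolerance) {
  tc <- at_cells(truth); pc <- at_cells(predicted)
  counts <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (r in seq_len(nrow(pairings))) {
    t <- pairings$truth_row[r]; p <- pairings$pred_row[r]
    if (is.na(p)) {
      counts["FN"] <- counts["FN"] + sum(!is.na(tc[t, ]))
    } else {
      tpres <- !is.na(tc[t, ]); ppres <- !is.na(pc[p, ])
      agree <- tpres & ppres & abs(tc[t, ] - pc[p, ]) <= tolerance
      counts["TP"] <- counts["TP"] + sum(agree, na.rm = TRUE)
      counts["FP"] <- counts["FP"] + sum(ppres & !tpres) +
        sum(tpres & ppres & !agree, na.rm = TRUE)
      counts["FN"] <- counts["FN"] + sum(tpres & !ppres) +
        sum(tpres & ppres & !agree, na.rm = TRUE)
      counts["TN"] <- counts["TN"] + sum(!tpres & !ppres)
    }
  }
  counts
}

# Exhaustive maximum-total-overlap assignment of truth rows to predicted
# rows (for small instances), returned as total overlap.
max_overlap_assignment <- function(predicted, truth, tolerance) {
  tc <- at_cells(truth); pc <- at_cells(predicted)
  nt <- nrow(tc); np <- nrow(pc)
  ov <- matrix(0L, nt, np)
  for (t in seq_len(nt))
    for (p in seq_len(np))
      ov[t, p] <- sum(!is.na(tc[t, ]) & !is.na(pc[p, ]) &
                        abs(tc[t, ] - pc[p, ]) <= tolerance)
  best <- 0L
  rec <- function(t, used, acc) {
    if (t > nt) { best <<- max(best, acc); return(invisible()) }
    rec(t + 1L, used, acc)  # leave t unpaired
    for (p in seq_len(np)) {
      if (!used[p] && ov[t, p] > 0L) {
        used[p] <- TRUE
        rec(t + 1L, used, acc + ov[t, p])
        used[p] <- FALSE
      }
    }
  }
  rec(1L, logical(np), 0L)
  best
}

# Fraction of scans mapped within `tol` scans of the true warp composition,
# for a profile table produced by cemapp_dtw_align on generated data.
scan_mapping_accuracy <- function(prof, gen, cfg, tol = 2L) {
  ctr <- attr(prof, "center")
  cells <- at_cells(prof)
  grid <- gen$chromatograms[[1]]$scan_rts
  fine <- seq(0, cfg$rt_span, length.out = 5000L)
  ok <- 0L; tot <- 0L
  for (o in setdiff(seq_len(cfg$K), ctr)) {
    u <- stats::approx(gen$warps[[ctr]](fine), fine, xout = grid)$y
    t_o <- gen$warps[[o]](u)
    true_scan <- round(stats::approx(grid, seq_along(grid), xout = t_o,
                                     rule = 2)$y)
    ok <- ok + sum(abs(cells[, o] - true_scan) <= tol)
    tot <- tot + length(true_scan)
  }
  ok / tot
}

# Attach a handful of peaks to a chromatogram from its own scans.
read_peak_list_fixture <- function(ch, apexes = c(5L, 15L, 30L)) {
  bins <- seq.int(ch$mass_range[1], ch$mass_range[2])
  ch$peaks <- lapply(seq_along(apexes), function(i)
    peak(ch$id, i, apexes[i], bins, ch$scans[apexes[i], ],
         ch$scan_rts[apexes[i]]))
  ch
}
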