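test_that("anchor filtering keeps a longest monotone chain and drops adjacent anchors", {
  expect_equal(filter_anchors(rbind(c(10, 12), c(20, 18), c(15, 25))),
               rbind(c(10L, 12L), c(20L, 18L)), ignore_attr = TRUE)
  mono <- rbind(c(5L, 7L), c(10L, 14L), c(30L, 31L))
  expect_equal(filter_anchors(mono), mono, ignore_attr = TRUE)
  expect_equal(nrow(filter_anchors(matrix(integer(), ncol = 2))), 0L)
  # directly neighbouring anchors collapse to the first
  adj <- rbind(c(5L, 5L), c(6L, 6L), c(7L, 7L), c(20L, 21L))
  out <- filter_anchors(adj)
  expect_equal(out[, 1], c(5L, 7L, 20L), ignore_attr = TRUE)
  # LIS minimality: kept size equals the longest strictly-increasing chain
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    pairs <- cbind(sample(1:50, n), sample(1:50, n))
    out <- filter_anchors(pairs)
    expect_true(all(diff(out[, 1]) > 0) && all(diff(out[, 2]) > 0))
    # oracle: longest chain over all subsets (n small)
    best <- 0L
    for (msk in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(msk, 2^(seq_len(n) - 1L)) > 0)
      sub <- pairs[sel, , drop = FALSE]
      sub <- sub[order(sub[, 1]), , drop = FALSE]
      if (nrow(sub) < 2 || (all(diff(sub[, 1]) > 0) && all(diff(sub[, 2]) > 0)))
        best <- max(best, nrow(sub))
    }
    # adjacency pruning may remove further anchors, never the chain order
    expect_lte(nrow(out), best)
    kept_no_adj <- sum(c(TRUE, !(diff(out[, 1]) <= 1 & diff(out[, 2]) <= 1)))
    expect_equal(nrow(out), kept_no_adj)
  }
})

test_that("layouts: unconstrained limit, anchor pinching, band monotonicity", {
  full <- build_layout(M = 8, N = 11, band_width = 1)
  expect_true(all(full$lo == 1L) && all(full$hi == 11L))
  expect_equal(full$cells, 8L * 11L)

  anc <- rbind(c(3L, 3L), c(6L, 6L))
  lay <- build_layout(anchors = anc, r = 0, M = 9, N = 9)
  expect_equal(lay$lo[3], 3L); expect_equal(lay$hi[3], 3L)
  expect_equal(lay$lo[6], 6L); expect_equal(lay$hi[6], 6L)

  small <- build_layout(M = 60, N = 60, band_width = 0.1, band_scope = "local")
  large <- build_layout(M = 60, N = 60, band_width = 0.5, band_scope = "local")
  expect_lte(small$cells, large$cells)

  # monotone interval bounds and diagonal connectivity
  set.seed(32)
  for (rep in 1:8) {
    M <- sample(10:40, 1); N <- sample(10:40, 1)
    n_anc <- sample(0:3, 1)
    anc <- if (n_anc) cbind(sort(sample(2:(M - 1), n_anc)),
                            sort(sample(2:(N - 1), n_anc))) else NULL
    lay <- build_layout(anchors = anc, r = sample(0:2, 1),
                        band_width = runif(1, 0.1, 1),
                        band_scope = sample(c("global", "local"), 1),
                        M = M, N = N)
    expect_true(all(diff(lay$lo) >= 0))
    expect_true(all(diff(lay$hi) >= 0))
    expect_true(all(lay$lo <= lay$hi))
    expect_equal(lay$lo[1], 1L)
    expect_equal(lay$hi[M], N)
    if (M > 1) {
      expect_true(all(lay$lo[-1] <= lay$hi[-M] + 1L))
    }
  }
})

test_that("stored-cell count stays within the banded budget", {
  for (w in c(0.05, 0.1, 0.3)) {
    M <- 120; N <- 100
    lay <- build_layout(M = M, N = N, band_width = w, band_scope = "global")
    h <- ceiling(w * max(M, N))
    expect_lte(lay$cells, (2 * h + 3) * (max(M, N) + 1))
  }
})

test_that("partitioned array get/set semantics honor the static layout", {
  lay <- build_layout(M = 6, N = 8, band_width = 0.3, band_scope = "global")
  pa <- partitioned_array(lay, default_value = -Inf)
  adm <- matrix(FALSE, 6, 8)
  for (i in 1:6) adm[i, lay$lo[i]:lay$hi[i]] <- TRUE
  set.seed(33)
  for (i in 1:6) {
    for (j in 1:8) {
      x <- rnorm(1)
      pa2 <- pa_set(pa, i, j, x)
      if (adm[i, j]) {
        expect_identical(pa_get(pa2, i, j), x)
      } else {
        expect_identical(pa_get(pa2, i, j), -Inf)
        expect_identical(pa2$d, pa$d)  # set outside layout is a no-op
      }
    }
  }
  expect_identical(pa_get(pa, 0, 1), -Inf)
  expect_identical(pa_get(pa, 7, 1), -Inf)
})

test_that("a single-cell problem returns the forced first alignment", {
  A <- matrix(c(1, 2, 3), 1, 3)
  B <- matrix(c(2, 4, 6), 1, 3)
  cfg <- sim_config("cosine", FALSE)
  al <- dtw_align(A, B, cfg, dtw_weights(match = 2.25))
  expect_equal(al$path, cbind(i = 1L, j = 1L), ignore_attr = TRUE)
  expect_equal(al$score, 2.25 * 1)
  expect_equal(al$score_corrected, 1)
})

test_that("identical series with dominant match weight align along the diagonal", {
  set.seed(34)
  A <- matrix(runif(20 * 6), 20, 6)
  al <- dtw_align(A, A, sim_config("cosine", FALSE),
                  dtw_weights(match = 2.25, comp = 1, exp = 1))
  expect_equal(al$path[, 1], 1:20, ignore_attr = TRUE)
  expect_equal(al$path[, 2], 1:20, ignore_attr = TRUE)
  expect_equal(al$score_corrected, 1, tolerance = 1e-12)
})

test_that("unconstrained DTW equals brute-force path enumeration for every kind", {
  set.seed(35)
  kinds <- c("cosine", "dot", "euclidean", "linCorr", "rankCorr")
  for (kind in kinds) {
    for (rep in 1:6) {
      M <- sample(2:6, 1); N <- sample(2:6, 1); L <- 8
      A <- matrix(runif(M * L), M, L)
      B <- matrix(runif(N * L), N, L)
      rt_a <- sort(runif(M, 0, 30)); rt_b <- sort(runif(N, 0, 30))
      use_pen <- rep %% 2 == 0
      cfg <- sim_config(kind, use_pen, D = 10, T = 0)
      wts <- dtw_weights(match = runif(1, 1, 3), comp = runif(1, 0.5, 1.5),
                         exp = runif(1, 0.5, 1.5))
      al <- dtw_align(A, B, cfg, wts, rt_a = rt_a, rt_b = rt_b)
      f <- cellwise_f_matrix(A, B, rt_a, rt_b, cfg)
      expect_equal(al$score, dtw_brute_force(f, wts), tolerance = 1e-9)
      # path validity
      d <- diff(al$path)
      expect_true(all(d >= 0) && all(d <= 1) && all(rowSums(d) > 0))
      expect_lt(nrow(al$path), 2 * max(M, N) + 1)
    }
  }
})

test_that("row-compressed DP reproduces the dense recursion bit for bit", {
  set.seed(36)
  for (rep in 1:15) {
    M <- sample(3:14, 1); N <- sample(3:14, 1)
    f <- matrix(rnorm(M * N), M, N)
    wts <- dtw_weights(match = runif(1, 1, 3))
    a <- dtw_dp(f, wts)                       # full layout, RCS storage
    b <- chromalign:::dtw_dp_dense(f, wts)    # dense reference
    expect_identical(a$score, b$score)
    expect_identical(unname(a$path), unname(b$path))
    expect_identical(a$moves, b$moves)
    expect_identical(a$score_corrected, b$score_corrected)
  }
})

test_that("with radius zero every path visits every anchor", {
  set.seed(37)
  for (rep in 1:10) {
    M <- sample(15:30, 1); N <- sample(15:30, 1)
    n_anc <- sample(1:3, 1)
    anc <- cbind(sort(sample(3:(M - 2), n_anc)), sort(sample(3:(N - 2), n_anc)))
    lay <- build_layout(anchors = anc, r = 0, band_width = 1, M = M, N = N)
    f <- matrix(runif(M * N), M, N)
    al <- dtw_dp(f, dtw_weights(), lay)
    anc <- lay$anchors
    for (k in seq_len(nrow(anc)))
      expect_true(any(al$path[, 1] == anc[k, 1] & al$path[, 2] == anc[k, 2]))
  }
})

test_that("weight-corrected scores are symmetric when compression equals expansion", {
  set.seed(38)
  A <- matrix(runif(12 * 5), 12, 5)
  B <- matrix(runif(9 * 5), 9, 5)
  cfg <- sim_config("cosine", FALSE)
  wts <- dtw_weights(match = 2.25, comp = 1, exp = 1)
  ab <- dtw_align(A, B, cfg, wts)
  ba <- dtw_align(B, A, cfg, wts)
  expect_equal(ab$score, ba$score, tolerance = 1e-12)
  expect_equal(ab$score_corrected, ba$score_corrected, tolerance = 1e-12)
})

test_that("similarity maxima along a path match a direct neighbour scan", {
  expect_equal(extract_similarity_maxima(c(0.1, 0.9, 0.1)), 2L)
  expect_equal(extract_similarity_maxima(c(0.1, 0.2, 0.5, 0.9)), 4L)
  expect_equal(extract_similarity_maxima(c(0.1, 0.5, 0.5, 0.2, 0.7)), c(2L, 5L))
  expect_length(extract_similarity_maxima(rep(0.3, 4)), 0L)
  set.seed(39)
  for (rep in 1:10) {
    f <- runif(sample(5:30, 1))
    got <- extract_similarity_maxima(f)
    want <- which(vapply(seq_along(f), function(k) {
      (k == 1 || f[k - 1] < f[k]) && (k == length(f) || f[k + 1] < f[k])
    }, logical(1)))
    expect_equal(got, want)
  }
})

test_that("center selection maximizes the score sum with deterministic ties", {
  s <- matrix(0, 3, 3)
  s[1, 2] <- s[2, 1] <- 0.9
  s[1, 3] <- s[3, 1] <- 0.2
  s[2, 3] <- s[3, 2] <- 0.8
  expect_equal(select_center(s), 2L)
  expect_equal(select_center(matrix(c(0, 1, 1, 0), 2, 2)), 1L)
  expect_equal(select_center(s + 0.05 * (1 - diag(3))), 2L)
  expect_error(select_center(matrix(1, 1, 1)), "at least 2")
})

test_that("identical chromatograms produce the identity profile alignment", {
  set.seed(40)
  scans <- matrix(runif(25 * 6), 25, 6)
  chroms <- lapply(1:3, function(k)
    chromatogram(sprintf("c%d", k), c(50, 55), scans = scans, scan_rts = 1:25))
  tab <- cemapp_dtw_align(chroms, sim_config("cosine", FALSE),
                          dtw_weights(2.25), band_width = 1)
  cells <- at_cells(tab)
  for (k in 1:3) expect_equal(cells[, k], 1:25, ignore_attr = TRUE)
  expect_false(any(is.na(cells)))
})
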