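test_that("two identical single-peak chromatograms are each other's best hit", {
  sp <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), ncol = 1)
  c1 <- chrom_from_peaks("c1", sp, 10)
  c2 <- chrom_from_peaks("c2", sp, 10)
  store <- compute_best_hits(list(c1, c2), sim_config("cosine", TRUE, D = 5, T = 0))
  expect_equal(store$hits[[1]][[2]]$idx, 1L)
  expect_equal(store$hits[[2]][[1]]$idx, 1L)
  g <- find_bbhs(store)
  expect_equal(nrow(g$edges), 1L)
})

test_that("pairs outside the retention-time window are pruned from candidacy", {
  set.seed(21)
  sp <- matrix(runif(20), 10, 2)
  c1 <- chrom_from_peaks("c1", sp, c(10, 500))
  c2 <- chrom_from_peaks("c2", sp, c(11, 499))
  cfg <- sim_config("cosine", TRUE, D = 5, T = 0.1)
  store <- compute_best_hits(list(c1, c2), cfg)
  # each peak can only hit its temporal counterpart; distant pairs pruned
  expect_equal(store$hits[[1]][[2]]$idx, c(1L, 2L))
  expect_gt(store$pruned, 0L)
})

test_that("best hits and BBH edges equal the dense brute-force oracle", {
  set.seed(22)
  for (rep in 1:12) {
    K <- sample(2:3, 1)
    chroms <- random_peak_instance(K, sample(4:10, 1))
    kind <- sample(c("cosine", "dot", "linCorr"), 1)
    cfg <- sim_config(kind, TRUE, D = runif(1, 5, 20), T = runif(1, 0, 0.3))
    store <- compute_best_hits(chroms, cfg)
    sim <- dense_similarity_oracle(chroms, cfg)
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (i == j) next
        for (p in seq_along(chroms[[i]]$peaks)) {
          row <- sim[[i]][[j]][p, ]
          if (all(is.na(row))) expect_true(is.na(store$hits[[i]][[j]]$idx[p]))
          else expect_equal(store$hits[[i]][[j]]$idx[p], which.max(row))
        }
      }
    }
    expect_identical(edge_keys(find_bbhs(store)), bbh_edges_oracle(sim))
  }
})

test_that("a fully mutual three-way hit merges into one clique of size three", {
  e <- data.frame(ci = c(1L, 1L, 2L), pi = c(1L, 1L, 1L),
                  cj = c(2L, 3L, 3L), pj = c(1L, 1L, 1L),
                  sim = c(0.9, 0.8, 0.85))
  cl <- merge_cliques(make_bbh_graph(e, 3L))
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 3L)
})

test_that("a missing mutual link blocks the three-way clique", {
  # C1-C2 and C2-C3 are BBHs, but chromatogram 3's peak pairs with a
  # different peak (B) in chromatogram 1: no clique may span C1, C2, C3.
  e <- data.frame(ci = c(1L, 2L, 1L), pi = c(1L, 1L, 2L),
                  cj = c(2L, 3L, 3L), pj = c(1L, 1L, 1L),
                  sim = c(0.9, 0.8, 0.7))
  cl <- merge_cliques(make_bbh_graph(e, 3L))
  expect_true(all(vapply(cl, nrow, integer(1)) == 2L))
  # peak disjointness: chromatogram 3 peak 1 appears exactly once
  occ <- sum(vapply(cl, function(m) any(m[, 1] == 3 & m[, 2] == 1), logical(1)))
  expect_equal(occ, 1L)
})

test_that("reported cliques are complete, maximal and peak-disjoint on random instances", {
  set.seed(23)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    l <- sample(3:8, 1)
    chroms <- random_peak_instance(K, l)
    cfg <- sim_config(sample(c("cosine", "dot"), 1), TRUE,
                      D = runif(1, 10, 40), T = 0)
    g <- find_bbhs(compute_best_hits(chroms, cfg))
    cl <- merge_cliques(g)
    expect_identical(check_cliques(cl, g, rep(l, K)), "ok")
    keys <- unlist(lapply(cl, function(m) sprintf("%d:%d", m[, 1], m[, 2])))
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("cliques agree with igraph's maximal clique enumeration", {
  skip_if_not_installed("igraph")
  set.seed(24)
  for (rep in 1:10) {
    K <- sample(3:4, 1)
    l <- sample(4:8, 1)
    chroms <- random_peak_instance(K, l)
    g <- find_bbhs(compute_best_hits(chroms, sim_config("cosine", TRUE, D = 30, T = 0)))
    if (!nrow(g$edges)) next
    vk <- unique(c(sprintf("%d:%d", g$edges$ci, g$edges$pi),
                   sprintf("%d:%d", g$edges$cj, g$edges$pj)))
    ig <- igraph::graph_from_edgelist(
      cbind(sprintf("%d:%d", g$edges$ci, g$edges$pi),
            sprintf("%d:%d", g$edges$cj, g$edges$pj)), directed = FALSE)
    maxcl <- lapply(igraph::max_cliques(ig), function(v)
      sort(igraph::V(ig)$name[v]))
    for (cl in merge_cliques(g)) {
      keys <- sort(sprintf("%d:%d", cl[, 1], cl[, 2]))
      # every reported clique is a subset of some maximal clique of the
      # BBH graph (completeness); equality holds when no member was
      # claimed by an earlier-merged clique
      expect_true(any(vapply(maxcl, function(mc) all(keys %in% mc), logical(1))))
    }
  }
})

test_that("alignment table respects MCS filtering, ordering and disjointness", {
  set.seed(25)
  # 3 chromatograms sharing 6 template peaks with small rt jitter
  L <- 12; n <- 6
  tpl <- matrix(runif(L * n), L, n)
  rts <- seq(10, 60, length.out = n)
  chroms <- lapply(1:3, function(k)
    chrom_from_peaks(sprintf("c%d", k), tpl, rts + runif(n, -1, 1),
                     c(50L, 50L + L - 1L)))
  cfg <- sim_config("cosine", TRUE, D = 5, T = 0)
  t2 <- bipace_align(chroms, cfg, mcs = 2)
  t3 <- bipace_align(chroms, cfg, mcs = 3)
  expect_gte(nrow(t2), nrow(t3))
  expect_true(all(diff(t2$median_rt) >= 0))
  # MCS = K rows have no absent cells
  expect_false(any(is.na(at_cells(t3))))
  # rows at larger MCS are a subset of rows at MCS 2
  key <- function(tab) apply(at_cells(tab), 1, paste, collapse = "/")
  expect_true(all(key(t3) %in% key(t2)))
  expect_error(bipace_align(chroms, cfg, mcs = 1), "mcs")
  expect_error(bipace_align(chroms, cfg, mcs = 4), "mcs")
})

test_that("threshold small enough to prune nothing reproduces the T = 0 result", {
  set.seed(26)
  chroms <- random_peak_instance(3, 6, rt_span = 20)
  c0 <- sim_config("cosine", TRUE, D = 50, T = 0)
  c1 <- sim_config("cosine", TRUE, D = 50, T = 1e-12)
  a0 <- bipace_align(chroms, c0, 2)
  a1 <- bipace_align(chroms, c1, 2)
  expect_equal(at_cells(a0), at_cells(a1))
})
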