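#' Similarity configuration
#'
#' Bundles the spectral similarity kind, the optional Gaussian retention-time
#' penalty with tolerance width `D`, and the penalty threshold `T` below
#' which a peak pair is pruned before its spectral similarity is evaluated.
#'
#' @param kind One of `"cosine"`, `"dot"`, `"euclidean"` (negated Euclidean
#'   distance), `"linCorr"` (Pearson), `"rankCorr"` (Spearman), or a custom
#'   function `f(u, v)`.
#' @param use_rt_penalty Multiply the spectral similarity by
#'   `exp(-(t_p - t_q)^2 / (2 D^2))`?
#' @param D Retention-time tolerance width in seconds (> 0 when the penalty
#'   is used).
#' @param T Threshold in `[0, 1]` on the penalty value; pairs whose penalty
#'   falls below `T` are reported as below-threshold without evaluating the
#'   spectral similarity.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(kind = c("cosine", "dot", "euclidean", "linCorr", "rankCorr"),
                       use_rt_penalty = TRUE, D = 2.5, T = 0) {
  if (!is.function(kind)) kind <- match.arg(kind)
  if (use_rt_penalty && D <= 0) stop("D must be > 0 when use_rt_penalty")
  if (T < 0 || T > 1) stop("T must lie in [0, 1]")
  structure(list(kind = kind, use_rt_penalty = use_rt_penalty,
                 D = as.numeric(D), T = as.numeric(T)),
            class = "sim_config")
}

#' Gaussian retention-time penalty
#'
#' `exp(-(t_p - t_q)^2 / (2 D^2))`: 1 for perfect retention-time
#' correspondence, decaying towards 0 as the difference grows relative to the
#' tolerance `D`.
#'
#' @param t_p,t_q Retention times in seconds.
#' @param D Tolerance width in seconds (> 0).
#' @return Value in `(0, 1]`; vectorized over `t_p`/`t_q`.
#' @export
rt_penalty <- function(t_p, t_q, D) {
  if (D <= 0) stop("D must be > 0")
  exp(-(t_p - t_q)^2 / (2 * D^2))
}

#' Spectral similarity between two binned mass spectra
#'
#' Degenerate inputs (all-zero vectors for the normalized kinds, constant
#' vectors for the correlation kinds) yield 0 rather than NaN: a noise-only
#' spectrum carries no matching information.
#'
#' @param u,v Numeric vectors of equal length.
#' @param kind Similarity kind as in [sim_config()].
#' @return Scalar similarity. Cosine and the correlations lie in `[-1, 1]`;
#'   the negated Euclidean distance is `<= 0`; the dot product is unbounded.
#' @export
spectral_similarity <- function(u, v, kind = "cosine") {
  if (length(u) != length(v)) stop("spectra must have equal length")
  if (is.function(kind)) return(kind(u, v))
  switch(kind,
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
    },
    dot = sum(u * v),
    euclidean = -sqrt(sum((u - v)^2)),
    linCorr = {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) 0
      else stats::cor(u, v, method = "pearson")
    },
    rankCorr = {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) 0
      else stats::cor(u, v, method = "spearman")
    },
    stop("unknown similarity kind: ", kind))
}

#' Below-threshold sentinel
#'
#' Returned by [peak_similarity()] when the retention-time penalty falls
#' below the threshold `T`, so that callers can count pruned pairs; it is a
#' distinct object rather than `-Inf` arithmetic.
#'
#' @export
BELOW_THRESHOLD <- structure(list(), class = "below_threshold")

#' Test for the below-threshold sentinel
#' @param x Object to test.
#' @export
is_below_threshold <- function(x) inherits(x, "below_threshold")

#' Penalized similarity between two peaks
#'
#' When the retention-time penalty is enabled, the penalty is evaluated
#' first; if it falls below `cfg$T` the spectral similarity is never
#' computed and [BELOW_THRESHOLD] is returned. Otherwise the product of the
#' spectral similarity and the penalty is returned.
#'
#' @param p,q [peak()] objects binned over the same mass range.
#' @param cfg A [sim_config()].
#' @return Scalar similarity, or [BELOW_THRESHOLD].
#' @export
peak_similarity <- function(p, q, cfg = sim_config()) {
  if (!identical(length(p$intensities), length(q$intensities)))
    stop("peaks must be binned over the same mass range")
  if (!cfg$use_rt_penalty)
    return(spectral_similarity(p$intensities, q$intensities, cfg$kind))
  pen <- rt_penalty(p$rt, q$rt, cfg$D)
  if (pen < cfg$T) return(BELOW_THRESHOLD)
  spectral_similarity(p$intensities, q$intensities, cfg$kind) * pen
}

# ---- vectorized internals -------------------------------------------------

# Column-wise transform of an L x n spectrum matrix so that every similarity
# kind reduces to a plain dot product between transformed columns (plus a
# post-transform for the negated Euclidean distance). Degenerate columns
# (zero norm / constant) are zeroed so they score 0 against everything.
.prep_spectra <- function(M, kind) {
  if (kind == "dot" || kind == "euclidean") return(M)
  if (kind == "rankCorr") M <- apply(M, 2, rank)
  if (kind %in% c("linCorr", "rankCorr"))
    M <- sweep(M, 2, colMeans(M), "-")
  nrm <- sqrt(colSums(M^2))
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M[, !nz] <- 0
  M
}

# Dense spectral-similarity matrix between the columns of two L x n matrices,
# consistent with spectral_similarity() up to floating-point error.
.sim_matrix <- function(A, B, kind) {
  if (is.function(kind)) {
    out <- matrix(0, ncol(A), ncol(B))
    for (i in seq_len(ncol(A)))
      for (j in seq_len(ncol(B)))
        out[i, j] <- kind(A[, i], B[, j])
    return(out)
  }
  Ap <- .prep_spectra(A, kind)
  Bp <- .prep_spectra(B, kind)
  s <- crossprod(Ap, Bp)
  if (kind == "euclidean") {
    na <- colSums(Ap^2); nb <- colSums(Bp^2)
    s <- -sqrt(pmax(outer(na, nb, "+") - 2 * s, 0))
  }
  s
}
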