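# Seeded synthetic GC-MS chromatogram generator. K chromatograms share a set
# of planted spectral templates; each realization applies a smooth monotone
# retention-time warp, lognormal intensity scaling, Bernoulli peak dropout,
# Gaussian spectral noise and a constant baseline. The planted group
# structure is returned as a ground-truth alignment table, so every aligner
# in the package can be scored without external data.

#' Synthetic chromatogram configuration
#'
#' @param K Number of chromatograms.
#' @param n_groups Number of planted peak groups.
#' @param mass_range Inclusive integer mass range (Da).
#' @param scans_per_chrom Scans per chromatogram.
#' @param rt_span Run length in seconds.
#' @param warp_amplitude Maximum absolute retention-time shift (s).
#' @param warp_knots Number of interior knots of the warp spline.
#' @param dropout_prob Per-peak dropout probability in `[0, 1)`.
#' @param intensity_cv Lognormal coefficient of variation of peak amplitudes.
#' @param spectral_noise_sd Gaussian noise standard deviation, relative to
#'   the base peak amplitude (100).
#' @param baseline_level Constant baseline intensity.
#' @param peak_sigma Chromatographic peak width (Gaussian sigma, s).
#' @param min_rt_spacing Minimum spacing between planted reference RTs (s).
#' @param n_fragments Integer pair: range of nonzero fragment bins per
#'   template.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(K = 5L, n_groups = 50L, mass_range = c(50L, 550L),
                         scans_per_chrom = 600L, rt_span = 600,
                         warp_amplitude = 10, warp_knots = 4L,
                         dropout_prob = 0, intensity_cv = 0.3,
                         spectral_noise_sd = 0.01, baseline_level = 0.5,
                         peak_sigma = 3, min_rt_spacing = 4,
                         n_fragments = c(5L, 30L), seed = 1L) {
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)")
  if (warp_amplitude < 0) stop("warp_amplitude must be >= 0")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate planted spectral templates and reference retention times
#'
#' Each template is a sparse nonnegative unit-norm spectrum with 5-30
#' nonzero fragment bins; rejection sampling keeps all pairwise cosines below
#' 0.95 so no two templates are spectrally confusable. Reference RTs are
#' spread over the run with a minimum spacing.
#'
#' @param cfg A [synth_config()].
#' @return List with `spectra` (bins x n_groups matrix) and `ref_rt`.
#' @export
make_templates <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$mass_range[2] - cfg$mass_range[1] + 1L
  spectra <- matrix(0, L, cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    repeat {
      nf <- sample(cfg$n_fragments[1]:cfg$n_fragments[2], 1L)
      v <- numeric(L)
      v[sample.int(L, nf)] <- stats::rexp(nf)
      v <- v / sqrt(sum(v^2))
      if (g == 1L) { spectra[, g] <- v; break }
      cosines <- crossprod(spectra[, seq_len(g - 1L), drop = FALSE], v)
      if (max(cosines) < 0.95) { spectra[, g] <- v; break }
    }
  }
  # reference RTs with minimum spacing, away from the run edges
  margin <- 0.05 * cfg$rt_span
  usable <- cfg$rt_span - 2 * margin
  if ((cfg$n_groups - 1L) * cfg$min_rt_spacing > usable)
    stop("rt_span too small for n_groups at min_rt_spacing")
  for (try in 1:200) {
    rts <- sort(stats::runif(cfg$n_groups, margin, cfg$rt_span - margin))
    if (cfg$n_groups < 2L || min(diff(rts)) >= cfg$min_rt_spacing) break
    rts <- NULL
  }
  if (is.null(rts)) { # deterministic fallback: jittered even spacing
    rts <- seq(margin, cfg$rt_span - margin, length.out = cfg$n_groups)
  }
  list(spectra = spectra, ref_rt = rts)
}

#' Generate the monotone retention-time warp of one chromatogram
#'
#' A strictly increasing monotone cubic spline through `warp_knots` random
#' knot offsets bounded by `warp_amplitude`; chromatogram 1 is the identity.
#' Elution order is preserved because knot spacing exceeds twice the
#' amplitude.
#'
#' @param cfg A [synth_config()].
#' @param k Chromatogram index (1-based).
#' @return A function mapping reference RT (s) to observed RT (s).
#' @export
make_warp <- function(cfg, k) {
  if (k == 1L || cfg$warp_amplitude == 0) return(identity)
  set.seed(cfg$seed + 97L * k)
  x <- seq(0, cfg$rt_span, length.out = cfg$warp_knots + 2L)
  off <- c(0, stats::runif(cfg$warp_knots, -cfg$warp_amplitude,
                           cfg$warp_amplitude), 0)
  y <- x + off
  if (any(diff(y) <= 0)) stop("warp_amplitude too large for knot spacing")
  stats::splinefun(x, y, method = "hyman")
}

#' Generate synthetic chromatograms and their ground-truth alignment
#'
#' Every planted group is realized in every chromatogram unless dropped
#' (Bernoulli `dropout_prob`; chromatogram 1 never drops, so each group
#' keeps at least one member). A realized peak is the group template scaled
#' by a lognormal amplitude, placed at the warped retention time with a
#' Gaussian elution profile; scans additionally carry a constant baseline
#' and truncated Gaussian spectral noise. Fully deterministic under the
#' seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `chromatograms` (list of [chromatogram()]s carrying
#'   peaks and scans) and `truth` (an [alignment_table()] of apex scans,
#'   `NA` where dropped, ordered by median reference RT), plus `warps` and
#'   `templates`.
#' @export
synth_generate <- function(cfg) {
  tpl <- make_templates(cfg)
  grid_rt <- seq(0, cfg$rt_span, length.out = cfg$scans_per_chrom)
  base_amp <- 100
  chroms <- vector("list", cfg$K)
  warps <- vector("list", cfg$K)
  apex_tab <- matrix(NA_integer_, cfg$n_groups, cfg$K)
  L <- cfg$mass_range[2] - cfg$mass_range[1] + 1L
  for (k in seq_len(cfg$K)) {
    warps[[k]] <- make_warp(cfg, k)
    set.seed(cfg$seed + 10007L * k)
    drop <- if (k == 1L) rep(FALSE, cfg$n_groups)
            else stats::runif(cfg$n_groups) < cfg$dropout_prob
    amp <- base_amp * stats::rlnorm(cfg$n_groups, 0, cfg$intensity_cv)
    scans <- matrix(cfg$baseline_level, cfg$scans_per_chrom, L)
    obs_rt <- warps[[k]](tpl$ref_rt)
    sigma_scans <- cfg$peak_sigma
    for (g in seq_len(cfg$n_groups)) {
      if (drop[g]) next
      apex <- which.min(abs(grid_rt - obs_rt[g]))
      apex_tab[g, k] <- apex
      shape <- exp(-(grid_rt - grid_rt[apex])^2 / (2 * sigma_scans^2))
      keep <- shape > 1e-4
      scans[keep, ] <- scans[keep, ] +
        outer(shape[keep] * amp[g], tpl$spectra[, g])
    }
    if (cfg$spectral_noise_sd > 0)
      scans <- pmax(scans + matrix(
        stats::rnorm(length(scans), 0, cfg$spectral_noise_sd * base_amp),
        nrow(scans)), 0)
    bins <- seq.int(cfg$mass_range[1], cfg$mass_range[2])
    id <- sprintf("synth%02d", k)
    apexes <- sort(apex_tab[!is.na(apex_tab[, k]), k])
    peaks <- lapply(seq_along(apexes), function(p)
      peak(id, p, apexes[p], bins, scans[apexes[p], ], grid_rt[apexes[p]]))
    chroms[[k]] <- chromatogram(id, cfg$mass_range, scans = scans,
                                scan_rts = grid_rt, peaks = peaks)
  }
  ord <- order(tpl$ref_rt)
  med <- vapply(seq_len(cfg$n_groups), function(g) {
    present <- which(!is.na(apex_tab[g, ]))
    stats::median(vapply(present, function(k)
      grid_rt[apex_tab[g, k]], numeric(1)))
  }, numeric(1))
  truth <- alignment_table(apex_tab[ord, , drop = FALSE],
                           vapply(chroms, `[[`, character(1), "id"),
                           med[ord])
  list(chromatograms = chroms, truth = truth, warps = warps,
       templates = tpl)
}
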