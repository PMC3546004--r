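---
title: "Aligning multiple GC-MS chromatograms: peak cliques, constrained warping, and their hybrid"
author: "chromalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning multiple GC-MS chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromalign)
```

## The problem

A GC-MS run produces a time-ordered series of mass spectra (scans). Run-to-run
fluctuations of the chromatographic system distort the time axis nonlinearly,
so the same analyte elutes at slightly different retention times in different
runs. Before any differential analysis, corresponding signals across runs must
be matched. `chromalign` implements two complementary aligners and a hybrid of
the two:

* a **peak-based multiple aligner** that groups previously detected peaks
  across K chromatograms into cliques of mutual best matches, and
* a **profile aligner** that warps whole scan series onto a common reference
  by dynamic time warping (DTW), assigning *every* scan,
* a **hybrid** in which the high-confidence peak cliques become anchors that
  the warping path must pass, shrinking the DTW search space.

## Penalized spectral similarity

Two peaks $p = (\mathbf m_p, \mathbf i_p, t_p)$ and
$q = (\mathbf m_q, \mathbf i_q, t_q)$ (nominal-mass vector, intensity vector,
retention time) are compared with

$$ f(p, q) = s(p, q)\,\exp\!\left(-\frac{(t_p - t_q)^2}{2 D^2}\right), $$

where $s$ is a spectral similarity — cosine by default; the dot product, the
negated Euclidean distance, Pearson's or Spearman's correlation are
alternatives — and the Gaussian factor penalizes retention-time differences
relative to a tolerance width $D$ (seconds). The penalty is 1 at perfect
correspondence and decays to 0; a threshold $T \in [0, 1]$ on the penalty
value short-circuits the (costly) spectral similarity for distant pairs,
which the implementation reports through a distinct below-threshold sentinel
so pruned pairs can be counted rather than silently treated as $-\infty$.

Degenerate spectra (all-zero vectors, or constant vectors for the
correlation kinds) score 0 against everything: a noise-only scan carries no
matching information, and returning 0 avoids NaN propagation.

**Parameters.** $D$ should reflect the expected retention-time spread of the
same analyte across runs (a few seconds for technical replicates, tens of
seconds across batches). $T$ trades completeness for speed; it does not
correspond directly to a time window and is best kept small.

## Peak-clique multiple alignment

All peak pairs from *distinct* chromatograms are scored with $f$ (self
similarities within a chromatogram are never computed). Conceptually this is
a K-partite edge-weighted graph; enumerating its cliques directly is
NP-complete, so the graph is pruned in two steps:

1. **Best hits.** For every peak, only its highest-similarity match in each
   other chromatogram is kept (ties broken by smaller retention-time
   difference, then lower peak index — the similarity function does not
   define an order on exact ties, so determinism is imposed explicitly).
2. **Bidirectional best hits (BBHs).** An edge survives only if both peaks
   are each other's best hit — the same mutuality criterion used for
   orthologous gene matching. On the resulting sparse unweighted graph the
   maximal-clique problem is polynomial.

BBH edges are then merged greedily into cliques with at most one peak per
chromatogram, processing edges in descending similarity so the strongest
evidence is consolidated first. A merge is accepted only if the result stays
*complete* (every member pair a BBH); a peak committed to a clique is never
reassigned, which keeps the output rows disjoint. Passes over the edge list
repeat until nothing changes, so no reported clique can be extended by a
still-unassigned peak. Cliques with at least `mcs` members (the minimum
clique size) become the rows of the multiple alignment table, ordered by
their median retention time; chromatograms without a member are marked
absent. `mcs = K` reports only full-width groups; small values report more
groups at the price of weakly supported ones.

## Profile alignment by constrained DTW

Two scan series $A = (a_1,\dots,a_M)$ and $B = (b_1,\dots,b_N)$ are aligned
by maximizing the sum of step-weighted similarities over all monotone,
continuous warping paths from $(1,1)$ to $(M,N)$:

$$ Q(i,j) = \max\begin{cases}
Q(i-1,j-1) + w_{\mathrm{match}}\, f(a_i, b_j)\\
Q(i,j-1) + w_{\mathrm{comp}}\, f(a_i, b_j)\\
Q(i-1,j) + w_{\mathrm{exp}}\, f(a_i, b_j)
\end{cases} $$

with row 0 and column 0 initialized to $-\infty$ except $Q(0,0) = 0$, which
forces a global alignment starting at $(a_1, b_1)$. Pure maximization would
favor the longest possible path (alternating horizontal and vertical steps),
so diagonal *match* steps carry a larger weight than horizontal
*compression* and vertical *expansion* steps; $w_{\mathrm{match}} = 2.25$
with unit compression/expansion weights is the default and counteracts
overadaptation. Traceback ties prefer match over compression over expansion,
again for deterministic, diagonal-favoring paths.

The final score $Q(M,N)$ is corrected for the weights by dividing by the sum
of step weights along the optimal path. How exactly the correction should be
normalized (path weight, $M+N$, or path length) is an open choice; dividing
by the total path weight makes the corrected score a per-step average
similarity and hence comparable between series of different lengths, which
is what the center selection below needs.

The threshold $T$ plays no role inside the recursion: a below-threshold
sentinel has no usable arithmetic meaning there (0 would *reward* cells for
the negated-Euclidean kind, $-\infty$ could disconnect the recursion), so
the DTW search space is restricted by the explicit layouts described next,
and the retention-time penalty itself already disfavors distant cells.

### Constraint layouts and row-compressed storage

Most of the $M \times N$ matrix is never relevant: chromatographic
distortion keeps true correspondences near the diagonal, and pre-matched
peaks pin the path locally. A *layout* assigns every row an admissible
column interval, built from:

* **anchors** — pre-matched scan pairs (here: peak-clique rows). Anchors are
  first filtered to a strictly monotone chain (a longest-increasing-
  subsequence keeps the most anchors; order-inverted and directly adjacent
  anchors are dropped). With radius `r = 0` the anchor rows are pinched to
  the single anchor column, so every admissible path passes every anchor;
  `r > 0` keeps a square neighbourhood for flexibility.
* a **Sakoe-Chiba band** of half-width $\lceil w \cdot \max(M,N) \rceil$
  cells, either around the global diagonal (`scope = "global"`) or around
  each inter-anchor segment (`scope = "local"`). `w = 1` disables the band.

After intersection the layout is minimally repaired so that consecutive row
intervals overlap or abut diagonally and a valid path exists; when the
repair has to widen a pinched anchor row (which happens when two anchors sit
on nearly adjacent rows with distant columns), the following rows are
restricted to columns past the anchor so that zero-radius anchors remain
forced. Degenerate anchor geometries aside, the repair only ever widens.

Admissible cells are stored row-compressed (RCS): one linear value array,
per-row offsets and lengths. Reads outside the layout return a default
value, writes outside are no-ops — the layout is static. The dynamic
programming recursion and traceback (implemented in C++) run entirely on
this structure, so time and memory scale with the stored-cell count, linear
in the band width rather than quadratic in the series length. The
similarity values themselves are computed blockwise with BLAS on row chunks
restricted to the admissible column span. A plain dense R implementation of
the same recursion ships with the package and the test suite verifies the
two agree exactly (identical scores and paths), isolating the storage
machinery from the arithmetic.

### Center-star multiple alignment

All pairwise weight-corrected DTW scores are computed first; the
chromatogram with the highest score sum to all others becomes the reference
(center-star heuristic, ties to the lowest index), and every other
chromatogram is aligned to it independently, reusing the already-computed
pairwise paths. The result is a dense table with one row per center scan and
no absent cells. When a compression maps several scans of a chromatogram
onto one center scan, the cell records the scan with the highest local
similarity to the center scan and the full mapped range is kept in an
auxiliary attribute — a dense index matrix needs a single representative,
but the collapse should not hide the multi-mapping. Along each path the
positions where the local similarity is strictly greater than at both path
neighbours (plateaus: first position) are reported as similarity maxima;
they coincide with aligned, highly similar spectra.

## Evaluation harness

Predicted tables are scored against ground-truth peak groups. Each truth row
is paired with at most one predicted row — the one sharing the most
per-chromatogram entries within a scan tolerance, greedily by descending
overlap with ties broken by the smaller median-retention-time gap. The
pairing rule is a package definition (the correspondence between reported
and reference groups is not otherwise fully determined); predicted rows
matching no truth row are reported separately as unassignable rather than
flooding the false positives. Within a paired row, per chromatogram:
present/present within tolerance → TP; present/present disagreeing → FP and
FN; absent/absent → TN; absent-in-truth/present → FP;
present-in-truth/absent → FN; unpaired truth rows contribute their present
entries to FN. Then

$$ \mathrm{Precision} = \frac{TP}{TP+FP},\quad
   \mathrm{Recall} = \frac{TP}{TP+FN},\quad
   F_1 = \frac{2\,\mathrm{Precision}\cdot\mathrm{Recall}}
              {\mathrm{Precision}+\mathrm{Recall}}. $$

Undefined denominators are reported as `NA`, not 0, except that $F_1$ is 0
when precision and recall are both 0. For profile alignments every scan is
assigned, so TN and FN are unavailable; only TP and FP are counted, looking
up each truth group at its center-chromatogram scan.

## The synthetic generator

`synth_generate()` plants `n_groups` sparse unit-norm spectral templates
(5–30 nonzero fragment bins; rejection sampling keeps pairwise cosines below
0.95) at reference retention times with a minimum spacing, then realizes
them in each of `K` chromatograms through:

* a **monotone warp**: a strictly increasing monotone cubic spline through
  random knot offsets bounded by `warp_amplitude`, identity for
  chromatogram 1 and pinned at the run ends — local elution order is
  preserved, matching the premise of both aligners;
* **lognormal intensity scaling** (`intensity_cv`), **Bernoulli dropout**
  (`dropout_prob`; chromatogram 1 never drops, so every group keeps one
  member), Gaussian **spectral noise** truncated at zero, and a constant
  baseline;
* Gaussian elution profiles (`peak_sigma`) on the scan grid; the reported
  apex scan is the argmax of the template's trace in the noise-free case,
  and peak lists carry the generator's apex scans, emulating an upstream
  peak finder.

The default configuration — 5 chromatograms, 50 groups, 600 scans over
600 s, 10 s warp amplitude, CV 0.3, no dropout — is the package's study
condition: a desk-scale version of typical metabolomics runs (thousands of
scans, hundreds of peaks, tens of seconds of drift), small enough that the
full three-way comparison (peak, profile, hybrid) runs in seconds. All
randomness derives from one seed with fixed per-chromatogram offsets, so
every run is bit-reproducible.

**What passing tests show — and what they do not.** The generator produces
well-separated, non-coeluting peaks with shared templates and smooth warps.
Success on it demonstrates the correctness of the machinery (mutual-best-hit
grouping, constrained DP, anchor forcing, scoring), not robustness to
deconvolution errors, co-elution, missing mass calibration, or detector
saturation, none of which are modeled.

## Numerical and design choices

* **Binning** rounds m/z half-up to integer Da (`floor(x + 0.5)`) —
  deterministic across platforms, unlike banker's rounding, and the
  convention chromatography software uses. Binning conserves total in-range
  intensity.
* **Scan indices** are 1-based in memory, following R convention; on-disk
  peak lists and tables default to 0-based indices (the common export
  convention) with a `base` argument on all readers and writers.
* The exponent of the retention-time penalty is negative; the penalty decays
  from 1 to 0 by construction.
* **Band width** `w` is a fraction of `max(M, N)`; the stored-cell count
  grows as `(2 ceil(w max) + 1)(max + 1)` plus anchor-radius overhead.
* **Dropped-row degeneracies**: empty anchor sets, empty peak lists, and
  all-zero spectra are all defined (full band, zero-row tables, similarity
  0) rather than errors, except where the result would be meaningless
  (fewer than two chromatograms, disconnected layouts).
* Test problem sizes: the DP oracle enumerates all paths up to 6×6; clique
  checks enumerate up to 4 chromatograms × 8 peaks; the synthetic study runs
  at the default scale above. These sizes make the exhaustive oracles exact
  while keeping the whole suite fast.

## Known limitations

* In signal-free stretches (e.g. the run margins) the warp is not
  identifiable from the data; the profile aligner then follows the
  penalty-optimal diagonal, so mapped indices in such stretches reflect the
  band geometry, not the (unknowable) true warp.
* The greedy clique merge is order-dependent on exact similarity ties; the
  descending-similarity order makes it deterministic but not provably
  optimal.
* The center-star construction cannot guarantee a bounded distance to the
  optimal multiple alignment; peaks absent from the chosen center can
  degrade the profile table.
* High-resolution (non-integer-bin) spectra and MS/MS similarities are out
  of scope; spectra are compared as stored, without per-kind renormalization.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
d <- synth_generate(cfg)

# peak-clique multiple alignment
tab <- bipace_align(d$chromatograms, sim_config("cosine", TRUE, D = 10, T = 0),
                    mcs = 2)
evaluate_alignment(tab, d$truth)[c("precision", "recall", "f1")]

# profile alignment, then the hybrid with clique anchors
prof <- cemapp_dtw_align(d$chromatograms, sim_config("dot", TRUE, D = 10, T = 0),
                         dtw_weights(2.25), band_width = 0.1,
                         band_scope = "local")
hyb <- run_hybrid(d$chromatograms, tab, sim_config("dot", TRUE, D = 10, T = 0),
                  truth = d$truth)
c(anchor_free_cells = attr(prof, "stored_cells"),
  hybrid_cells = hyb$stored_cells)
```
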