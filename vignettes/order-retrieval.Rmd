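---
title: "Recovering the cutting order of magnetically collected serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering the cutting order of magnetically collected serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsort)
```

## The problem

In magnetic collection of ultrathin sections, a resin block augmented with
magnetic material is cut into hundreds of ~50 nm sections that float onto a
water bath, are herded by a magnet, and settle on a silicon wafer in arbitrary
positions and orientations. The cutting order -- which is the axial order of
the imaged volume -- is lost at that moment and must be recovered
computationally before any volumetric reconstruction is possible.

The physical trick that makes recovery possible: the magnetic resin carries
fluorescent microspheres of ~2 μm mean diameter. Because the bead diameter is
forty times the section thickness, every bead is sliced by many consecutive
sections. A section at axial offset $z$ from a bead's center shows a circular
cross-section of apparent diameter

$$ d(z) = 2\sqrt{r^2 - z^2}, \qquad |z| < r, $$

so each bead traverses a contiguous run of ~40 sections (for $r = 1$ μm,
50 nm thickness) with a smoothly varying footprint. Two physically adjacent
sections cut each shared bead at nearly the same latitude; sections far apart
share few or no beads, and where they do, the apparent diameters differ
substantially. This is the ordering signal.

## The method

The pipeline is a chain of five stages, each exposed as ordinary functions on
tibbles and matrices.

**Simulation** (`sim_config()`, `generate_bead_volume()`, `slice_volume()`,
`render_sections()`, `generate_em_volume()`, `render_em_sections()`). A
virtual block is filled with a Poisson number of beads (uniform positions,
lognormal diameters), sliced by the sphere--slab rule above, posed per
section with a random in-plane rotation and translation, rendered as 16-bit
images (spot intensity proportional to apparent cross-section area, additive
Gaussian noise), and written to disk in a *shuffled* catalog order. The true
order and poses travel in a separate ground-truth file that no downstream
stage reads; only the evaluation stage sees it.

**Detection** (`normalize_local_contrast()`, `detect_beads()`,
`merge_channels()`). Images are standardized by local mean and standard
deviation in a sliding block, thresholded, and connected components become
beads at their intensity-weighted centroid with apparent diameter
$2\sqrt{\text{area}/\pi}$. The two fluorescent channels are merged into one
point set per section, collapsing cross-channel detections closer than half
a bead diameter.

**Bead dissimilarity** (`match_point_sets()`, `bead_pair_dissimilarity()`,
`build_bead_matrix()`). For each pair of sections, bead constellations are
matched: each point gets a rotation/translation-invariant descriptor
(distances and relative angles to its $k = 4$ nearest neighbours), candidate
correspondences pass a nearest/second-nearest ambiguity test, and a 2-D
affine transform is fitted by seeded consensus sampling with a least-squares
refit. If no consistent transform exists the pair receives a sentinel value
($10^6$) meaning "not plausibly adjacent". Otherwise the fitted affine maps
the first set into the second's frame, beads outside a central bounding box
(60% of the frame per side) are discarded -- they may be visible in only one
section because of the limited field of view -- the survivors are matched
again, and the dissimilarity is

$$ D(a, b) = \sum_{\text{matches } (i,j)} \left| d_i^{(a)} - d_j^{(b)} \right|. $$

**EM dissimilarity** (`tile_dissimilarity()`,
`section_pair_dissimilarity()`, `build_em_matrix()`). The same banded
structure can be computed from the tissue imagery itself: per tile pair, an
affine alignment is sought by matching difference-of-Gaussians blob-keypoint
constellations (same descriptor/consensus machinery as the beads); after
alignment, the Pearson normalized cross-correlation $c$ is computed in a
central box (capped at 2000 px per side) and the tile dissimilarity is
$2 - c \in [0, 4]$. Per section pair, tile values are averaged over the
tiles that matched; unmatched tiles are excluded whenever at least one tile
matched, which protects the average from per-tile artifacts.

**Ordering** (`solve_exact()`, `solve_heuristic()`, `solve_order()`). The
cutting order is the minimum-cost Hamiltonian *path* through the sections
with the dissimilarities as edge weights -- an open traveling-salesman
problem. Small instances (n ≤ 12) are solved exactly by Held--Karp dynamic
programming over subsets. Larger instances are closed into a cycle problem
by a dummy node at distance zero to every section: every cycle through the
dummy node, cut at that node, is a Hamiltonian path of identical cost, and
conversely every path extends to such a cycle, so the optima coincide. The
cycle is then solved by multi-start nearest-neighbour construction plus
2-opt improvement, deterministically given a seed. An order is only defined
up to reversal, so results are reported with the smaller terminal id first
(`canonicalize()`).

**Evaluation** (`link_costs()`, `is_perfect()`, `compare_orders()`). Given
a ground truth, each link between consecutive sections of a proposed order
costs the absolute difference of the two sections' ground-truth indices,
minus one. An order of $n$ sections has $n - 1$ links; identity and exact
reversal both score all zeros, and the frequency of the costs localizes and
grades mistakes. `run_pipeline()` chains everything and scores the result.

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_sections = 12, seed = 7), seed = 7)
res <- run_pipeline(cfg)
res$report$total          # 0 = perfect up to reversal
autoplot(res$matrix, order = res$order)   # banded matrix after reordering
```

## Parameters that matter

* `bead_density` (beads/μm³): presets `"high"` = 0.010 and `"low"` = 0.002,
  giving roughly 130 vs 26 detectable beads per section in the default
  80×80 μm field. The presets mirror the dense and sparse bead-loading
  regimes in which ordering is respectively easy and error-prone; the 5×
  ratio matches the 1% vs 0.2% w/w loadings used in practice. The mapping
  from weight fraction to volumetric density is not physically derivable
  here, so density is exposed directly.
* `bead_mean_diameter` (2 μm) and `section_thickness` (50 nm): their ratio
  sets the ~40-section bead span and thus how far apart two sections can be
  and still share signal.
* `bead_diameter_cv` (0.15): lognormal spread. Only the mean is physically
  pinned; a modest positive spread is typical of polymer microspheres and
  makes diameters more informative (a zero spread would make all equatorial
  cross-sections identical).
* `threshold` (0.85 of the normalized range): after local z-scoring maps
  the local mean to 0.5 and ±3 SD to [0, 1], 0.85 sits ≈2 SD above the
  local background. A threshold at 0.5 of the range would be *at* the local
  mean and mark half of every noisy background as foreground; 2 SD is the
  usual operating point for spot detection after local contrast
  normalization. Exposed in `detect_beads()`.
* `match_params()`: descriptor neighbourhood `k = 4`, ambiguity ratio 0.9,
  inlier tolerance 2 px, `min_inliers = 6`, 300 consensus iterations,
  ±20% tolerated affine scale deviation. For EM keypoints the budget is
  1000 iterations with ratio 0.95 and 3 px tolerance: blob keypoints are
  noisier than bead centroids, and the larger budget keeps the probability
  of missing a true adjacent-pair alignment negligible.
* `central_fraction` (0.6): the exclusion box. Large enough to retain most
  shared beads, small enough that beads lost to the field edge under
  differing poses cannot inflate the sum.
* `exact_limit` (12): Held--Karp memory/time grows as $2^n n$; 12 keeps the
  exact solver instant while covering every case where exhaustive certainty
  is cheap.

## What the simulator does and does not emulate

It emulates: the sphere--slab bead geometry with contiguous spans and
unimodal apparent-diameter profiles; arbitrary per-section pose; two bead
channels to be merged; brightness growing with cross-section; additive
sensor noise; field-of-view clipping; a shuffled on-disk order; and, for the
EM variant, a texture volume whose axial correlation decays over a few
sections so adjacent sections look alike and distant ones do not.

It does not emulate: optical point-spread blur, bead aggregation, uneven
illumination, section folds or debris, EM contrast physics, or segmentation
failures of real wafer imagery. Passing tests therefore demonstrate the
correctness and robustness of the *ordering machinery* under the stated
geometry and noise, not detector performance on any particular microscope's
raw data.

## Numerical choices and degenerate inputs

* Sentinel = $10^6$, far above any attainable finite sum, stored in the
  matrix object so solvers and plots can recognize "no match".
* The matrix diagonal is 0 by convention in both modalities. For EM a
  self-pair would score $2 - 1 = 1$, but the path solver never uses the
  diagonal, and a zero diagonal keeps the type's invariants uniform.
* Empty bead sets, constant tiles, and sets smaller than $k + 1$ points
  yield "no match" (sentinel), never an error; an empty image yields an
  empty bead table.
* A local-contrast block larger than the image falls back to global
  normalization with a message; locally constant regions map to mid-gray.
* Ties in the path solvers are broken deterministically (first-improvement
  2-opt, fixed scan order, seeded multi-start); continuous dissimilarities
  make exact ties measure-zero.
* The per-link metric uses $n - 1$ links for $n$ sections (the last section
  has no outgoing link); each cost is an integer in $[0, n - 2]$, and a
  total of zero characterizes exactly the truth and its reversal.
* All randomness flows from one integer seed per run; the pipeline fans it
  out by fixed offsets (simulation +0, matching +10, solver +20, EM texture
  +30) so stages can be rerun in isolation bit-identically.

## Design choices where the design was open

* **Raw sum, not mean, of diameter differences.** The summed dissimilarity
  grows both with per-bead diameter divergence and with how many beads two
  sections share, reinforcing the banded structure at small gaps. Its cost
  is sensitivity to the matched-bead count at large gaps, where the mean
  dissimilarity still trends upward but individual pairs fluctuate; the
  final correspondence set is therefore rebuilt from the fitted transform
  over *all* points (one-to-one, within tolerance), which makes the count
  stable across parameter seeds.
* **Affine, not rigid, alignment.** Deposition is nominally rigid, but an
  affine fit (with singular values constrained near 1) tolerates slight
  anisotropy at no cost in discrimination.
* **Blob keypoints for EM.** Scale-space blob extrema plus constellation
  descriptors give a rotation/translation-invariant alignment without an
  external feature library, reusing the audited bead-matching path.
* **Internal solvers.** An exact subset-DP solver and a dummy-node 2-opt
  heuristic remove any dependence on an external TSP binary; on banded
  matrices of the kind this problem produces, the heuristic reproduces the
  exact optimum (asserted in the tests up to n = 12).

## Problem sizes used by the test suite

The suite validates the full chain at sizes a laptop handles in minutes:
end-to-end recovery on a 30-section stack at the high-density preset
(recovered perfectly, total link cost 0); a 20-seed paired comparison of the
high and low density presets on 10-section stacks (sparse beads yield
strictly more link-cost errors on average); exact-vs-exhaustive solver
equivalence on 50 random instances up to n = 8; and heuristic-vs-exact
equivalence on simulator-derived matrices up to n = 12. Wafer-scale runs
(hundreds of sections) use the same code path through `solve_heuristic()`,
whose cost grows quadratically per 2-opt pass.

## Known limitations

* With very sparse beads (low preset at small fields) sections may carry
  fewer points than the descriptor neighbourhood needs, making whole rows
  sentinel; the solver then has no signal to place those sections -- the
  intended, observable failure mode of sparse loading.
* Very dim bead cross-sections (a bead almost tangent to the section) can
  fall below the local-contrast floor when a much brighter bead shares the
  normalization block, shortening observed spans near their ends. This
  removes the least informative detections first and has not affected
  ordering in any tested condition.
* The heuristic solver guarantees only a 2-opt local optimum; an adjacent
  transposition that survives 2-opt is conceivable on noisy matrices. The
  metric's histogram makes such flips visible for manual or EM-based
  correction.
* Diameters are measured in pixels and never converted to μm; this is
  deliberate (both sections of a pair share the pixel size) but means
  matrices computed at different magnifications are not comparable.
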