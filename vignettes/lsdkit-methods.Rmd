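---
title: "Local shape descriptors and affinity-based segmentation: methods"
author: "lsdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local shape descriptors and affinity-based segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsdkit)
```

## The problem

Dense neuron segmentation in volume electron microscopy is usually solved in
two stages: a voxel classifier predicts boundary evidence — most commonly
*affinities*, per-voxel probabilities that a voxel and a specific neighbor
belong to the same neurite — and a combinatorial post-processing stage turns
that evidence into a segmentation (seeded watershed into supervoxels,
followed by hierarchical agglomeration on a region adjacency graph).
*Local shape descriptors* (LSDs) are per-voxel statistics of the object under
each voxel, computed inside a local window; they summarize local size,
center-of-mass offset and coordinate covariance (diameter, elongation,
direction). Used as an auxiliary prediction target next to affinities, they
force a boundary classifier to attend to object-level context rather than a
few central voxels. This package implements everything around that idea that
does not involve training a network: computing definition-true LSDs and
affinity targets from label volumes, the watershed/RAG/agglomeration chain
(monolithic and block-wise), the evaluation metrics, and a synthetic fixture
generator that makes the whole chain testable without external data.

## The descriptor

Let `y` be a label volume over voxels, with 0 denoting background. For a
voxel `v` with label `y(v) != 0`, intersect its object with a window centered
at `v` to obtain the voxel set `S_v`. The descriptor concatenates, in the
package's default channel order:

* channels 0–2 — **mean offset** `m(S_v) − v` per axis `(z, y, x)`, in nm:
  the displacement from the voxel to the local center of mass of its object;
* channels 3–5 — **covariance diagonal** of the coordinates of `S_v`
  (`zz`, `yy`, `xx`), nm²;
* channels 6–8 — **covariance off-diagonals** (`zy`, `zx`, `yx`), nm²;
* channel 9 — **size**: the (weighted) number of voxels in `S_v`.

With a weighted window `w`, size, mean and second moments are weighted sums;
the covariance follows from the moment identity
`c_kl = E[p_k p_l] − E[p_k] E[p_l]`. A background voxel has the all-zero
descriptor, in every mode.

Two windows are provided. The **ball** of radius `sigma` (an ellipsoid under
per-axis `sigma`) is the uniform-weight, definition-faithful variant; for an
object that fills the window its covariance diagonal approaches the analytic
second moment of a ball, `r²/5` per axis. The **Gaussian** window with
per-axis standard deviation `sigma`, truncated at `truncate * sigma`
(default 3), is the smooth variant used for learning targets; its filled-
window covariance approaches `sigma²`. Gaussian weights are left unnormalized
(center weight 1), so the size channel reads as an effective voxel count and
is bounded by the kernel mass. Both discretized windows are validated in the
tests against independent enumeration of their support.

Axis conventions: everything is `(z, y, x)` with `z` the sectioning axis;
`voxel_size` and `offset` are nm; a world point `p` belongs to 0-based voxel
`floor((p − offset) / voxel_size)`. Statistics are computed in world units so
`sigma` is physically meaningful on anisotropic grids (the default fixture
uses 20 × 9 × 9 nm voxels); computing in voxel units is the special case
`voxel_size = c(1, 1, 1)`.

### Dense computation

`compute_lsds()` evaluates the descriptor densely by convolution: per label
`i`, the binary mask `b_i` and its coordinate-weighted products
(`p_k b_i`, `p_k p_l b_i`) are convolved with the window and combined at the
voxels of that label, then stitched onto the 10-channel grid. Convolutions
are exact linear convolutions via zero-padded FFTs restricted to each
label's bounding box (padded sizes rounded up to 2-3-5-smooth numbers);
zero padding implements the border convention that statistics use in-volume
voxels only. `lsd_at_voxel_bruteforce()` is the literal per-voxel
implementation of the definition and serves as the oracle: the test suite
checks the two routes agree at every voxel of a random anisotropic fixture
to well below the 1e−4 tolerance. Because a voxel always belongs to its own
`S_v`, the convolved size is bounded below by the center weight and the
division is never degenerate. Tiny negative FFT residues on the covariance
diagonal are clamped at zero.

Choices that were genuinely open:

* **Channel order.** The figure-documented layout (offset first, size last)
  is the default; the concatenation order with size first is available as
  `channel_order = "equation"`.
* **Normalization** (`normalize = TRUE`), for commensurate regression
  targets in `[0, 1]`: size is divided by the kernel mass; offsets are
  clipped to `[−sigma, sigma]` and mapped affinely to `[0, 1]`; covariance
  entries are divided by `sigma_k sigma_l`, with diagonals clipped to
  `[0, 1]` and off-diagonals mapped from `[−1, 1]`. Background stays
  all-zero rather than at the mid-scale 0.5, keeping the background
  convention uniform across modes.
* **Downsampling** (`downsample = n`) computes the statistics on an
  `n`-strided grid (subsampled labels, scaled voxel size) and
  nearest-neighbor upsamples — the usual cost-saving approximation for
  training targets; it is exact only in the limit of smooth objects and is
  excluded from the oracle-equivalence guarantee.
* `sigma` has **no default**: it is a physical scale the user must choose
  (of the order of the process radius of interest).

## Affinity targets

`compute_affinities()` sets channel `j` at voxel `v` to 1 exactly when
`y(v) = y(v + n_j) != 0` — the Kronecker predicate over an ordered offset
neighborhood, with the explicit clause that background never connects to
anything. The direct neighborhood is `(−1,0,0), (0,−1,0), (0,0,−1)`;
negative offsets mean the value for a voxel pair is stored at the
higher-index voxel. Pairs whose partner leaves the volume get value 0 plus a
0 entry in a companion validity mask, so border pairs can be excluded
downstream. `make_long_range_neighborhood(extra)` appends `extra` offsets
per axis at configurable strides (default 2×, 4×, 8× the unit step), giving
`3(1 + extra)` channels — the long-range auxiliary-task layout; only the
count is canonical, the distances are a configuration default.

## From affinities to segments

The post-processing chain follows the standard supervoxel pipeline:

1. **Boundary map**: per voxel, the mean of the valid direct-affinity values
   incident to it (up to six).
2. **Mask**: `boundary_map > mask_threshold` (default 0.5).
3. **Distance transform**: exact anisotropy-aware Euclidean distance inside
   the mask (separable squared-distance transform, compiled).
4. **Seeds**: local maxima of the distance transform; plateaus (connected
   equal-valued maxima) are collapsed to the voxel nearest their centroid;
   greedy non-maximum suppression at `seed_min_distance` (nm; default 10)
   ordered by decreasing distance, ties broken lexicographically `(z, y, x)`.
5. **Watershed**: priority flood of the mask from the seeds in order of
   decreasing distance, 6-connected, with a FIFO tie-break so runs are
   bit-reproducible; fragment ids are assigned in seed scan order.
6. **Filtering** (optional): fragments whose mean boundary-map value falls
   below `min_avg_aff` are dropped to background — the guard against
   low-affinity regions such as glia.
7. **RAG**: one node per fragment (center of mass, voxel count), one edge
   per face-adjacent fragment pair, each edge retaining the multiset of
   affinities across its boundary voxel pairs.
8. **Agglomeration**: edges merge greedily in increasing *merge score*
   `1 − aggregate(boundary affinities)`, i.e. in decreasing affinity. The
   aggregate is the configurable merge function: `mean`, or a `quantile`
   (default q = 0.75, linear interpolation). On a merge, parallel edges pool
   their multisets and their aggregate is recomputed. The full merge history
   is recorded, so `extract_segmentation()` can produce the segmentation at
   any threshold by union-find over merges with score strictly below it.

Numerical and convention details worth stating: scores live in `[0, 1]`;
ties merge the smallest fragment-id pair first; recorded history scores are
clamped to be non-decreasing (a pooled mean can drop below the current merge
level, and a monotone history is what makes threshold extraction a
hierarchy); with the strict `<` rule, threshold 0 returns the fragments
unchanged and an edge with score exactly 1 (all-zero boundary affinities)
never merges.

**Block-wise processing** (`blockwise_segment()`) runs the watershed per
block on a context-padded region, crops to the block core, offsets fragment
ids per block (global uniqueness), and then builds a single global RAG over
the assembled fragment volume — cross-block adjacencies appear on the shared
faces automatically — before agglomerating globally. On fixtures with
adequate context this reproduces the monolithic partition exactly (checked
as VOI = 0); it is an in-process correctness demonstration of the scheme,
not a distributed scheduler.

## Metrics

**VOI.** `voi()` returns the two conditional entropies of the contingency
distribution between segmentation and ground truth: `voi_split = H(Seg|GT)`
(over-segmentation) and `voi_merge = H(GT|Seg)` (under-segmentation), natural
logarithm by default, computed over ground-truth foreground voxels. Because
the watershed only claims voxels inside the boundary-map mask, thin or
corner ground-truth voxels — whose incident ground-truth affinities are
mostly 0 by the background clause — can remain unclaimed even under perfect
affinities; `restrict_to_seg = TRUE` restricts the comparison to the jointly
claimed foreground, which is the mode under which the noiseless-fixture
exactness checks attain exactly (0, 0).

**ERL.** `erl()` maps skeleton nodes to segments and scores *runs*: maximal
skeleton sub-paths whose nodes share one nonzero, non-merged segment. A
segment hosting nodes of two or more skeletons is merged and all its runs
score 0 — one small spurious attachment invalidates the whole neuron, which
is what makes the metric so merge-sensitive. Nodes on background break runs,
and an edge whose endpoints disagree contributes only to the total length.
The default length-weighted mode returns `sum(len_run²) / L_total`, the
expected run length at a uniformly random point of the skeletons; `uniform`
mode averages per-skeleton expected run lengths instead. The ceiling
`max_erl = sum(L_k²) / L_total` is attained by a perfect segmentation, and
adding a short, perfectly segmented skeleton *lowers* both quantities — the
fragmentation pathology that makes ERL values incomparable across ROI sizes;
the tests reproduce it on closed-form toys. One discretization note: the
"split at the midpoint halves the ERL" closed form holds in the dense-node
limit, since the edge crossing the cut is lost from every run; tests assert
it at 1% with 2 nm node spacing.

**MCM.** `mcm()` counts the edit operations of a hypothetical proofreader
equipped with a min-cut split tool. At a given threshold, for every segment
whose fragments host two or more skeletons, the two skeletons with the most
nodes in the conflicted component (ties: lowest ids) are separated by an
s–t min-cut on the component's fragment subgraph — capacities are the
aggregated boundary affinities (`1 −` merge score), the source/sink sides
are the fragments hosting each skeleton's nodes — cut edges are deleted and
one *split* is counted, until every component hosts at most one skeleton.
*Merges* are then, per skeleton, the number of remaining components it spans
minus one, summed. The min-cut is solved exactly (max-flow); the tests
verify it against exhaustive edge-subset enumeration on graphs of up to 12
edges. The procedure's free choices (capacity definition, seed sets,
pairing and stopping rules) are package decisions exposed through the
function's arguments, since only the metric's intent — count split and merge
interactions — is canonical.

**Threshold selection.** `threshold_sweep()` evaluates a segmentation per
threshold and reports the optimum — minimum VOI sum or maximum ERL — which
is the "line search on validation data" by which an operating threshold is
chosen in practice. Because merging only proceeds along the hierarchy,
`voi_merge` is non-decreasing and `voi_split` non-increasing in the
threshold, and the two criteria can legitimately disagree: an early false
merge that improves VOI (small mixing entropy) zeroes whole neurons under
ERL. Both behaviors are asserted on constructed fixtures.

## The synthetic fixtures

`make_toy_labels()` generates either non-overlapping **spheres** (radii
sampled from a range, rejection-placed with a surface-to-surface gap of at
least `min_separation`) or **tubes**: smooth random-walk centerlines
(per-step direction perturbation `tube_wobble`, reflected at the volume
boundary) rasterized at a fixed radius, each regrown if it approaches
existing objects. The defaults — 64³ voxels at 20 × 9 × 9 nm, five objects,
35 nm tube radius, 40 nm separation — were chosen once to resemble
serial-section EM geometry: anisotropic voxels, neurite-scale processes, and
gaps wide enough that ground-truth affinities never bridge objects. Tube
centerlines are retained, so `toy_skeletons()` yields matched ground-truth
skeletons whose nodes provably lie on their tube's voxels. The tests and the
acceptance script run on 48³ crops of these conditions, which keeps the full
suite in the minutes range while leaving every object several windows wide.

`perturb_affinities()` injects errors whose ground truth is known exactly
and returned as a manifest. A **false split** is a one-voxel slab of an
object (perpendicular to its longest extent, in the middle half of its
range) whose incident affinities are zeroed — a spurious membrane. Such a
slab removes the mask there, so the object falls into fragments with *no*
connecting RAG edge; fixing it is a merge operation, and `k` cuts in
straight tubes yield exactly `k` MCM merges. (A planar cut can sever a bent
or boundary-reflected tube more than once, in which case MCM honestly counts
more merge operations than cuts.) A **false merge** is a high-affinity
bridge rasterized along the closest-approach segment between two objects;
at moderate thresholds the pipeline fuses the two, ERL collapses for both
skeletons, and MCM must spend at least one min-cut. Optional Gaussian
smoothing (`blur_sigma`, nm) grades the evidence. What the generator does
*not* emulate: EM texture and raw intensities, learned-predictor noise
correlations, or anisotropic section artifacts — so green tests certify the
correctness of the descriptor algebra, the pipeline plumbing and the metric
definitions, not real-data segmentation accuracy.

## Known limitations

* Everything network-related is out of scope by design: the package
  produces training *targets* and consumes (real or synthetic) affinities;
  it neither trains nor runs predictors.
* The agglomeration and MCM implementations target fixture-scale graphs
  (thousands of fragments); the block-wise path demonstrates the stitching
  logic in-process rather than distributing it.
* The zarr container dialect is deliberately small: C-order, uncompressed
  chunks, v2 metadata. It round-trips bit-exactly and is readable by the
  reference implementations, but it is not a general zarr client (no
  compressors, no consolidated metadata).
* ERL run lengths are node-path lengths; closed forms involving cuts are
  met in the dense-node limit as discussed above.
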