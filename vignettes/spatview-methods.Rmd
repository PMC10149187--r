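---
title: "spatview: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatview: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatview)
```

`spatview` re-implements, as an R package, the server-side machinery of
a multiresolution spatial-omics viewer: image pyramid tiling and
serving, columnar ingestion of marker tables, region geometry,
render-buffer data contracts, and the spatial statistics such a viewer
hosts as plugins. This vignette records the models, the parameters that
matter, the numerical choices, and the places where the design was
genuinely open.

## Coordinate conventions

All geometry lives in *level-0 pixel space*: the full-resolution image
frame, origin at the top-left corner, x growing right, y growing down.
Pixel windows are half-open. Marker coordinates are continuous values
in this frame; tile and bin indices are 0-based (matching the on-disk
`{level}/{col}_{row}` naming), while R-facing row indices are 1-based.
The one deliberate seam is the packed vertex record, whose
`markerIndex` field is 0-based because it addresses GPU-style buffers.

## Deep Zoom pyramids

A pyramid over a `width x height` image has levels `0..L` where `L`
(`maxLevel()`) is the smallest integer with `2^L >= max(width,
height)`; level 0 is a single pixel and each level doubles resolution
with ceiling division. Tiles are `tileSize` pixels square (default
254) plus `overlap` pixels (default 1) on every interior edge, so
interior tiles are 256 px — a GPU-friendly power of two. These
defaults follow the common Deep Zoom converter convention; they are
choices, not facts of the format.

Downsampling between adjacent levels is a 2x2 area average. Odd-sized
edges average the pixels that exist, implemented by replicating the
last row/column before averaging (equivalent, and branch-free).
Nothing sharper is warranted: tiles are viewed, not measured.

Tiles are encoded losslessly as PNG by default, which is what makes
the reconstruction property exact: stitching the top-level tiles with
overlaps stripped reproduces the input image *bit for bit*, provided
the input is 8-bit-quantised (the synthetic generator emits
`k/255`-valued pixels for that reason). JPEG encoding is available for
serving but is never used where exactness is asserted.

Layer compositing maps each single-channel pixel `p` through
`clamp(p * contrast + brightness)^gamma * color * opacity` and sums
layers additively with a final clamp to `[0, 1]`. The adjustment order
(contrast, brightness, gamma, then color/opacity) and the additive
blend are design decisions — "blending" has no canonical formula —
chosen so that identity parameters are exactly the identity map and so
that compositing commutes with cropping (the property
`captureViewport()` is tested against). Collection mode (side-by-side
layers) is represented as offsets in the project configuration, not as
pixel math.

## Columnar marker ingestion

Marker tables are stored struct-of-arrays: one contiguous vector per
column, numeric columns as 64-bit doubles (missing = `NaN`),
everything else as categorical strings (missing = `""`). The numeric
detection rule is: a column is numeric iff it has at least one
non-empty cell and *every* non-empty cell parses as a finite decimal
or scientific-notation number. This codifies "columns detected as
containing only numeric values" deterministically; hexadecimal and
infinity spellings deliberately do not count.

CSV parsing streams in chunks of `chunkRows` text rows, so the peak
raw text held is proportional to the chunk, not the file. Field
splitting has a fast path for chunks without quote characters and an
RFC-4180 path (escaped quotes, embedded delimiters and newlines)
otherwise; logical rows spanning physical lines are re-joined by quote
parity. The contract — verified by test — is that the parse is
*identical* for any chunk size. Ragged rows fail with their row
number. The delimiter is an explicit flag (comma by default); there is
no dialect sniffing, to keep parses deterministic.

HDF5/AnnData reads are column-selective: only the requested datasets
(or single hyperslab columns of 2D datasets, via the `"obsm/spatial:0"`
selector syntax) are read from disk, and values keep the precision
stored on disk. AnnData categorical groups (`categories` + `codes`)
are decoded to strings. Sparse `X`, layers and Zarr backing are out of
scope. The `memoryFootprint()` model is 8 bytes per numeric value and
dictionary-encoded strings (4-byte codes + unique string bytes).

## The 32-byte vertex record

The viewer's GPU contract is 32 bytes per drawn marker. The published
contract names the total size and some fields; the exact byte map here
is this package's frozen allocation (see `vertexLayout()`):
position as two float32, a uint32 marker index, RGBA color, float32
opacity and size, uint16 group and shape ids, and two 16-bit
fixed-point pie-sector fractions (value/65535). Records are appended
in chunks of at most 100 000 records — the upload granularity — with
each chunk logged; buffer content is independent of the chunk size.
There is **no sub-sampling on the default path**: every
finite-coordinate row is packed (rows with non-finite coordinates are
skipped and counted). Marker sizes above 256 px trigger a warning,
reflecting the point-sprite size restriction of GPU point rendering;
it is a validation threshold, not a hard limit. The legacy quad-tree
sub-sampler is retained for comparison, with an explicit seed argument
and no global randomness.

Pie-chart display duplicates each marker once per sector: extents are
`value / rowSum`, starts are the running cumulative fraction.
Zero-valued sectors keep their row with extent 0 so the `n * k` record
count is exact; all-zero and negative rows are errors that name the
offending row.

## Regions

Regions are GeoJSON FeatureCollections of Polygons/MultiPolygons with
holes; properties pass through untouched. Containment uses the
even-odd ray-casting rule, with points within `1e-9` px of any edge
counted inside. Both choices are explicit decisions: the boundary
semantics of the viewer's SVG rendering are unspecified, and a stated
rule that the brute-force oracle can share is worth more than any
particular convention. Overlapping regions resolve to the first
feature in document order. Assignment is accelerated by a uniform
grid (cell size = bounding-box diagonal / 64) listing candidate
features per cell; the contract, property-tested on randomized scenes
of star-shaped polygons with holes, is exact agreement with testing
every feature directly.

## Neighborhood enrichment

Given an undirected spatial neighbor graph (k-nearest-neighbor with
union symmetrisation and lower-index tie-breaks, or fixed-radius) and
one category label per node, the observed statistic for a pair (a, b)
is the number of edges joining an a-node and a b-node; the diagonal
counts within-category edges. The null fixes the graph and permutes
the label vector uniformly (`nPerms` draws, default 1000, seed
mandatory), and

$$ z(a,b) = \frac{\mathrm{obs}(a,b) - \overline{\mathrm{null}}(a,b)}
  {\mathrm{sd}_{\mathrm{null}}(a,b)} $$

with the *population* standard deviation over permutations, matching
the exhaustive-enumeration oracle used in the tests. A null with zero
spread (e.g. a complete graph, where every labeling gives the same
counts) yields z = 0 and a `degenerate` flag rather than a division
by zero. Uniform label permutation conditions on the category
abundances, so no further abundance normalisation is applied — the
permutation handles it implicitly. The test suite checks symmetry,
invariance under category renaming, sign behaviour on constructed
geometries, agreement with the exhaustive oracle on a 4-node path
graph, and calibration: on complete-spatial-randomness scenes (200
replicates of 400 markers, 3 categories, k = 6 graphs, 1000
permutations) the fraction of |z| > 1.96 must sit in 0.05 ± 0.02 with
mean z within ±0.05.

## Points-to-regions clustering

The pipeline is normative for this package: (1) markers fall into
square bins of side `binSize`; (2) each bin gets a per-category count
vector; (3) counts are smoothed across the bin grid with a Gaussian
kernel of sigma `smoothingRadius` pixels (default `binSize`; 0
disables smoothing; zero-padded truncated kernel — edge effects cancel
in the subsequent normalisation because the kernel is shared across
categories); (4) rows are L1-normalised to compositions; (5) seeded
K-means with 10 restarts (best within-cluster sum of squares wins)
clusters the non-empty bins into K regions; (6) markers inherit their
bin's cluster; (7) optionally, connected same-label bin components are
contoured into closed polygon rings (verified to rasterise back to the
bin label map). L1 composition is a deliberate, configurable-by-design
simplification; frequency re-weighting schemes would slot in at step
4. `binSize` should be chosen so a typical bin holds on the order of
20 markers — the default used in the recovery tests (50 000 markers on
a 1000-px field, `binSize` 20). Recovery is asserted as adjusted Rand
index >= 0.9 against the planted two-domain truth across 10 seeds.

## Gating and classifier comparison

Gating selects rows whose coordinates — in either the 2D feature
embedding (user-supplied columns; the package computes no UMAP/t-SNE
itself) or physical space — fall inside a polygon; row identity links
the spaces, so the returned index set addresses the same markers in
both. The two-classifier confusion matrix matches markers across
tables by exact coordinate equality (tolerance 0) or greedy one-to-one
nearest neighbor within a tolerance, processing A-rows in order with
lower-index tie-breaks; the tolerance is an extension beyond the
identical-coordinates assumption, defaulting to 0.

## Serving and projects

The HTTP service is a small blocking single-threaded responder on base
R sockets: descriptors, on-demand tiles (byte-identical to the offline
pyramid, by construction and by test), column-selective marker JSON,
and the project configuration. An LRU cache keyed by tile address only
short-circuits re-encoding; responses are pure functions of (project,
request). The `.tmap` project schema is versioned JSON and normative
for this package — the format name is conventional, its contents were
not published. Static-page export is represented as pre-built tile
directories plus project JSON; HTML generation is out of scope, as are
authentication and multi-user sessions.

## Synthetic scenes: what they do and do not show

The generator produces seeded images (checkerboard, gradient, blobs,
noise) and marked point processes: `csr` (uniform positions,
independent labels — the calibration null), `domains` (vertical
domains with distinct compositions, purity 1 by default — clustering
ground truth), and `attract` (two categories sharing Gaussian blob
centers, sd 10 px on a 1000-px field — the enrichment positive
control). Scenes are fully determined by their arguments, and all
parameters are logged into the scene. These fixtures emulate the
*statistical structure* the analytics target; they do not emulate
segmentation artifacts, spatially varying detection efficiency,
anisotropic tissue geometry, or the label noise of real decoding
pipelines. Passing tests therefore demonstrate correctness of the
implementations under their stated models, not robustness to every
failure mode of real data.

## Problem sizes and numerical tolerances

The test and acceptance runs use: 100 000-row CSV fixtures (chunk
sizes 1, 7, 1000), 250 000-marker packing, pyramids up to 2048 px,
10 geometry scenes of 1000 points x 20 polygons, 200 CSR replicates x
1000 permutations, and 10 clustering seeds at 50 000 markers — sizes
chosen to exercise the asymptotic behaviour of each component while
keeping a full run in the minutes range on one CPU. Exact assertions
(tile reconstruction, parse equivalence, geometry agreement) use
identity, not tolerances; floating-point assertions use 1e-12 for
double-precision mass conservation, 1e-6 relative for float32
round-trips, and 1/65535 for the fixed-point sector fractions.

## Known limitations

* The server is single-threaded and intended for scripted use and
  testing, not production hosting.
* `buildNeighborGraph()` materialises the full distance matrix
  (O(n^2) memory), fine for the tens of thousands of nodes the
  enrichment test targets, not for tens of millions.
* AnnData support reads `obs` columns, `obsm` columns, dense `X`
  columns and 1D datasets only.
* Polygon boolean operations, simplification and interactive drawing
  are out of scope; regions come from files or from the clustering
  contour step.
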