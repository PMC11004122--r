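---
title: "Methods: per-cell smFISH quantification, thresholded classification, and the spillover model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell smFISH quantification, thresholded classification, and the spillover model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qufish)
```

## What the package computes

smFISH assays such as RNAScope render each mRNA molecule of a probed gene as
one fluorescent punctum. Upstream image analysis (QuPath) detects cells from
a nuclear stain, approximates each cell's boundary by a fixed radius around
its nucleus, and counts the puncta per channel inside each boundary. `qufish`
consumes those detection tables and computes per-cell expression profiles and
everything the downstream biology needs: positive-cell abundance, multi-target
cell-type calls, co-expression rates against two denominators, per-image
replication for statistics, and spatial plots.

The central modelling assumption inherited from the upstream pipeline is
**one nucleus = one cell, one punctum = one transcript**. Neither is exactly
true (clusters are decomposed to estimated spot counts; boundary radii are a
geometric approximation), and the second approximation is the source of the
artefact this package is built to control.

## Reading QuPath exports: the dialect

QuPath's measurement-export column names vary with version, locale and
detection settings, so the reader takes an explicit `qupath_dialect()`
object: separator, object-type column and labels, image / object-id / parent
columns, centroid columns (µm), and two templated measurement patterns with a
`{c}` channel placeholder (spot count and total intensity). The defaults
model QuPath 0.3.x TSV exports. Two deliberate strictness choices:

- **Comma decimal marks are rejected, not coerced.** A locale drift that
  turns `3.5` into `3,5` corrupts every number in a file; failing loudly at
  the first offending row is the only safe behaviour.
- **A missing spot-count measurement for a configured channel is an error,
  not a zero.** A silent zero is indistinguishable from real absence of
  expression. The only exception is the child-row layout (below), where cell
  rows legitimately carry no count columns and `require_counts = FALSE`
  initialises the tally at zero before subcellular rows are added.

Morphometric columns (cell area, nucleus shape, ...) are dropped at read
time; only pattern-matched measurements survive into the detection table.

Two layouts of the same information are supported, because QuPath emits
both: per-channel count columns directly on cell rows (*columns*), and
separate subcellular detection rows linked to their parent cell
(*child rows*). The two-branch split (`split_branches()`) isolates cell and
subcellular rows; `attach_subcellular()` re-associates the latter by parent
link first, then by nearest cell centroid within a capture radius
(default 5 µm, matching the generator's cell radius and the radius-based
boundary approximation upstream). Detections that resolve to no cell are
counted per gene in an orphan report, never dropped silently — this is what
makes the transcript-conservation invariant testable.

Fractional spot counts (QuPath estimates the content of merged clusters) are
rounded **half-up** to integers at harvest, because every downstream
positivity rule is stated in whole transcripts.

## Positivity, co-expression and the two denominators

A cell is *positive* for a profile query {g₁, …, gₖ; t} when its count for
**every** queried gene is ≥ t. The default threshold is 1 transcript.
Summaries report the positive count against:

- all cells in the dataset (`pct_all`), and
- *transcript-expressing* cells — those with ≥ 1 transcript of **any**
  configured target (`pct_expressing`).

The expressing denominator is deliberately **threshold-independent**, so
percentages at t = 1 and t = 2 are comparable against a fixed base.
Percentages are rounded half-up to one decimal (R's `round()` is banker's
rounding, which would turn e.g. 0.25 into 0.2); `coexpression_from_counts()`
exposes the same arithmetic for externally tabulated counts.

## Threshold calibration against impossible combinations

In a tissue where marker genes partition cell types (helper-T cells express
*Cd4* and not *Cd79a*; B cells the reverse), any double-positive call is a
mis-categorisation. The observed rate of such an *impossible combination*
therefore estimates the pipeline's false-call rate directly, with no ground
truth needed. `calibrate_threshold()` sweeps integer thresholds upward from
1 (transcripts are integers; sweeping fractions would be meaningless) and
returns the smallest t whose impossible rate is at or below the user's
bound, together with the full sweep. If no t up to `t_max` achieves the
bound the result is flagged `achieved = FALSE` — a calibration that cannot
succeed must never look like one that did.

## The statistical test

Between-condition comparisons use the two-sided Mann–Whitney U test: per-cell
counts are heavily skewed small integers and per-image percentages are few
and non-normal, so a rank test is the appropriate default. The policy in
`mann_whitney_u()` is the exact null distribution when n₁ + n₂ ≤ 16 with no
ties, otherwise the normal approximation with midranks, tie-corrected
variance and continuity correction (delegated to `stats::wilcox.test`, with
the switching policy owned and documented here). Two edge rules: identical
constant samples return p = 1 with a `degenerate` method flag, and U is
always reported for the first sample (so U(x, y) + U(y, x) = n₁·n₂). The
per-image percentage is the unit of replication for condition comparisons —
each image contributes one value — and images with zero cells are flagged
and excluded from tests explicitly.

No multiple-testing correction is applied: analyses here are single planned
pairwise comparisons, and the CSV outputs preserve the option of doing any
correction externally.

## Spatial plots and overlays

`distribution_points()` emits one point per (cell, gene) passing the
threshold, at the cell centroid. Marker **area** grows linearly with
transcript count (diameter ∝ √count), with a configurable minimum — area
coding keeps perceived ink proportional to expression; the scaling law and
the fixed Okabe–Ito gene palette are package choices, exposed as arguments.
When one cell passes for several genes, one point per gene is drawn at the
same centroid, z-ordered by descending count so small markers stay visible.
The y axis follows the image convention (origin top-left, y downward) by
default so overlays on the micrograph need no flip; a math-convention flag
exists. A centroid at (x, y) µm maps to pixel (x/sx, y/sy) under the
micrograph's physical extent, and `overlay_micrograph()` refuses extents
that do not cover the plot.

## The synthetic-tissue generator

The generator is the package's validation surface: it produces ground truth
the pipeline can be checked against bit for bit.

- **Placement**: seeded rejection sampling of centroids at a minimum
  spacing (default 12 µm) within the extent; a packing-feasibility check
  rejects impossible configurations up front.
- **Types and counts**: each cell draws a type from the configured mixture,
  then per-gene counts from a Poisson (default) or negative-binomial model.
  The default scenario is two equally frequent, mutually exclusive types —
  a helper-T-like type (*Cd4* only) and a B-like type (*Cd79a* only) — with
  a mean of 8 own-gene transcripts per cell, emulating the classic
  round-cell lymphoid validation design in which every double-positive is
  an artefact by construction. Eight transcripts per cell is a realistic
  order of magnitude for an abundantly expressed marker under RNAScope and
  leaves headroom for thresholds of 1–3.
- **Spillover**: each transcript is independently mis-allocated with
  probability p to the **nearest** other cell — nearest, not random,
  because boundary overlap is a phenomenon of adjacent cells. Transcripts
  are conserved exactly and every event is recorded. This one-parameter
  model reproduces the phenomenology that matters (false double-positives
  concentrated at low counts, rescued by t = 2) without simulating optics.
- **Intensities**: a cell's fluorescence for a gene is the sum over its
  observed transcripts of N(100, 15) draws truncated at zero (arbitrary
  units), so intensity is zero exactly when the count is zero.
- **Seeding**: one global seed drives placement, typing, counts, spillover
  and intensities through fixed derived substreams, so a configuration
  reproduces its tissue bit for bit and single stages can be re-run
  independently.

What the generator does **not** emulate: optical blur and spot-detection
errors, background fluorescence (assumed subtracted upstream via negative
controls), irregular (ramified) cell shapes, spatially clustered cell types,
and gene-gene expression correlation. Tests passing on synthetic tissue
therefore validate the *bookkeeping and inference chain* — parsing,
splitting, harvesting, classification, calibration arithmetic — not the
upstream imaging; conclusions about detection accuracy on real micrographs
are out of reach by design.

## Numerical and degenerate-input choices

- Half-up rounding everywhere a printed decimal is produced
  (`round_half_up()`), for stability of reported percentages at the .x5
  boundary.
- CSV outputs serialise doubles at 17 significant digits so a written table
  re-reads to bit-identical values.
- An export with a valid header and zero data rows is an error by default
  (`allow_empty = FALSE`): in practice it means a failed upstream export.
  The flag exists because an intentionally empty tissue (e.g. a blank
  region) is representable and must round-trip.
- An abundance query with no positive cells is an error (a mean over zero
  cells is undefined), not an NA that could propagate silently.
- A zero-cell dataset cannot be summarised (`n_total = 0` errors); a
  dataset where no cell expresses any target reports `pct_expressing = NA`
  with the denominator flagged.
- Duplicate (image, object) identifier pairs across concatenated files are
  a hard error: they almost always mean the same image was exported twice.

## Problem sizes used in the test suite

The shipped tests run the generator at 10–200 cells per tissue, 20-seed
batches for paired threshold-rescue checks, 100 random 30-cell tissues for
monotonicity properties, exhaustive Mann–Whitney enumeration up to combined
n = 10, and 2,000 null simulations for the test's size — sizes chosen so the
full suite exercises every property at tight tolerances while remaining
quick enough to run on every change.

## Known limitations

- The dialect defaults are modelled on QuPath 0.3.x; other versions may need
  a custom `qupath_dialect()` (that is the point of making it data).
- Nearest-centroid orphan assignment ignores cell shape; for strongly
  ramified cells a capture radius tuned per tissue is advisable.
- The spillover model moves transcripts only to the single nearest
  neighbour; real boundary errors can involve several neighbours at once.
- Thresholding controls mis-categorisation but cannot recover the true
  owner of a spilled transcript; re-segmentation is explicitly out of
  scope.
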