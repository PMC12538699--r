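---
title: "Methods: screen curation, replicate filtering, and the synthetic screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen curation, replicate filtering, and the synthetic screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toposcreen)
```

## The problem this package addresses

High-content screens on micro-topographical chips measure how cells —
in the motivating system, kidney podocytes — respond to thousands of
surface designs arrayed as a grid of walled TopoUnits. Between the
microscope and any downstream model sits a long chain of plumbing whose
correctness determines whether the dataset means anything: tiles must be
named so the grid position is recoverable, z-stacks collapsed without
losing puncta, segmentation artifacts culled without culling biology,
replicate units compared honestly, and every removal accounted for.
`toposcreen` implements that chain, with the accounting as a first-class
object rather than a by-product.

The package operates at the feature-table level: segmentation itself
(e.g. a CellProfiler pipeline) is upstream, and model training
(gradient boosting on design descriptors) is downstream. Both ends are
represented only by their interfaces — the required cell-table columns
on one side, exported standardized matrices and a hyperparameter fixture
on the other.

## The chip model

A chip is an `n_rows × n_cols` grid (66 × 66 by default) carrying
`n_designs` unique designs in duplicate plus `flat_count` flat units,
with the arity constraint `2·n_designs + flat_count = n_rows·n_cols`
(2 × 2176 + 4 = 4356 by default). Two placement facts are knowable from
the outside: designs are duplicated with replicates spread across the
chip, and the flat units sit in the lower-right corner, where they serve
as the orientation landmark. Everything else about placement is a
convention this package fixes explicitly: non-flat positions are ranked
by column with a seeded shuffle breaking ties, and each design receives
one position from the low-column half of that ranking and one from the
high-column half. This guarantees spatial separation of replicates and
is deterministic under the seed; it is a stated convention, not a
reconstruction of any physical chip.

Tile filenames follow
`[Channel]_[ChipID]_Col[c]_Row[r]_Seq[s]_[Stain].tif`. Numeric widths
are not dictated by the grammar, so the formatter zero-pads columns and
rows to 2 digits and the sequence to 4 — making lexicographic order
equal grid order — while the parser accepts any width. Filenames are
1-based; the sequence index is row-major acquisition order
`(r−1)·n_cols + c`, stored but never trusted for geometry.

## Derived features

* **Form factor** `4πA/P²` is 1 for a circle and below 1 for any other
  convex shape evaluated with exact area and perimeter (isoperimetric
  inequality). On rasterized masks the digitized perimeter can push the
  value above 1; such values are reported as computed, not clamped.
* **NtoC** is read as nucleus over *cytoplasm*:
  `A_nuc / (A_cell − A_nuc)`. This is the reading under which "a value
  of 1 means nucleus and cytoplasm occupy equal areas" is literally
  true; a `denominator = "cell"` switch serves users who prefer the
  plain nucleus-over-cell quotient. A cell whose recorded cell area does
  not exceed its nuclear area is exactly the mis-segmentation the metric
  exists to catch, so it yields an `NA` sentinel instead of an error,
  and sentinels are excluded from unit means with their count recorded.
* **Peripheral actin fraction** is the outermost of 4 radial bins'
  share of total signal; the bin count is fixed at 4 and bin geometry
  only matters when bins are computed from synthetic masks.
* Unit aggregation uses the n−1 SD throughout (single-cell units get an
  `NA` SD), and conserves cells exactly: unit counts plus recorded
  exclusions equal the input row count.

The CV-versus-count curve computes `sd/mean` of a *unit-level* feature
across units sharing a cell count. Whether the original analysis pooled
single cells or unit means per count bin is not determinable; unit
means are used here because the curve's purpose is to bound the
reliability of unit-level summaries.

## Three-tier QC and the ledger

Tier order is object filters → (optionally) IQR filters → count band →
NtoC percentiles; the order is configurable and the ledger records what
actually ran.

* Object tier: nuclei outside the 15–65 px diameter band (inclusive
  band — "between" is read as closed), border contact, and wall contact
  are removed; wall contact of the secondary object removes the whole
  cell record (the linkage rule), and each removal is logged with the
  first failing rule in the fixed order diameter → border → wall.
* IQR tier: quartiles use linear interpolation between order statistics
  (quantile type 7) — the convention is not dictated by the method, so
  the ubiquitous default is used, documented, and switchable. The
  multiplier k defaults to 1.5 and is exposed.
* Count band: the fixed default keeps 11–64 cells per unit ("fewer than
  11 … more than 64 … removed" reads as an inclusive-retain band).
  Alternatively the band is derived from CV curves: the maximal
  contiguous run of observed counts on which every supplied curve stays
  within `cv_ceiling` times its own minimum; if nothing qualifies the
  fixed band is used with a warning and the provenance field says so.
* NtoC percentiles: thresholds at the 2.5th/97.5th percentiles of the
  unit-mean NtoC distribution, computed once on the input and then
  frozen — re-applying a filter to its own output must not cascade, so
  every unit filter accepts precomputed thresholds. Units strictly
  outside are removed; all-sentinel units are always removed and counted
  separately.

Two historical accountings exist for the same screen — an IQR-based
curation (39,204 → 36,024 images) and a band-plus-NtoC curation
(39,204 → 31,920) — which cannot be the same pipeline run. The package
treats them as alternative tier configurations (`tiers =
c("iqr_count", "iqr_focus")` versus `c("count_band", "ntoc")`), both
supported, with the ledger making explicit which one ran.

The ledger itself enforces, at every tier and separately for images and
objects, `in − removed = next tier's in`, rejects any tier that removes
more than remains, and exposes totals. The headline worked example —
39,204 images / 1,213,838 objects, minus (5278; 63,789) then
(2006; 27,804), giving 31,920 / 1,122,245 with tier sums 7284 / 91,593 —
is exact integer arithmetic and is asserted in the acceptance suite.

## The replicate-consistency filter

Replicates of a design are compared with the k-sample Anderson–Darling
test in the tie-corrected (midrank) form. With pooled distinct values
$z_j$ of multiplicity $l_j$, $B_j$ the pooled count below $z_j$ plus
half the ties, and $M_{ij}$ the analogous count for sample $i$ of size
$n_i$ (total $N$):

$$A^2_{k} = \frac{N-1}{N}\sum_{i=1}^{k}\frac{1}{n_i}\sum_j
\frac{l_j}{N}\,\frac{(N M_{ij} - n_i B_j)^2}{B_j(N-B_j) - N l_j/4}.$$

The statistic is standardized by its exact null variance (a cubic in
$N$ involving the harmonic-type sums $H$, $h$, $g$) and the p-value is
obtained by quadratic interpolation of $\log p$ against the tabulated
asymptotic critical values $t_m(\alpha) = b_0 + b_1/\sqrt{m} + b_2/m$,
$m = k-1$, spanning $\alpha$ from 0.25 down to 0.001. Two numerical
choices matter:

* the interpolating parabola in $\log p$ has positive curvature for
  small $k$ and would bend upward far beyond the table; the evaluation
  is therefore frozen at the parabola's vertex, keeping the p-value
  monotone in the statistic (for k = 2 the vertex sits near
  $p \approx 3\times10^{-7}$, far below any decision threshold);
* the approximation is trusted as an interpolation of the tabulated
  tail ($p \le 0.25$); outside it the value is only qualitative. The
  test suite validates the tail against exhaustive permutation (all 70
  assignments for two samples of four) and large-sample behaviour
  against a seeded permutation reference, `ad_ksample_perm()`, which is
  implemented independently of the analytic path.

Degenerate input (all pooled values identical) is rejected by
`ad_ksample()` with an explicit message; inside `dual_filter()` such
designs are instead routed to the SNR arm, which assigns them infinite
SNR and removes them.

The dual filter retains a design only if the AD p-value lies in
(0.05, 1] — "low p means inconsistent replicates" read strictly — and
the SNR of the pooled replicate values lies strictly inside (2, 20).
The SNR upper bound rejects implausibly noise-free surfaces; no
mechanistic rationale is available for the specific value, so it is
carried as a documented screening convention. The two criteria are
applied in parallel on the full design set with union removal (the
alternative, AD-then-SNR-on-survivors, is obtainable by chaining two
calls); a design with fewer than two usable replicate groups is flagged
untestable rather than silently classified either way.

Replicate grouping is genuinely ambiguous in screens of this shape, so
both readings are implemented: the default compares the cell-level value
distributions at a design's two grid positions, pooled across chips
(k = 2 groups); the alternative compares chip-wise unit-level summaries.
The mode is recorded by the caller via `replicate_groups(mode=)`.
Table-style removal counts from the original screen are *not*
reproduction targets: they depend on the deposited data and on grouping
conventions left open; the package's claims about the filter are the
property-based ones (nominal type-I error, permutation agreement,
planted-artifact recall).

## Ranking and the nested split

Designs are ranked by a readout (mean retained cell count by default);
the top and bottom N (default 90) become classes 1 and 0, with ties
broken stably by design id and the bottom block drawn from designs not
already taken by the top block, so even fully degenerate readouts yield
disjoint classes of exactly N. The split holds out `round(0.2·n)` items
(round-half-up; the source procedure says "approximate", so the rounding
is fixed here and documented), splits the holdout 80/20 into test and
validation the same way, and allocates per class by largest remainder —
preserving class proportions within one item per subset. 180 balanced
items therefore split 144/29/7, and the nominal validation fraction is
0.20 × 0.20 = 4 %.

Standardization of descriptor matrices is computed on the training
subset only and applied everywhere — a deliberate deviation from
pipelines that scale before splitting, to avoid leakage into the scaler;
a `scope = "global"` mode reproduces the scale-first behaviour for
compatibility. Zero-variance descriptors are dropped with a warning and
recorded. Model training itself is out of scope; the shipped YAML
fixture of gradient-boosting hyperparameters is configuration for
external trainers, nothing in this package consumes it.

## The synthetic screen generator

The generator is the package's test bed: it draws feature tables (and
toy images) with the statistical structure the analysis assumes, so
every downstream stage is exercisable offline and scorable against
planted ground truth. It emulates:

* nine chips in two density classes — six at 39 ± 13 cells/unit, three
  (chips 4, 7, 8) at 15 ± 11 — with counts drawn as rounded normals
  truncated at 1 (the count distribution is otherwise unspecified);
* single-cell nuclear area `μ + design effect + unit effect + e` with
  μ = 737 px², total SD σ = 161 px², and unit means spreading with
  SD 65 px²;
* per-cell DAPI/phalloidin intensities from a bivariate normal with
  Pearson r = 0.83, and solidity / peripheral-actin-fraction from a
  Gaussian copula with Beta(8,2) and Beta(2,3) marginals at Pearson
  r = −0.87 (the copula attenuates Pearson correlation through the
  marginal transforms by a fixed measurable factor, 0.9856 for these
  marginals, so the latent correlation is inflated by its inverse);
* a unit-level focus score ~ N(1, 0.05²) — the screen's focus metric is
  not defined anywhere recoverable, so an abstract unitless score is
  synthesized and the real definition treated as out of scope;
* Bernoulli border/wall contact flags at 2 % each.

**Variance decomposition.** Writing σ_w and σ_b for the within- and
between-unit SDs, the generator solves
σ_b² + σ_w² = σ² and σ_b² + σ_w²·E[1/n] = (unit-mean SD)², with E[1/n]
computed exactly by enumerating the truncated rounded-normal count
distribution of each density class. The harmonic moment E[1/n], not the
arithmetic mean count, is what drives the spread of unit means when
counts vary as strongly as they do here — the low-density class puts
real mass near n = 1, and using 1/n̄ in its place underestimates the
within-unit contribution. The solution fails loudly (reporting the
implied negative σ_b²) when the requested unit-mean SD is below the
floor σ²·E[1/n] reachable for the configured counts. Gaussian marginals
keep this decomposition exact; an optional log-normal tail mixture
(default weight 0) is available for studying right-skew, at the price of
exactness. The between-unit component is split as design effect
(σ_b/2, shared by a design's replicates) plus independent unit effect,
giving the replicate filter real signal to preserve; counts receive an
analogous design effect.

**Planted artifacts.** `plant_artifacts()` corrupts a seeded selection
of units — `floor(rate · n_units)` per kind, never the same unit twice —
and records every corruption in a truth registry: counts forced to 1–5
or 70–90, focus shifted by −0.5, cell area shrunk to 1.05× the nucleus
(driving NtoC to ~20), and, per design, one replicate position's nuclear
areas shifted by 3 pooled SDs. Rates above 0.5 are rejected because the
QC thresholds themselves are estimated from the data and assume the bulk
is clean; the tests use 2 % per kind. Against the registry, the
acceptance suite requires recall ≥ 0.9 for the count band, the NtoC
percentile filter, the focus IQR filter, and the replicate filter.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: spatial autocorrelation of seeding
density across the chip, right-skewed single-cell area (unless the tail
mixture is enabled), intensity dependence on design, chip-to-chip
staining batch effects, segmentation error structure beyond the planted
kinds, and any real topography–phenotype relationship (design effects
are random, not structured). Synthetic images are schematic — walls,
pillar-dot lattice, elliptical nuclei — sufficient for the geometry
operations (cropping, orientation, projection) but not for testing
segmentation.

## Problem sizes and runtime choices

The test suite exercises three scales, chosen as the package's own
trade-off between statistical resolution and a short default test run:
a 3-chip, 16 × 16, 126-design screen (~25,000 cells) for module tests;
one full 66 × 66 chip with 2 % planted artifacts for recall checks; and
the full nine-chip default screen (~1.2 million cells) generated once
for parameter recovery, where the single-cell SD is required within 3 %
of 161 and the unit-mean SD within 10 % of 65. Type-I error of the AD
arm is measured over 600 null designs against a 3-binomial-SD band
around α = 0.05.

## Serialization

Screens serialize to a CSV directory or a single HDF5 file (one group
per table, columnar datasets, schema-version attribute); the two
renderings load to identical tables and the CSV rendering is
byte-deterministic given the store (rows canonicalized by chip, row,
column, cell id; no timestamps in provenance for exactly this reason).
The provenance block carries tool version, config hash, and seed. The
internal schema of any externally deposited HDF5 file is not documented
anywhere recoverable, so no compatibility with it is promised; this
package's schema is self-describing instead.

## Known limitations

* The AD p-value is an asymptotic interpolation; for very small samples
  use `ad_ksample_perm(exhaustive = TRUE)` when exactness matters.
* The NtoC percentile filter operates on unit means by default; a
  single-cell-level variant would catch within-unit mis-segmentation
  that unit means dilute.
* Orientation detection assumes a square grid and relies on flat units
  being texture-poor; chips whose flat block is contaminated return an
  ambiguity report rather than a guess.
* The generator's artifact kinds are idealized; real screens mix them
  within single units.
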