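---
title: "Selecting partial diffraction datasets to merge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting partial diffraction datasets to merge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxclust)
```

## The problem

In multi-crystal and serial macromolecular crystallography a complete dataset
is assembled by merging many small rotation wedges (here of the order of 2
degrees, a few percent complete each) collected from different crystals.
Crystals are never perfectly isomorphous: unit cells drift, lattices strain,
radiation damage accumulates. Merging non-isomorphous wedges degrades the
merged intensities, which matters most when the signal of interest is small —
native sulfur SAD phasing being the canonical example. The task `mxclust`
automates is therefore a selection problem: out of N partial datasets, find
the subset that is mutually isomorphous *and* pools to an acceptably complete
dataset.

## Non-isomorphism distances

The default metric works on intensities. For a pair of datasets (a, b), both
are first reduced to the asymmetric unit; repeated observations of a
reflection within one wedge are collapsed by an inverse-variance weighted
mean. The Pearson correlation cc(a,b) of the common reflection intensities is
then mapped to a distance

    d(a, b) = sqrt(1 - cc(a, b)^2),

so d = 0 for perfectly correlated wedges and d = 1 for uncorrelated ones.
The quadratic form means the distance is forgiving near cc = 1 (cc = 0.92
gives d = 0.4) and punishing at moderate correlations (cc = 0.77 already
gives d = 0.64). Because the conversion is invertible, a dendrogram cut at
height t has a direct physical reading: the selected cluster's members
correlate, on average, at 100·sqrt(1 - t^2) percent.

Three guards keep the metric honest:

* pairs whose unit cells differ by more than 1% (relative to the pair mean,
  checked on all six parameters) are assigned d = 1 before any correlation is
  attempted — this isolates outlier crystals cheaply;
* pairs sharing fewer than `n_min` reflections (default 3, tunable) have an
  undefined correlation and get d = 1, since a correlation over a couple of
  points is noise;
* non-positive correlations also map to d = 1: an anticorrelated pair is
  maximally non-isomorphous, and keeping the conversion monotone on cc > 0
  only avoids the sign ambiguity of the square.

The alternative `cell` metric is the maximal variation of the cell edges,
max(|Δa|, |Δb|, |Δc|) in Å. It is useful when cells are well determined, but
for very small wedges the cell parameters (notably those along the beam) are
too imprecise, which is why the correlation metric is the default.

## Average-linkage clustering and node bookkeeping

Clusters are built agglomeratively with average linkage (UPGMA): the distance
between clusters X and Y is the mean over all |X|·|Y| cross-pair distances.
Average linkage is monotone, so merge heights never decrease and a
"threshold" is well defined. The agglomeration itself is delegated to
`stats::hclust(method = "average")`; the tests verify its heights against a
brute-force O(n^3) re-implementation that recomputes every cluster-pair mean
from the raw matrix at every step. The merge table is re-expressed with
leaves numbered 0..N-1 in manifest order and internal nodes N, N+1, ... in
merge order, which makes the written `linkage.txt` stable and diffable. All
tie-breaks (equal cluster sizes, equal growth) resolve toward the smallest
leaf index or earliest height so that reruns are byte-identical.

## Choosing the threshold

Two estimators are provided.

**Largest-cluster growth** (`threshold_by_growth`) evaluates the size of the
largest cluster at each distinct merge height and finds the height where the
size jump is largest. The returned threshold is the merge height *preceding*
that jump. The reasoning: the biggest accretion is typically the merge that
glues two internally coherent but mutually non-isomorphous blocks together
(on two-class data it is provably the class-joining merge), and the useful
cut is the last height before it. When the maximal jump is the very first
merge — two leaves, or a chain where every merge adds one leaf and the
earliest tie wins — the first merge height itself is returned, so the
estimate is always an attainable cut. We implement the discrete size
difference rather than a smoothed derivative; with at most N-1 scan points a
derivative estimate would add a bandwidth choice without changing the argmax
in any case we examined.

**Minimal threshold for completeness** (`threshold_by_completeness`) scans
merge heights in ascending order, pools the unique asymmetric-unit
reflections of the largest cluster at each height, and returns the smallest
height whose pooled completeness reaches the target (default 98%, tunable).
Scan points are exactly the merge heights plus zero — cluster composition
only changes there, so a finer grid cannot change the answer. The resolution
limit for the completeness denominator defaults to the best resolution
observed in the input; the theoretical unique count excludes systematic
absences, which are screened from the translation parts of the symmetry
operators. If the target is never reached the maximal height is returned
with a warning rather than an error, since a pipeline can still proceed with
the most complete cluster available.

## Merging and statistics

Merging is deliberately simple: per asymmetric-unit key (Friedel-separated
when the anomalous flag is on, the default), the merged intensity is the
inverse-variance weighted mean and the merged sigma is sqrt(1/Σw). No
per-dataset scale or B-factor refinement is applied: the synthetic generator
produces data on a common scale, and real XDS-ASCII input is assumed to have
been brought to a common scale upstream. A per-dataset median-ratio scale is
available behind an opt-in flag (`scale = TRUE` in `pool_observations`) for
inputs that need it; proper error-model refinement is out of scope.

The statistics block mirrors what merging programs print. Shells are bounded
at equal volumes in 1/d^3 between the observed low-resolution limit and
d_min. Conventions worth stating:

* Rmerge, Rmeas and Rpim use the unweighted group mean and only reflections
  observed at least twice; singletons enter neither numerator nor
  denominator. For a doublet-only pool Rmeas = sqrt(2)·Rmerge and
  Rpim = Rmerge, identities the tests assert.
* CC1/2 splits each reflection's observations into random halves (the extra
  observation of odd multiplicities alternates between halves) and
  correlates the per-reflection half means. The split is seeded and the seed
  is recorded in the output, so reruns are identical. We use the random-half
  construction rather than the sigma-tau analytic form because it is directly
  testable against its defining procedure.
* sigAno is mean(|I+ - I-| / sqrt(sigma+^2 + sigma-^2)) over acentric
  reflections with both Friedel mates measured. It is computed on
  intensities; no conversion to amplitudes is in scope, so absolute values
  are not comparable to amplitude-based pipelines, while the null baseline
  is the same: under no anomalous signal the statistic concentrates at the
  half-normal mean sqrt(2/pi) ≈ 0.798.
* Completeness and multiplicity always count Friedel-merged unique
  reflections, so toggling the anomalous flag does not silently change the
  denominator.

## The synthetic generator

`simulation_config()` describes an experiment; its defaults emulate a serial
collection from ~200 microcrystals of a tetragonal protein: 184 integrated
wedges, 4.9% completeness each, unit cell 58.07, 58.07, 150.56 Å in space
group P41212 to 1.8 Å, about 2500 observations per wedge. Ground-truth
intensities are log-normal (positive, heavy-tailed — a loose stand-in for
Wilson statistics, not a physical claim) over the enumerated asymmetric
unit. With several isomorphism classes, class intensity sets share a latent
Gaussian component whose mixing weight is solved from the log-normal
correlation identity so that the expected between-class correlation equals
`between_cc` exactly. Each wedge samples a contiguous block of the
key-ordered asymmetric unit plus random scatter (half and half by default):
the block mimics the structured coverage of a rotation wedge, the scatter
guarantees that any two wedges share of the order of
(wedge_fraction)^2 · N_unique reflections, which is what makes
correlation-based clustering of 2-degree wedges workable at all. Observed
intensities carry a per-dataset-per-reflection multiplicative perturbation
sized analytically so that the expected within-class pair correlation equals
`within_cc` given the noise level, plus Gaussian noise of s.d.
noise_level·I recorded in the sigma column. Observation indices are written
as random symmetry equivalents with random Friedel parity, so the reduction
code downstream is genuinely exercised. Class cells are jittered by 0.2% by
default — inside the 1% gate, so classes must be separated by correlation,
not by the cell check.

What the generator does *not* emulate: rotation geometry and partiality,
radiation-damage time series, per-crystal scale and B drift, misindexing,
and outlier observations. Tests passing on this generator therefore
demonstrate the selection machinery (distances, clustering, thresholds,
merging arithmetic), not robustness to every pathology of real serial data.

## Numerical and design choices

* Canonical asymmetric-unit representative: the lexicographically greatest
  index triple over the orbit (including Friedel mates when merged). This is
  library-independent and makes reduction idempotent by construction.
* Embedded space groups: P1, P212121, P41212, P42212, P43212 — the primitive
  orthorhombic/tetragonal groups of the intended test systems. Extending the
  table is one xyz-triplet entry per group.
* Keys are encoded as a single double (base-1025 positional code, indices up
  to ±511), so set operations on reflections are plain vector operations.
* Observations with sigma <= 0 are dropped on input (the XDS misfit
  convention), never errored; the dropped count is kept on the dataset.
* Problem sizes in the tests: the class-recovery experiment uses 40 wedges
  per class at 5% coverage over the full 1.8 Å asymmetric unit (about 59
  common reflections per wedge pair), 100 seeds; the completeness-scan
  checks use the full 184-wedge default. These sizes keep the whole suite
  in the minutes range on a single CPU while staying in the regime the
  method is meant for.

## Known limitations

No inter-dataset scaling means datasets on genuinely different scales will
look less correlated than they are (Pearson correlation absorbs a pure scale
factor, but noise does not scale with it). The cc metric requires a common
space group across datasets and will refuse mixed inputs rather than guess a
reindexing; indexing-ambiguity resolution is a separate problem. sigAno on
intensities is not numerically comparable to amplitude-based sigAno. The
completeness estimator counts unique reflections only — it does not weight
by shell, so a cluster can hit 98% overall while its highest shell is
sparse; the per-shell table in the statistics output is the place to check.
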