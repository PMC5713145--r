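# mxclust

Hierarchical cluster analysis and merging for multi-crystal macromolecular
crystallography.

## What it is for

In serial and multi-crystal MX experiments, a complete dataset is compiled by
merging many small partial datasets ("wedges", often ~2° of rotation and a few
percent complete each) collected from different crystals. Because crystals are
not perfectly isomorphous, merging everything indiscriminately degrades the
result; this matters most for weak signals such as native sulfur SAD.
`mxclust` selects *which* wedges to merge:

1. **Distance matrix.** For every pair of unmerged datasets it computes a
   non-isomorphism distance. The default is the intensity-correlation
   distance

       d(a,b) = sqrt(1 − cc(a,b)²)

   where `cc(a,b)` is the Pearson correlation of the common asymmetric-unit
   reflection intensities. Pairs whose unit cells differ by more than 1% in
   any parameter get d = 1 (outlier gate), as do pairs with fewer than
   `n_min` common reflections or non-positive correlation. The alternative
   metric is the maximal unit-cell edge variation, max(|Δa|,|Δb|,|Δc|) in Å.
2. **Dendrogram.** Average-linkage (UPGMA) clustering: the distance between
   two clusters is the mean over all cross-cluster pair distances.
3. **Threshold.** Either given explicitly, or estimated automatically: the
   *largest-cluster growth* heuristic (cut just below the biggest jump in
   largest-cluster size) or the *minimal threshold for completeness* (the
   smallest merge height whose largest cluster pools to ≥ 98% unique-
   reflection completeness; the target is tunable). Because the distance is
   invertible, a cut at height t means the selected wedges correlate at
   `100·sqrt(1 − t²)` percent on average — a cut at 0.4 corresponds to ~92%
   correlation.
4. **Merging + statistics.** The selected cluster(s) are pooled, reduced to
   the asymmetric unit (Friedel-separated when "anomalous on", the default)
   and merged by inverse-variance weighting. The report gives completeness,
   multiplicity, half-set correlation CC1/2, Rmerge/Rmeas/Rpim, ⟨I/σ(I)⟩ and
   sigAno, overall and in equal-volume resolution shells.

Inputs are unmerged XDS-ASCII reflection files (or a documented plain-text
table), listed in a one-per-line manifest. A synthetic wedge generator
(`simulation_config()` / `simulate_experiment()`) produces controllable
test beds — isomorphism classes with chosen within/between-class correlation,
coverage, noise and cell jitter — so the whole workflow can be exercised
without experimental data.

## Worked example

Simulate two isomorphism classes of 20 wedges each (10% coverage per wedge,
within-class correlation 0.95, between-class 0.30), then cluster, estimate
the threshold from largest-cluster growth, and merge the largest cluster:

```r
library(mxclust)

cfg <- simulation_config(n_classes = 2, datasets_per_class = 20,
                         wedge_fraction = 0.1, seed = 7)
sim <- simulate_experiment(cfg, dir = "demo")         # writes files + manifest

run <- run_pipeline("demo/manifest.txt", threshold = "growth",
                    mode = "largest", anomalous = TRUE, seed = 1,
                    outdir = "demo/out")
```

The log and report this prints:

```
read: 40 datasets, 205764 observations total
distance: cc metric, 780 pairs
linkage: 39 merges, heights 0.128..0.941
threshold: 0.3126 (growth)
cut: 1 cluster(s), sizes 20
merged 20 datasets: 21855 unique, completeness 88.2%, CC1/2 0.977
clustering run: 40 datasets, threshold 0.3126, 1 merged cluster(s)
Resolution range (A)        41.07-1.80 (1.86-1.80)
Total No. of reflections    103072 (10607)
No. of unique reflections   21855 (2159)
Completeness (%)            88.2 (89.2)
Multiplicity                4.7 (4.9)
Half-set correlation CC1/2  0.977 (0.978)
<I/sigma(I)>                20.6 (21.0)
Rmerge                      0.105 (0.105)
Rmeas                       0.124 (0.123)
Rpim                        0.063 (0.063)
sigAno                      1.216 (1.226)
```

Reading it: the within-class merges all happen below ~0.45 and the two
classes only join at 0.94, so the growth estimator cuts at 0.31 and the
largest cluster is exactly one 20-wedge class (`sim$labels` confirms zero
mis-assignments). Twenty wedges at 10% coverage pool to 88% completeness
with multiplicity 4.7; CC1/2 of 0.98 and Rmeas of 0.12 reflect the 0.95
within-class correlation plus 10% measurement noise. Values in parentheses
are the highest-resolution shell. `demo/out/` now holds the labelled
distance matrix, the linkage table, and one directory per merged cluster
with the merged reflections, a JSON statistics report, the member list and
the threshold used.

A command-line wrapper with `cluster`, `merge`, `stats` and `simulate`
subcommands is installed at
`system.file("cli", "mxclust.R", package = "mxclust")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mxclust.R",package="mxclust"))')" \
    cluster --manifest demo/manifest.txt --threshold completeness --outdir demo/out
```

## Documentation

The methods vignette (`vignettes/multi-crystal-clustering.Rmd`) documents the
model, the two threshold estimators, merging conventions, what the synthetic
generator does and does not emulate, and known limitations.
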