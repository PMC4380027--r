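---
title: "Profiling peptide families with ampsieve: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling peptide families with ampsieve: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ampsieve)
library(dplyr)
```

`ampsieve` characterizes a peptide family by the smallest feature set
that lets unsupervised k-means clustering isolate the family from a
background of unrelated peptides. This vignette explains the model,
the parameters that matter, the numerical conventions, and what the
synthetic benchmark does and does not demonstrate.

## The region model

A peptide of length $L$ is split into four N-terminal sub-regions
(`n1`–`n4`) of $d_N$ residues each, a C-terminal region of $d_C$
residues, and a middle region `M` with the remainder. Family signals in
antimicrobial peptides concentrate at the termini, which is why the
N-terminus gets the finest resolution. When $L < 4 d_N + d_C$ the
layout shrinks proportionally: the N block receives
$\lfloor 4 L d_N / (4 d_N + d_C + 1) \rfloor$ residues (split as evenly
as possible across `n1`–`n4`, earlier sub-regions taking the
remainder), the C-terminal $\lfloor L d_C / (4 d_N + d_C + 1) \rfloor$,
and `M` the rest. Because flooring can zero out a region at very small
$L$, single residues are then reassigned from the largest region until
all six are non-empty; this repair is deterministic, so a given
$(L, d_N, d_C)$ always yields the same spans. In the nominal layout
the middle region simply holds $L - 4d_N - d_C$ residues and may be
empty; empty regions encode as zero vectors rather than errors, so
short peptides remain representable. Sequences shorter than 6 residues
are rejected — there is no sensible six-region layout for them.

```{r}
partition_regions(19, d_n = 10, d_c = 10)
```

$d_N$ and $d_C$ are tunable per family (residue units). The search
grids used by `select_family_features()` are
$d_N \in \{10, 12, 14, 16\}$ and $d_C \in \{8, 10\}$, which bracket the
terminal lengths that discriminate well for short cationic peptides;
single values can be passed for quick runs.

## The compositional feature vector

Each peptide maps to 184 features in a fixed order: residue composition
in the six regions and the full sequence ($7 \times 20$), twin
(adjacent identical) residue composition in `M` (20), and four six-bin
distance-frequency histograms (24). A distance histogram looks at the
gaps $H$ between successive residues of a class — basic (R, K, H),
hydrophobic (I, V, L, F, M, A, G, W, P), or the remaining "other"
class — and counts them into $H = 1$, $1 < H \le 6$, $6 < H \le 11$,
$11 < H \le 16$, $16 < H \le 21$, $H > 21$. Basic-residue histograms
are computed for the N block (`n1`–`n4` concatenated; gaps never span
the N/M boundary) and for `M`; hydrophobic and other histograms for `M`
only.

Conventions worth noting:

* Distance frequencies are **raw counts**, not length-normalized: for
  `ARMRAASKAALLMAHKNAK` the basic-residue gaps are 2, 4, 7, 1, 3 and the
  histogram is (1, 3, 1, 0, 0, 0).
* Twin composition counts **overlapping** pairs (`"AAA"` has two
  A-twins) and divides by the number of adjacent pairs, $L - 1$; a
  composition-style normalization keeps the feature comparable across
  region lengths. Whether to normalize at all was a genuinely open
  choice; the convention is pinned by tests.
* Composition of an empty span is all zeros; of a non-empty span it
  sums to 1 within $10^{-12}$.

## Restrictive physicochemical properties

Amino-acid property scales (AAIndex1 format; one real value per
canonical residue, scales with missing values dropped at parse time)
are first pruned: a graph connects scales with $|r| \ge 0.9$ (Pearson,
over the 20 residue values), and one representative per connected
component is kept, drawn uniformly under a caller-supplied seed. The
absolute value matters — anticorrelated scales carry the same
information up to sign. Zero-variance scales, for which correlation is
undefined, stay as singletons with a warning.

A (property, region) pair is *restrictive* for a family when the
family's residues in that region occupy a narrow, characteristic band
of the scale. The test is leave-one-out: peptide $i$ passes if every
residue in its region has a property value inside the min/max envelope
of the values taken by that region across the other family members; the
pair is retained when the pass fraction reaches the coverage threshold
(default 0.9, inclusive — "at least 90% of peptides"). A peptide with
an empty region passes vacuously; if all *other* peptides have the
region empty, a non-empty held-out region fails (there is no envelope
to be inside of); a region empty in every family member is skipped.
Each retained pair becomes one feature: the **median** property value
over the peptide's region residues (even counts average the two central
values; empty regions give 0), computed identically for family and
non-family peptides.

By default the envelope test runs on the raw region-partitioned
sequences. An alignment-based mode is also provided
(`mine_restrictive(..., alignment = progressive_align(family))`), where
region spans are taken on alignment columns and gaps are skipped;
aligning the family first can sharpen envelopes when members differ
mainly by indels. The region-based mode is the default because the
region definitions are stated on sequences and the mode needs no
aligner parameters.

## Progressive alignment

The bundled aligner is a standard progressive scheme: Gotoh affine-gap
global alignment (a gap of length $g$ scores
$\text{open} + g \cdot \text{extend}$; BLOSUM62, open $-10$, extend
$-1$ by default — the usual protein-alignment defaults, configurable),
an average-linkage (UPGMA) guide tree on score-derived distances
($d = \max s - s$), and profile–profile merges with sum-of-pairs column
scores in which gap characters carry zero weight. Traceback ties
resolve diagonal-first, then gap-in-second, then gap-in-first, so
alignments are reproducible. `read_alignment()` is an escape hatch for
alignments computed with any external tool.

## Preprocessing, clustering, and evaluation

Feature matrices are filtered (columns constant across all peptides are
removed — they carry no information and break scaling) and z-scored,
$x' = (x - \mu)/\sigma$, with statistics over *all* peptides in the
family-specific matrix, target and background alike. The sample
standard deviation ($n-1$) is used; the population convention is one
argument away and the choice only rescales columns uniformly.

k-means uses squared-Euclidean Lloyd iterations from **class-mean
centroids**: cluster 1 starts at the target-family mean and, for
$K = 2$, cluster 2 at the background mean. For $K > 2$ the background
rows are pre-split by a seeded k-means++ draw of $K-1$ centers among
them and their group means used — this keeps the class-informed,
reproducible character of the two-cluster start without inventing
structure in the target class. Assignment ties go to the lowest cluster
index; a cluster left empty is reseeded to the point farthest from its
current centroid; iteration stops when assignments stabilize (cap 300).

After clustering, the cluster with the most family members (ties to the
lowest index) is the *target cluster*, giving TP/FP/FN/TN and the
derived accuracy, sensitivity, specificity, precision, F-measure
$= 2TP/(2TP+FN+FP)$, and Jaccard index $= TP/(TP+FP+FN)$. Entropy is
the cluster-size-weighted class entropy in bits,
$\sum_k \frac{n_k}{n} H_k$, and purity the fraction of peptides in
their cluster's dominant class; both follow the standard external
clustering criteria, with purity accumulated in integer counts so that
purity $= 1$ and entropy $= 0$ coincide exactly.

## GA feature selection

The wrapper selection minimizes
$F = 1 - \text{F-measure} + m/N$ over binary feature masks, where $m$
of $N$ candidate features are selected: the first term rewards a clean
family cluster, the second biases toward parsimonious, interpretable
subsets. The GA is generational with tournament selection (size 2),
uniform crossover at rate 0.8, per-bit mutation at rate 0.01, elitism 1,
and initial bits set with probability 0.5 — the crossover and mutation
rates are the published operating point for this fitness; the operator
choices themselves were open and these are robust defaults for binary
encodings, all configurable via `ga_config()`. An empty mask scores the
worst possible fitness, 2. Fitness values are memoized within a run, and
every stochastic step runs under the single run seed, so identical
configurations reproduce results bit for bit.

`ga_config()` defaults to the full-scale settings (population 1000,
1000 generations). The examples in this vignette, the test suite, and
the CLI's defaults use population 60 and 40–50 generations on matrices
of a few hundred features and tens of peptides — sizes chosen so a
complete profiling run takes seconds while still letting the GA
separate planted signal from noise; the CLI's `--paper-scale` flag
restores the full settings. `select_family_features()` re-runs the GA
per grid cell ($d_N, d_C, K$) and returns the run with the best
F-measure, breaking ties toward fewer features, then smaller $K$,
$d_N$, $d_C$ — the parsimony order. $K$ is an outer loop rather than a
chromosome field so each GA run optimizes a fixed clustering geometry.

## The synthetic benchmark

`generate_peptides()` emulates the structure the profiler is meant to
detect: families with (i) per-region residue enrichments — the
background residue distribution reweighted by a planted factor — and
(ii) per-region property restrictions — region residues truncated to
those whose value under a planted scale falls in a planted interval —
plus an unbiased background pool. Defaults: uniform background over the
20 residues, lengths uniform on 30–90 residues (typical of mature AMPs,
most of which are under 100 residues), families of 20 peptides
(curated AMP families usually hold 10–50). All generation runs under
one seed and regenerates byte-identically.

```{r}
spec <- synth_spec(
  n_families = 1, peptides_per_family = 12, n_background = 20,
  enrichments = tibble(family = 1L, region = "n1",
                       residue = "R", weight = 20),
  seed = 11
)
peps <- generate_peptides(spec)
feats <- encode_basic(peps)
feats |>
  group_by(family) |>
  summarise(mean_R_n1 = mean(`composition:n1:R`))
```

What passing on synthetic data shows: the encoder exposes planted
regional biases, the miner recovers planted (property, region) pairs at
their design coverage, and the GA finds small separating subsets when
they exist. What it does not show: performance on real families, whose
signals are weaker, correlated across regions, and entangled with
phylogeny; the generator plants independent signals into an i.i.d.
background and does not model evolutionary relatedness, indels between
family members, or realistic residue frequencies (an empirical
background distribution can be supplied, but is not the default).

## Degenerate inputs and numerical conventions

* Non-canonical FASTA records (B, Z, J, X, U, O) are skipped whole at
  read time — per-residue masking would corrupt region lengths.
* Median of an even number of values is the mean of the two central
  values; envelope and coverage comparisons are inclusive.
* Cluster-count grids are capped by the number of peptides; classes
  must both be present for initialization and evaluation.
* All tolerances used in tests: composition sums to 1 within
  $10^{-12}$; z-scored columns hit mean 0 / sd 1 within $10^{-9}$;
  clustering and GA oracle equivalences hold to $10^{-9}$ and
  $10^{-12}$ respectively.

## Known limitations

* The restrictive-envelope test is brittle to single outlier residues
  by construction; that is intentional (it is what "restrictive"
  means), but noisy annotations can suppress genuinely characteristic
  properties.
* The progressive aligner is a plain sum-of-pairs scheme without
  iterative refinement; for families with long indels an external
  alignment via `read_alignment()` is preferable.
* Grid search re-runs the GA per cell; the full grid at full GA scale
  is computationally heavy and intended for batch use through the CLI.
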