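---
title: "Ensemble-guided RNA structure alignment and motif clustering: methods"
author: "dotclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-guided RNA structure alignment and motif clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotclust)
```

This vignette documents the models, parameters and numerical choices
behind `dotclust`, in the spirit of a methods section: what is computed,
under which assumptions, and what the shipped tests do and do not
establish.

## 1. The ensemble representation

Every sequence is represented by its **dot plot**: the symmetric matrix of
base-pair probabilities $p_{ij}$ over the Boltzmann ensemble of its
nested secondary structures. Downstream code never looks at a single
predicted structure; it consumes $p_{ij}$ and the derived
**unpaired profile** $q_i = 1 - \sum_j p_{ij}$.

Dot plots can be supplied externally (the PostScript dot-plot dialect,
where `ubox` entries store $\sqrt{p}$, or a plain TSV), or computed by the
built-in folding engine. The engine exists so that the whole pipeline is
self-contained and testable without downloads; it is *not* a full
nearest-neighbour thermodynamic model.

### The simplified energy model

A structure $S$ is a non-crossing set of canonical pairs (G·C, A·U, G·U)
with hairpin loops of at least `min_hairpin = 3` unpaired residues. Its
weight is

$$V(S) = \sum_{(i,j) \in S} w(i,j) \;+\; b \cdot \#\{(i,j) \in S : (i{+}1, j{-}1) \in S\}$$

with defaults $w(GC)=3$, $w(AU)=2$, $w(GU)=1$ and stack bonus $b=1$
(dimensionless, $kT=1$); the reported "energy" is $-V$. These weights
keep the familiar stability ordering GC > AU > GU, and the stacking term
provides the helix cooperativity that makes ensembles concentrate on
stems rather than isolated pairs. Base-pair probabilities are exact under
this model: McCaskill-style inside recursions compute interval partition
functions $Z(i,j)$ and pair-closed functions $Z_b(i,j)$, an outside pass
computes the complementary weights, and
$p_{ij} = Z_b(i,j)\,\hat Z(i,j)/Z$. Arithmetic is carried in scaled form
(per-base scale $C = \exp(V^*/n kT)$ from the max-weight structure $V^*$)
so both strong and structure-free sequences of several hundred nt stay in
double range.

Entries below `p_min = 0.001` are dropped from the dot plot. This floor
realises the fold-envelope idea as a probability threshold: ensemble
elements with $p < 10^{-3}$ contribute nothing measurable to the
alignment score but dominate memory and time.

Because the engine is simplified, absolute energies and SCI values are
comparable **within this engine only**. Any thermodynamic folder can be
plugged in by supplying its dot plots to the aligner; none is required.

### The maximum-weight folder

`mfe_fold()` (and its consensus variant) run the same model through a
Nussinov-style maximisation; it supplies the numerator and denominator of
the structural conservation index. Backtracking ties are broken toward
the lexicographically smallest pair list (prefer pairing the leftmost
base, then its smallest partner) so results are reproducible across
platforms. For the consensus, a column pair is admissible when at least a
fraction `rho` (default 0.5) of rows are complementary there, with weight
equal to the mean over all rows (non-complementary rows contribute 0);
requiring the fraction to be strictly positive prevents stacking bonuses
from accruing on unsupported pairs.

## 2. The two-step aligner

### Base-wise similarity

$$\sigma(x_i, y_j) = \theta\, m(x_i,y_j) + (1-\theta)\,(1 - |q^X_i - q^Y_j|)$$

with $m = 1$ for identical residues and `mismatch_score` (default 0)
otherwise. $\theta$ (default **0.5**) is the weight of sequence identity
against unpaired-probability similarity — at $\theta = 1$ (with
$\kappa = 1$) the aligner degenerates to plain Needleman–Wunsch, which
together with `free_end_gaps = TRUE` provides the sequence-only
semi-global baseline.

### Step 1: optimal path and partition function

Gotoh three-layer recursions maximise $\sum \sigma$ with affine gaps:
a gap of length $L$ costs $g_o + (L-1)\,g_\mathrm{ext}$, defaults
$g_o = 1$, $g_\mathrm{ext} = 0.05$. (The convention — opening column
charged $g_o$, each further column $g_\mathrm{ext}$ — is one of the two
common readings of "open + extend"; it is fixed here and mirrored by the
enumeration oracle in the tests.) Replacing max with log-sum-exp of
$\exp(\text{score}/T)$ gives the partition function $Z$ over all global
alignment paths. With `free_end_gaps`, terminal single-type gap runs cost
nothing and the path space excludes alignments whose terminal runs mix
gaps in both sequences (the conventional semi-global space); this is
enforced identically in the max, partition and sampling recursions so the
three stay mutually consistent.

### Step 2: stochastic backtracking and dot-plot scoring

`sample_paths()` draws $s$ paths, each with probability
$\exp(\text{score}/T)/Z$, by tracing the partition matrices backwards.
$T$ (default **0.25**) controls sampling diversity; scores saturate by
$s \approx 1000$ at this temperature, and at $T = 0.01$ the sampler
collapses onto the optimal path (both properties are asserted in the
tests). Every candidate path (optimal + samples) is rescored by

$$\text{dp}(\pi) = \sum_{\substack{(i,j),(i',j') \in \pi \\ i < i'}} p^X_{ii'}\; p^Y_{jj'},$$

the superposition of the two dot plots along the path, and the final
similarity is

$$\text{score} = \mathrm{clamp}\!\left(\kappa \frac{\text{raw string score}}{\sqrt{|X||Y|}} + (1-\kappa) \frac{\text{dp}(\pi)}{\sqrt{\sum (p^X)^2 \sum (p^Y)^2}},\; 0, 1\right)$$

with $\kappa = 0.3$. Normalising by the self-alignment geometric means
anchors identity at exactly 1, which is what the dissimilarity transform
downstream assumes. Whether the published method normalises by
self-alignment or by length alone is not stated in its description; the
self-normalisation is this package's choice, so absolute scores are
comparable within `dotclust` only — rank behaviour (classification,
clustering) is the meaningful surface. For the same reason the default is
`n_samples = 0`: sampling buys a slightly better path at ~25× the cost,
and the clustering results do not need it.

Symmetry: `align_pair()` canonically orders the pair by id before
aligning, so `score(x, y) = score(y, x)` to $10^{-9}$ including
tie-breaks (match > gap-in-Y > gap-in-X).

An optional diagonal band (`band_width`) implements the
alignment-envelope heuristic; it is off by default because the benchmark
sequences are short enough for full matrices.

**PID** is reported as identical match columns over *all* alignment
columns (gap columns count in the denominator). Conventions differ
between tools; this one is applied uniformly and only rounded for
display.

## 3. Clustering

All-vs-all scores (diagonal 1) are inverted and min–max rescaled over the
off-diagonal entries: best pair → distance 0, worst → 1
(`to_dissimilarity()`; a degenerate all-equal matrix is an error with a
`no_rescale = TRUE` escape hatch). OPTICS then runs on the precomputed
distances — mirroring a `search = "dist"` call, no spatial index — with
`eps = 1` (the whole normalised range) and `minPts = 4`. The core
distance counts the point itself (distance to the (minPts−1)-th other
point), the convention of standard DBSCAN and of the common OPTICS
implementations; the DBSCAN oracle in the tests uses the same convention.
The visit starts at the lowest-index unprocessed point and priority ties
break by index, making the ordering fully deterministic.

Clusters are extracted with the xi-steepness method at `xi = 0.006`:
valleys bounded by ξ-steep down/up areas, with up to `minPts` consecutive
non-steep points tolerated inside an area, the mib (maximum in between)
conditions of the original algorithm, and predecessor correction peeling
trailing points that were reached from outside the valley (as modern
implementations do). Clusters smaller than `minPts` are dropped;
`minimum_only = TRUE` keeps only leaf clusters, and the trivial "cluster"
spanning the entire ordering is never reported (hence flat reachability
yields no clusters). Infinite reachability is serialised as the string
`"inf"` in reports and drawn capped at 1.05× the largest finite value in
plots.

## 4. The synthetic benchmark: what it emulates

`make_benchmark()` builds the stated world the tests run in: families of
sequences that share a secondary structure while diverging in sequence,
plus negatives that preserve composition but not structure.

* A family consensus is a random nested structure, stems of 3–8 pairs,
  hairpins ≥ 3, 40–70 % of residues paired — the regime of structured
  ncRNA families. Lengths are drawn from 70–170 nt.
* Members derive from a structure-compatible ancestor by **compensatory
  substitution**: at paired sites the whole pair is redrawn (G·U with
  probability 0.1), at loops residues mutate freely. The mutation rate is
  tuned, with rejection, until every pairwise identity lands in the
  requested band (default 55–95 %). Compensatory change is the essential
  statistical property copied from curated RNA families: it decouples
  sequence identity from structural homology.
* Controls are **dinucleotide-preserving shuffles** of the members, 1:1,
  via Euler-path resampling (random arborescence by loop-erased random
  walks, then random exit orders), which samples uniformly among all
  arrangements with the exact dinucleotide multiset and fixed terminal
  residues.

What the generator does **not** emulate: indels within families (members
are equal-length, so family PID is positional), pseudoknots, modified
bases, transcript context, and the heterogeneous length/GC distribution
of real CLIP fragments. A green benchmark therefore establishes that the
pipeline separates ensemble-level structural homology from composition at
realistic identity ranges — not performance on any particular organism's
data.

At the default scale (5 families × 8 members + 40 controls) the pipeline
at default parameters recovers all families with sensitivity ≥ 0.7 and
specificity ≥ 0.85 under the cluster-level confusion bookkeeping
(dominant family counts as TP, tied or control-dominated clusters charge
1 FP — a documented reading of an ambiguous rule; set
`fp_counts_members = TRUE` to charge all members instead).

## 5. Numerical choices and degenerate inputs

* Folding uses scaled arithmetic (§1); alignment partition recursions are
  in log space and stay finite to length 500 (tested).
* Oracle tolerances: enumeration comparisons at $10^{-9}$; file
  round-trips at $10^{-12}$; score symmetry at $10^{-9}$.
* Empty sequences error; sequences without complementary bases produce
  empty dot plots, whose dot-plot score term is defined as 0.
* `mcc()` returns 0 when a root factor is 0 and errors on all-zero
  counts; `sci()` returns 0 for a zero mean single energy; `delta_sci()`
  errors on a zero reference.
* Sampling reproducibility: one seeded R RNG stream; in `all_vs_all()`
  each pair derives its own seed from the base seed and the pair indices,
  so results are identical for any worker count.
* ROC-AUC uses each unordered pair once (upper triangle) with half-credit
  ties; note that three-score textbook examples are easy to get wrong —
  the tests pin `roc_auc(c(0.9, 0.8, 0.4), c(1, 0, 1)) = 0.5` (one
  concordant, one discordant pair).

## 6. Known limitations

* The folding engine is a weight model, not Turner thermodynamics;
  absolute SCI/energy values do not transfer across engines.
* No local alignment optimisation: free end gaps expose local similarity,
  but boundary refinement of motifs is out of scope.
* No pseudoknots anywhere (folding, consensus, Stockholm import strips
  them).
* The xi extraction follows the original steep-area algorithm; clusters
  near the reachability plot's ends depend on the implicit infinite
  sentinel past the last point, as in other implementations.
* `cluster_confusion()` implements one documented reading of the
  tied-cluster FP rule; the alternative is available behind a switch.
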