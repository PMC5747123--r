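# dotclust

Ensemble-guided pairwise RNA structure alignment and unsupervised
clustering of RNA structure motifs.

## The problem

Many functional RNAs conserve their secondary structure while their
sequence drifts: below roughly 60 % sequence identity, sequence-only
alignment stops recovering common structural features. Full
sequence-and-structure alignment (the Sankoff algorithm) is too expensive
for the all-vs-all comparisons that motif discovery needs. `dotclust`
takes the middle road: each sequence is represented by its *dot plot* —
the matrix of base-pair probabilities `p(i,j)` over its whole Boltzmann
ensemble of secondary structures — and pairs of sequences are aligned by a
fast string alignment that is *guided* by those ensembles. The resulting
similarity drives density-based clustering that pulls out groups of
structurally homologous sequences (e.g. from CLIP peak collections)
without any a-priori family model.

## The method

**Pairwise alignment** works in two steps.

1. A Gotoh-style affine-gap dynamic program maximises the summed base-wise
   similarity

   σ(x_i, y_j) = θ·m(x_i, y_j) + (1 − θ)·(1 − |q_i − q_j|)

   where `m` is sequence identity and `q_i = 1 − Σ_j p(i,j)` is the
   probability that a base is unpaired; θ (default 0.5) weighs the two.
   The same recursions, with max replaced by log-sum-exp of Boltzmann
   weights `exp(score/T)`, give a partition function over *all* alignment
   paths.
2. Suboptimal paths are drawn from that partition function by stochastic
   backtracking (each path with probability `exp(score/T)/Z`) and every
   candidate path is rescored by how well it superimposes the two dot
   plots: Σ p^X(i,i′)·p^Y(j,j′) over matched position pairs. The final
   similarity is

   score = clamp(κ·seq_norm + (1 − κ)·dotplot_norm, 0, 1), κ = 0.3,

   with both terms normalised so that a self-alignment scores exactly 1.
   With `n_samples = 0` (the default, and the recommended trade-off) only
   the optimal string path is rescored.

**Clustering**: all-vs-all scores are inverted and rescaled to a
dissimilarity matrix (best pair → 0, worst → 1), ordered by OPTICS
(`eps = 1`, `minPts = 4`) on the precomputed distances, and clusters are
extracted as reachability valleys with the xi-steepness method
(`xi = 0.006`, leaf clusters only). Items in no cluster are noise.

The package also bundles: a simplified thermodynamic folding engine
(McCaskill-style inside/outside over a pair-weight + stacking model) so no
external folding software is needed; quality metrics (MCC, SCI, ΔSCI,
structure edit distances, ROC-AUC, cluster confusion); a synthetic
benchmark generator (structure-constrained families at controlled pairwise
identity with dinucleotide-shuffled controls); and CLIP-peak
pre-processing (≥ 8-fold enrichment, P ≤ 1e-4, > 50 nt overlap merging,
same-strand intersection).

## Worked example

```r
library(dotclust)

fam <- read_fasta(system.file("extdata", "synthetic_family.fa",
                              package = "dotclust"))
aln <- align_pair(fam$seq[1], fam$seq[2],
                  id_x = fam$id[1], id_y = fam$id[2])
aln
#> <dot_alignment> synthetic_m01 vs synthetic_m02
#>   score 0.7250 (seq 0.7880, dotplot 0.6980)  PID 77%
#>   GCGUUCUGUUGACGAGAUCCAGUAAUCGACGGUUUGUCGCGUGGUGACAUUGUACUUACUGGACUGCGCA
#>   GUUUAAUGCUGCCGAGAACCAGUCCUCGUCGGUUUGUCGCGUGGUGACAUUGAACGGACUGGUCGGAGCA
```

The two family members share 77 % sequence identity and a conserved
structure, giving a combined similarity of 0.725 (sequence term 0.788,
dot-plot term 0.698). A dinucleotide-shuffled control of the same
composition scores only 0.174 against the first member — that separation
is what the clustering stage exploits. The family's alignment has a
structural conservation index (consensus folding energy over mean single
energies) of 0.944, close to the value 1 expected for a perfectly
conserved structure:

```r
st <- read_stockholm(system.file("extdata", "synthetic_family.sto",
                                 package = "dotclust"))
sci(st$alignment$aln)
#> [1] 0.944
```

A full discovery run on a labelled synthetic benchmark:

```r
bench <- make_benchmark(n_families = 5, members = 8,
                        pid_range = c(55, 95), seed = 1)
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 1), seqs = bench)
res$metrics
#> sensitivity 1.00  specificity 0.95 ...
```

All 5 planted families come back as distinct clusters; of the 40 shuffled
controls only a couple are dragged into clusters (specificity 0.95 at
seed 1).

A command-line front end with `fold`, `align`, `cluster`, `eval`,
`simulate`, `peaks` and `pipeline` subcommands lives at
`inst/cli/dotclust.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it generates the synthetic benchmark (5 families × 8 members at
55–95 % identity, 70–170 nt, plus one dinucleotide-shuffled control per
member), folds every sequence, performs the all-vs-all ensemble-guided
alignments at the default parameters, clusters with OPTICS/xi and writes
the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
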