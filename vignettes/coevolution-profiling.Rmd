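---
title: "Detecting co-evolving genes from phylogenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-evolving genes from phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functionally linked bacterial genes — members of one pathway, complex or
cellular process — tend to be gained and lost together in evolution. Given
a panel of genomes and all-vs-all protein similarity searches, the pattern
of presence and absence of a gene's orthologs across the panel (its
*phylogenetic profile*) is therefore a signal of function: genes whose
profiles are correlated are candidates for a functional link, even when
neither gene has an annotation. `phylocoevo` implements a complete desk-
scale pipeline for this inference, from raw BLAST-style hit tables to
clusters of co-evolving genes, together with a simulator that generates
fully specified synthetic panels with planted truth.

## The method

### Orthologs and the per-gene adaptive threshold

Orthologs are called as bidirectional best hits (BBH): genes `a` (organism
A) and `b` (organism B) are orthologs when each is the other's best-scoring
match. The score of a hit is

    s = i * c

where `i` is the percent identity and `c` the alignment length divided by
the length of the *longer* of the two proteins, clamped at 1; `s` lives on
a 0–100 scale. Ties inside the best-hit search break by higher identity,
then lexicographic subject id, so results are deterministic.

A fixed global cutoff on `s` treats all genes as if they diverged at one
rate, which they do not: a fast-evolving gene's genuine orthologs in
distant genomes score far below the equally genuine orthologs of a slow
gene. There is no common molecular clock. The pipeline therefore thresholds
each gene against *its own* score distribution. For one target gene with
candidate scores `s_1 … s_n`, candidate `k` is retained iff

    s_k > avg(s)   OR   d(s_k) > avg(d)

where `d(.)` is a Gaussian kernel density estimate over the gene's own
scores, evaluated at each candidate's score. The first clause keeps the
well-conserved half of the candidates; the second rescues coherent blocks
of organisms that maintain the gene under a common (possibly fast) regime —
a dense clump of similar scores is evidence of a family of genomes keeping
the gene functional, wherever that clump sits on the score axis.

Numerical choices, made once:

* the density estimator is a Gaussian KDE with Silverman's rule-of-thumb
  bandwidth (`stats::bw.nrd0`), evaluated at the candidate scores
  themselves (not on histogram bins);
* degenerate samples — a single candidate, or zero variance — take uniform
  density 1, so the strict inequalities fail and the tie rule applies:
  **if the rule selects nothing (all scores equal), all candidates are
  retained.** Equal scores are equally credible orthologs, and dropping
  all of them would erase a perfectly conserved gene;
* the averages are over the gene's own candidates only, never pooled.

### Profiles and the phi coefficient

The retained orthologs of each target-organism gene define a binary
occurrence vector over the panel (the gene's own organism is always 1).
Two profiles are compared with the phi coefficient computed from the 2×2
contingency counts,

    phi = (n11*n00 - n10*n01) /
          sqrt((n11+n10)(n01+n00)(n10+n00)(n01+n11))

which equals the Pearson correlation of the 0/1 vectors and is symmetric.
If either vector is constant a marginal factor vanishes; the package
returns 0 by convention — a ubiquitous (or panel-absent) gene carries no
co-occurrence information, and the convention drops such genes from
networks without NaN propagation.

### Weighting by phylogenetic distance

Sequenced genomes are a heavily skewed sample of the tree of life: dozens
of near-identical strains for some taxa, single representatives of others.
Co-occurrence inside a clump of near-identical genomes is weak evidence;
co-occurrence across distant genomes is strong evidence. Lacking a genome
evolution model, the pipeline uses a phenomenological content-based
distance between organisms,

    D(A,B) = 1 - N(A,B) / max(N(A), N(B))

with `N(A)` the gene count of organism A and `N(A,B)` the number of BBH
ortholog pairs between A and B. `N(A,B)` is deliberately *not* filtered by
the per-gene adaptive selection: it measures genome-content overlap, and
tying it to the selection would let per-gene threshold noise inflate the
apparent distance between near-identical genomes — precisely the genomes
the weighting must recognise as redundant.

For a gene pair, the relevant distance is `dmax`, the largest `D(A,B)`
over organisms A, B in which *both* genes occur. If the genes co-occur in
at most one organism there is no witnessing pair and `dmax = 0`. The
weight enters cubed — a deliberately non-linear boost for co-occurrence
across distant genomes — giving the raw score `phi * dmax^3`.

### The gene-neighborhood factor

Conserved gene neighborhood is independent evidence of a functional link.
The pipeline multiplies the score by

    K = 1    if the two genes are found at least once in synteny
    K = 0.9  otherwise

"In synteny" means: in at least one organism (including the target genome
itself), the representatives of the two genes lie on the same replicon
with at most `window` intervening gene positions (default 5; adjacent
genes have 0). Strand is ignored. This windowed proximity criterion stands
in for a full graph-matching synteny engine: since only the binary outcome
enters the 10% factor, a simple, exactly testable rule preserves the
method's behaviour.

The final co-evolution score is

    C(X,Y) = phi(X,Y) * dmax^3 * K(X,Y)

symmetric in X and Y. Scoring all gene pairs of a target organism yields
n(n-1) ordered scores; symmetry collapses them to one score per unordered
pair. Edges with `C >` a threshold (default 0.77) form the co-evolution
network. Because `dmax^3 <= 1` and `K <= 1`, `C <= phi`, and pairs with
`phi` below a non-negative threshold can be skipped exactly.

### Markov clustering

The network is partitioned with a from-scratch Markov Cluster algorithm:
the thresholded adjacency gets a self-loop per node equal to its maximum
incident edge weight (1 for isolated nodes), is column-normalised, and
then alternates expansion (matrix squaring) with inflation (entrywise
power, default 2, followed by pruning of entries below `1e-5` — the column
maximum always survives — and renormalisation) until the largest entry
change is below `1e-8` or 100 iterations pass. Clusters are read from the
attractor structure: rows with positive diagonal mass are attractors,
attractors joined by positive flow merge, and each node follows the
attractor holding most of its column mass (ties to the lexicographically
smallest gene id). The procedure is deterministic, and a threshold sweep
utility re-filters and re-clusters the network across a threshold grid,
tracking a query gene's cluster size.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| edge threshold | 0.77 | minimum C for a network edge |
| synteny window | 5 | max intervening genes for "in synteny" |
| distance exponent | 3 | power on dmax (exposed for experimentation) |
| MCL inflation | 2.0 | entrywise power per iteration |
| MCL pruning | 1e-5 | entries dropped after inflation |
| MCL tolerance | 1e-8 | convergence threshold on entry change |

The 0.77 threshold is calibrated for panels in which distant genomes share
a small fraction of their gene content, so that `dmax^3` can approach 1.
On very small panels with large proportional overlap (such as the 6-genome
worked example shipped with the package, where no organism pair exceeds
`D = 7/12`) every score is compressed by `dmax^3 <= 0.2`, and a
correspondingly lower threshold must be used; the worked example's golden
run uses 0.15.

## The synthetic panel generator

`simulate_panel()` produces genome tables, hit tables and exact truth for
a panel evolved down a phylogeny:

* **Taxon sample.** The default tree (`clade_tree()`) is a star-like deep
  radiation of shallow clades with stems of varied depth — the regime of
  genome databases, which sample tight clusters of relatives hanging off
  an effectively unresolved deep backbone. A `sampling_bias` option
  replicates chosen tips into near-identical genome copies to exercise the
  distance weighting.
* **Gene content.** A root repertoire of planted modules plus background
  families evolves by loss (per-family rates); each module is lost as a
  single block, so its genes share one presence history — the signal the
  pipeline must recover. Regain of a lost family is disabled by default,
  keeping truth profiles unambiguous. Independently, lineages acquire de
  novo families at rate `pangenome_gain` per unit branch length (an open
  pangenome): this gives genomes realistic bulk (hundreds of genes) whose
  overlap across clades is small, which is exactly what lets `D` approach
  1 between distant genomes. Module genes are laid out contiguously
  (operon-like) on each genome's single replicon.
* **Hit fabrication.** For every family and organism pair carrying it, the
  generator draws reciprocal hits around a linear identity decay in the
  patristic distance (95% at distance zero to 30% at the tree diameter,
  floored at 25), with three variance components: a per-gene rate
  multiplier (coherent across organisms — the different-clock effect the
  adaptive threshold absorbs), a lineage effect per organism pair shared
  by all families (standard deviation 4 identity points at the diameter,
  scaled by relative distance, so near-identical strains agree), and a
  small incoherent residual (0.2 points). Coverage is drawn near 0.97 and
  converted to alignment lengths; low-identity single-direction decoy hits
  are sprinkled in and must be rejected by BBH mutuality.
* **Truth.** The family-by-organism presence matrix, module membership and
  the tree are returned alongside the panel.

What the generator does *not* emulate: sequence-level evolution, in-
paralogs and gene duplications, horizontal transfer of existing families
between lineages, partial-gene decay, or annotation noise. Passing the
validation experiments therefore shows that the statistical machinery
recovers block-loss co-evolution under realistic divergence and sampling
structure — not that the pipeline is robust to paralogy or assembly
artefacts.

## Validation experiments and problem sizes

The test suite runs two simulation experiments end to end, at sizes chosen
to exercise the method's mechanisms while staying comfortable on one CPU:

* **Module recovery.** 20 panels (seeds 1–20) of 30 tips (15 clades of
  2), three planted modules of 8, 6 and 5 genes with loss rates 0.8, 1.0
  and 1.2, 40 root background families, pangenome gain 1000. The pipeline
  (threshold 0.77, inflation 2) must recover the modules among the target
  organism's genes with adjusted Rand index at least 0.9 in at least 18 of
  the 20 seeds.
* **Sampling-bias stress.** Duplicating one clade's tips fivefold must not
  create module-background edges above the threshold: co-occurrence
  support confined to the duplicated clade is annihilated by `dmax^3`,
  because content-based distances inside the clade are near zero.

A note on the bias experiment: duplication also inflates `phi` slightly
for pairs that genuinely co-occur across many clades (it adds joint-
presence counts). A pair sitting within ~0.01 of the threshold can
therefore cross it under duplication through the `phi` channel, which the
distance weighting does not govern. This is a real sensitivity of
threshold-based profiling, distinct from the clade-confinement artefact
the `D^3` factor eliminates.

## Design decisions on open points

* Whether the score density should be evaluated per candidate or per
  histogram bin: per candidate, matching the smooth unimodal curves the
  selection rule is designed around. Within-organism paralogs never enter
  a candidate list (one BBH per organism at most).
* `N(A,B)` from raw BBH counts rather than selection-filtered counts, for
  the redundancy-recognition reason above.
* The target organism's own entry in every profile is 1: the gene exists
  there by construction.
* Negative-phi pairs are never edge candidates at the default threshold;
  the network builder also refuses negative edge weights, so MCL inputs
  are always non-negative.
* Cluster files order clusters by size then lexically, floats print at 6
  significant digits, and all sorts use C-locale collation, making every
  artifact byte-stable across runs and machines.

## Known limitations

* Phi on short profiles (tens of organisms) is coarse: one flipped
  organism moves it by ~0.05–0.1, so scores near the threshold are
  unstable by construction. The database-scale regime (thousands of
  genomes) does not have this granularity problem.
* The content-based distance conflates genome reduction with phylogenetic
  distance: a streamlined endosymbiont looks distant from everything,
  including its relatives.
* The windowed synteny criterion ignores strand and local rearrangement
  structure; it only feeds a 10% factor, but K = 1 verdicts from chance
  proximity in gene-dense regions are possible.
* MCL granularity is controlled by the inflation parameter, which the
  literature's default (2.0) fixes; no attempt is made to select it per
  network.
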