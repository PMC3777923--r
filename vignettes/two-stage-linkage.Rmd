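---
title: "Two-stage prediction of protein functional linkages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of protein functional linkages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pplink)
```

## The problem

Two proteins are *functionally linked* here if they participate in at least
one common metabolic or signalling pathway. pplink predicts such linkages
for a query organism by combining two independent sources of evidence:

1. **Co-evolution.** Genes whose products work together tend to be
   co-present and co-absent across genomes. A gene's *phylogenetic
   profile* records how strongly it is conserved in each organism of a
   reference collection, and similar profiles suggest a functional link.
2. **Sequence composition.** A classifier trained on pairs of known
   relatedness in a *training organism* can recognise compositional
   signatures of linked pairs from the sequences alone, and transfers to
   the query organism.

The two stages are serial: stage 1 is a permissive filter that discards
pairs with no co-evolution evidence, and stage 2 ranks the survivors.

## Stage 1: profiles, normalization, the non-zero filter

For query gene $a$ and reference organism $b$, the *S-value* $S_{ab}$ is
the best BLAST bit score of $a$ against all ORFs of $b$. Because
non-homologous sequences can reach bit scores up to about 50, S-values
below 50 are trimmed to zero. The *R-value* normalizes away the
sequence-dependence of the bit score,

$$R_{ab} = \min\!\left(\frac{S_{ab}}{S_{aa}},\, 1\right),$$

where $S_{aa}$ is the self-alignment score. The clamp at 1 is a package
decision: a cross-organism score exceeding the self-score is pathological,
and the clamp keeps the documented $[0,1]$ range (clamping is reported).
Within each reference organism, the non-zero R-values of all genes are then
divided by their mean, so no phylogenetically close organism can dominate
every similarity. The pair similarity is the plain inner product
$\sum_b R_{ib} R_{jb}$ of the two column-normalized profiles; no cosine
rescaling is applied.

A profile with very few non-zero entries makes the inner product rest on a
handful of organisms, which is statistically equivalent to using a tiny
reference collection. The *non-zero filter* therefore rejects a pair if
either profile has fewer than `nz` non-zero entries; such pairs receive no
prediction at all (their similarity is reported as `NA`, not 0). With the
defaults (`nz = 1`, similarity threshold 0, both taken from the study
design this package implements) only all-zero profiles and zero-similarity
pairs are removed. The similarity comparison is strict (`> threshold`), so
the default removes exactly the zero-similarity pairs.

Order of operations is fixed as trim → R-value → column normalization →
inner product.

## Stage 2: conjoint triads and the RVKDE

Each protein is encoded by collapsing its residues into seven
physicochemical groups (Ala/Gly/Val; Ile/Leu/Phe/Pro; Tyr/Met/Thr/Ser;
His/Asn/Gln/Trp; Arg/Lys; Asp/Glu; Cys) and counting every window of three
consecutive group symbols: a 343-dimensional occurrence vector of raw
counts ($7^3$ triad types; a length-$L$ sequence contributes $L-2$
counts). A pair is the 686-dimensional concatenation of the two vectors,
in lexicographic gene-id order so the encoding is orientation-free. Raw
counts (not frequencies) are the default because the occurrence vector is
defined as counts; a min–max scaling option exists for experimentation.
The triad index is the base-7 positional code — any consistent bijection
works, it only has to be shared between training and prediction.

The classifier is a relaxed variable kernel density estimator. For each
training pair $s_i$ of class $j$ (related/unrelated), the bandwidth

$$\sigma_i \;=\; \beta \, R(s_i)\,
  \frac{\Gamma(m/2+1)^{1/m}}{\sqrt{\pi}\,(\alpha\,k_s)^{1/m}}$$

scales with $R(s_i)$, the distance to the $k_s$-th nearest neighbour
*within the same class* (the two densities are separate per-class
estimates). The class-conditional density at a query $\mathbf v$ sums
Gaussian kernels over only the $k_t$ nearest class samples,

$$\hat f_j(\mathbf v) = \frac{1}{n_j} \sum_{i \in \mathrm{knn}_{k_t}(\mathbf v)}
  (2\pi)^{-m/2} \sigma_i^{-m}
  \exp\!\left(-\frac{\lVert \mathbf v - s_i \rVert^2}{2\sigma_i^2}\right),$$

and the pair is assigned to the class maximizing
$L_j(\mathbf v) = (n_j/n)\hat f_j(\mathbf v)$ — the empirical prior times
the density. The ranking score is $L_r/(L_r+L_u)$, with ties and the
no-evidence case ($L_r = L_u = 0$) resolved to *unrelated*: false
positives are what a precision-oriented evaluation punishes.

### Numerical choices

* **Log-space evaluation.** At $m = 686$ the kernel constant
  $(2\pi)^{-m/2}\sigma^{-m}$ underflows double precision by hundreds of
  orders of magnitude. All densities and likelihood comparisons are
  computed with log-sum-exp; `class_density()` exposes the linear value
  for low-dimensional use.
* **Bandwidth floor.** Duplicate training vectors (triad-count vectors do
  collide) give $R(s_i)=0$; $\sigma_i$ is floored at $10^{-9}$ times the
  class's median pairwise distance (1 if degenerate).
* **Neighbour search.** Radii and $k_t$-neighbourhoods use exact blocked
  matrix algebra (a crossprod expansion). At the package's problem sizes
  (up to a few thousand training pairs) this is faster in R than tree
  structures would be; tree-based search is an optimization for much
  larger $n$, not a semantic change.
* **kt-truncation.** Truncation is within-class and one-sided (a truncated
  density never exceeds the full sum); with $k_t \ge n_j$ the estimator is
  a proper density integrating to 1.

### Parameters, and the default for pair features

$\alpha, \beta, k_s, k_t$ are set by stratified 5-fold cross-validation
maximizing the F-measure over a grid (`grid_search_cv()`, deterministic
given a seed; ties prefer smaller $(k_s, k_t, \beta, \alpha)$). The
default grid is $\alpha \in \{0.5,1,2\}$, $\beta \in \{0.5,1,2,4\}$,
$k_s \in \{5,10,20\}$, $k_t \in \{20,50,100\}$, which suits
low-dimensional features.

High-dimensional features need a different $\beta$ scale, and it is worth
seeing why. The ball-volume constant $\Gamma(m/2+1)^{1/m}/\sqrt{\pi}$
grows like $\sqrt{m/(2\pi e)}$ — about $6.4$ at $m=686$ — while
$(\alpha k_s)^{1/m} \approx 1$, so with $\beta = 1$ every bandwidth is
$\approx 6.4\,R(s_i)$: kernels far wider than the inter-point spacing. In
that regime $\hat f_j$ is governed by the $m \log \sigma_i$ term alone and
the class with the smaller bandwidths (the denser, larger class) wins
everywhere, regardless of where the query lies. $\alpha$ and $k_s$ cannot
repair this (exponent $1/m$); $\beta$ is the only effective knob, exactly
why the original procedure tunes it by cross-validation.
`pair_rvkde_params()` therefore sets $\beta = 0.01$ for 686-dimensional
triad counts, putting kernel widths at a fraction of the $k_s$-NN radius;
the choice follows this geometric argument and was confirmed with the
method's own cross-validation procedure on a synthetic training organism.
Whole-pipeline helpers default to it; `rvkde_params()` keeps the generic
defaults.

The same observation applies in the other direction for density
estimation: because of the $(\alpha k_s)^{1/m}$ divisor, $\sigma_i$ is
roughly $\beta$ times the *per-point* spacing (not the $k_s$-neighbourhood
radius), so recovering a smooth 1-D density at $n = 2000$ needs $\beta$ of
order tens — $\beta$ always carries the absolute smoothing scale, whatever
the dimension.

Euclidean distance on raw counts is length-sensitive (two same-pathway
proteins of very different lengths are far apart); this matches the
raw-count encoding decision and is mitigated by the adaptive bandwidths.

## Data filters and pair labels

A gene enters the analysis if its nucleotide sequence is strictly longer
than 150 nt ("longer than" is read as a strict inequality and pinned by a
test), its protein sequence uses only the 20 proteinogenic residues, and
it belongs to at least one pathway. When the nucleotide length is unknown,
$3(L_{aa}+1)$ — coding length plus stop codon — is substituted and the
substitution is reported. All $\binom{G}{2}$ pairs are enumerated; a pair
is positive iff the pathway sets intersect. Pairs are everywhere kept in
lexicographic (C-locale) gene-id order, and rankings break score ties by
pair id, so every run is reproducible.

## Evaluation protocol

`run_pred_both()` ranks stage-1 survivors by RVKDE score;
`run_pred_first()` ranks the same survivors by profile similarity;
`run_pred_second()` draws random samples from the nz-passing pairs with
the positive/negative counts matched to the stage-1 survivors, ranks each
sample by RVKDE score, and averages the precision-at-k curves pointwise
over repeats (default 10) — sampling bias is what the repetition
alleviates, and pointwise averaging is the package's interpretation of
"repeated".

`precision_at_k()` is the fraction of true pairs in the top $k$.
`auc_at_recall()` integrates the recall–precision curve from recall 0 to a
target $r$: the curve is sampled at every rank where a positive is
retrieved, anchored at recall 0 with the first precision value, integrated
with the trapezoid rule, and linearly interpolated to end exactly at $r$
(a perfect ranking gives exactly $r$; the scheme is validated against a
brute-force oracle in the tests). `adjusted_auc()` divides by $r$, the
perfect predictor's AUC. The recall denominator defaults to the positives
present in the ranking; pass the study-wide positive count when the
ranking covers only the filtered subset.

## The synthetic generator

`generate_bundle()` produces a complete, seeded study: a query organism
and a training organism that share pathway-level structure (clades over
the reference collection, per-pathway residue-group distributions) but
have independent gene-level draws, so cross-organism training is mirrored
without leaking identical sequences.

* **Presence.** Each pathway's clade includes each of the 40 reference
  organisms with probability 0.35; each gene inherits its pathway's row
  with per-cell flips (baseline rate 0.08).
* **Scores.** Self scores are uniform in (200, 600); a present cell draws
  $S_{ab}/S_{aa}$ from Beta(5, 2) rescaled onto $(50/S_{aa}, 1]$, so every
  present cell survives the trim; an absent cell is 0, or with probability
  0.05 a spurious score in (0, 50) that the trim removes.
* **Sequences.** Each pathway has a Dirichlet-drawn distribution over the
  seven groups (concentration around 0.5, i.e. spiky); residues are drawn
  group-first, then uniformly within the group; lengths are uniform in
  80–300 residues.
* **Coherence.** A per-pathway factor $c_p \sim \mathrm{Beta}(2,2)$
  scales the flip rate by $2(1-c_p)$ and sharpens the group distribution
  for coherent pathways. This encodes that strongly conserved functional
  modules are conserved in both their presence pattern and their
  composition — the agreement between the two evidence channels that a
  two-stage design exploits. Without it the two signals would be
  independent given the pathway, and filtering by one could not improve
  the ranking by the other.
* **Disjoint-clade mode.** `disjoint_clades = TRUE` partitions the
  organisms round-robin among pathways. With noise and spurious scores
  off, cross-pathway similarities are then exactly 0 and stage 1 is
  provably perfect — the regime used by the calibration checks. Random
  clades (the default) overlap, which is the realistic regime.

These defaults are the package's standing study conditions; the
acceptance workflow runs 10 replicate bundles of the default size (96
genes per organism, 4,560 pairs of which 528 are positive, 40 reference
organisms) — sizes chosen so a full replicate, including fitting the
RVKDE on all 4,560 training pairs, completes in seconds.

What the generator does *not* emulate: overlapping pathway membership
(synthetic pathways are disjoint, so the positive-pair fraction is exactly
$\sum_p \binom{g_p}{2} / \binom{G}{2}$), sequence homology and alignment
(scores are drawn, not computed from the sequences, so profile strength
and sequence similarity are coupled only through the pathway), genome-scale
class imbalance, and phylogenetic correlation among reference organisms.
Passing tests on these bundles show the machinery is correct and that the
two-stage logic composes as designed — not that the method attains any
particular accuracy on real genomes.

## Known limitations

* The package parses BLAST tabular output; it never runs BLAST, and
  binary/quantized profile variants and alternative distance functions are
  out of scope.
* Column normalization is computed over the genes present in the matrix
  (post-filter); normalizing over a larger unfiltered gene universe would
  change similarities slightly.
* Whether the 150-nt filter applies before or after ORF trimming is not
  derivable from the data contract; the filter is applied to the
  `nt_length` the caller supplies (or the protein-length proxy).
* The score saturates at 0/1 when one log-likelihood dominates by more
  than ~35 nats; within a saturated block the ranking falls back to the
  deterministic pair-id order.
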