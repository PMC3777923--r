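# pplink

Two-stage prediction of protein functional linkages: phylogenetic
profiling with a reliability filter, followed by an adaptive-bandwidth
kernel density classifier over conjoint-triad sequence features.

## The problem

Proteins that act in the same pathway tend to be gained and lost together
across genomes. pplink scores candidate protein pairs of a query organism
in two serial stages:

1. **Phylogenetic profiling (stage 1).** Each gene's profile is the
   vector of R-values across a reference collection of organisms:
   R<sub>ab</sub> = S<sub>ab</sub>/S<sub>aa</sub>, where S<sub>ab</sub> is
   the best BLAST bit score of gene *a* against all ORFs of organism *b*
   (trimmed to 0 below 50) and S<sub>aa</sub> the self-alignment score.
   Profiles are column-normalized so each organism's non-zero R-values
   average 1; pair similarity is their inner product. A **non-zero
   filter** rejects pairs where either profile has fewer than `nz`
   non-zero entries — similarities resting on a handful of organisms are
   unreliable, and such pairs get *no* prediction rather than a low score.
2. **RVKDE classification (stage 2).** Each protein is encoded by
   counting triads of 7 physicochemical residue groups (343 counts; 686
   per pair), and a relaxed variable kernel density estimator — Gaussian
   kernels whose per-sample bandwidth scales with the distance to the
   ks-th nearest same-class neighbour, evaluated over the kt nearest
   samples — is trained on the labeled pairs of a training organism.
   Survivors of stage 1 are ranked by L<sub>rel</sub>/(L<sub>rel</sub> +
   L<sub>unrel</sub>), with L<sub>j</sub> = (n<sub>j</sub>/n)·f̂<sub>j</sub>(v).

Evaluation follows the ranked-retrieval protocol: precision among the top
k predictions, AUC in the recall–precision plane up to a target recall,
and the adjusted AUC (ratio to a perfect predictor). A seeded synthetic
generator (`generate_bundle()`) produces complete miniature studies —
clade-structured hit tables, group-biased sequences, pathway memberships —
so the whole pipeline runs with no external databases.

## Worked example

```r
library(pplink)

bundle <- generate_bundle(synth_config(seed = 1001))   # 96 genes/organism
model  <- train_linkage_model(bundle)                  # RVKDE on 4,560 pairs

both   <- run_pred_both(bundle, model = model)         # two-stage ranking
first  <- run_pred_first(bundle)                       # profile similarity only
second <- run_pred_second(bundle, seed = 1001, model = model)

precision_at_k(both, 100)    # 1
precision_at_k(first, 100)   # 1
precision_at_k(second, 100)  # 1

head(both, 3)
#>   gene_a gene_b score related
#> 1  Q0001  Q0002     1    TRUE
#> 3  Q0001  Q0004     1    TRUE
#> 4  Q0001  Q0005     1    TRUE

nrow(both)                                     # 4559 stage-1 survivors
auc_at_recall(both, 0.05)                      # 0.05
adjusted_auc(auc_at_recall(both, 0.05), 0.05)  # 1 = perfect up to that recall
```

On this bundle all three protocols are near-perfect at the top of the
ranking; their differences appear under heavier presence noise and deeper
in the ranking (the test suite measures the pattern over 10 replicate
bundles). Each row of a ranking is one candidate pair with its score and
its true label; `run_pred_second()` instead returns a precision-at-k curve
averaged over matched random samples.

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "pplink.R", package = "pplink"))')" \
  synth --out /tmp/bundle --seed 42
```

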