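# coremod — cross-tissue core expression module discovery

`coremod` finds compact gene-expression modules that discriminate treated
from control samples *consistently across tissues*. It was built for
multi-tissue, multi-timepoint two-class designs such as the mouse
social-defeat (stress/PTSD) paradigm — blood plus several brain regions,
sampled over exposure/recovery conditions — where the questions are (1)
which pathway-level responses are shared between tissues and (2) whether
modules inferred in an accessible tissue (blood) validate as classifiers
in the tissues of interest (brain). The intended users are computational
biologists analyzing such designs and methodologists studying
cross-cohort biomarker validation.

## The method

1. **Time deconvolution.** Per gene and tissue, log2 expression is fit by
   least squares to
   `y = alpha_defeat * 1[defeat] + beta_j(sample) + e`, one row per
   replicate across the four exposure/recovery conditions; subtracting
   the fitted per-condition effects `beta_j` leaves the
   "time-standardized" matrix in which only the treatment effect `alpha`
   separates the classes.
2. **Candidate modules (CORG).** For each pathway, member genes are
   ranked by moderated t; a prefix grows while the pooled t of the mean
   z-scored activity `y_k = (x1 + ... + xk)/k` strictly improves, up to
   25 genes; both directions are tried and candidates are ranked by
   |activity t|, keeping the top 100.
3. **Validation (consensus feature elimination).** Candidate activities
   are regenerated in each validation tissue. Ensembles of 250 groups x
   500 ridge-LDA classifiers — trained on resampled inference-tissue
   samples, scored on resampled validation-tissue samples — rank features
   by mean normalized |weight|; each group votes for its worst feature,
   the top-voted feature is removed, and elimination stops when the
   ensemble mean AUC reaches 0.75 (an exhausted run returns the empty
   set).
4. **Core modules and network.** Modules surviving in at least half of
   the validation tissues are core; they are projected onto a PPI
   network with edges labeled `within_module` / `between_module`.

Supporting layers: moderated t-tests (empirical-Bayes variance
shrinkage), iGA rank enrichment of GO terms and best sub-pathways
(sizes 3–10) with selection-respecting permutation nulls and BH FDR,
pairwise hypergeometric overlap tests, microarray-style preprocessing
(missing-probe filter, KNN imputation, per-tissue quantile
normalization, sibling-probe aggregation), and a fully seeded synthetic
study generator with planted modules and ground truth.

## Worked example

```r
library(coremod)

cfg <- simulation_config(seed = 42)   # 2 tissues, 1000 genes, 5 planted
sim <- generate_study(cfg)            #   10-gene modules, delta = 1,
ann <- generate_annotations(cfg)      #   sigma = 0.5, 10 mice/class/cond
res <- run_pipeline(sim$studies, ann$pathways, ann$ppi,
                    top_k = 20, n_groups = 25, group_size = 50, seed = 42)

head(candidate_table(res$candidates), 5)
#>             pathway                                   genes n_genes direction    abs_t rank
#> 1 pathway_planted01 g0153,g0561,g0074,g0146,g0634,...      10        up 32.49243    1
#> 2 pathway_planted03 g0930,g0621,g0283,g0879,g0932,...      10        up 30.02748    2
#> 3 pathway_planted05 g0348,g0197,g0406,g0292,g0967,...       8        up 26.90512    3
#> 4 pathway_planted04 g0872,g0298,g0314,g0299,g0911,g0989     6      down 25.49417    4
#> 5 pathway_planted02 g0882,g0303,g0165,g0410,g0356,...      10        up 23.80633    5

res$summary
#>   inference validation n_final_modules n_final_genes mean_auc mean_error
#> 1     Blood         HB              20           109        1          0

res$network
#> CoreModuleNetwork: 20 core module(s), 109 gene(s), 97 edge(s) ( 95 within / 2 between )
```

All five planted modules rank first among the candidates (the greedy
aggregation recovers 6–10 of each module's 10 genes), every candidate
transfers to the second tissue (the planted effects are active in both,
so the validation AUC saturates at 1.0 and nothing is eliminated), and
the projected network's edges are overwhelmingly within-module — the
generator wires planted modules at 50% PPI density against a 1%
background.

The same pipeline is available from the shell:

```sh
inst/scripts/coremod simulate --out-dir data --seed 42
inst/scripts/coremod run-all --data-dir data --out-dir out --seed 42
```

Subcommands `preprocess`, `deconvolve`, `diffexpr`, `overlap`, `enrich`,
`infer`, `validate`, `core` and `network` expose the individual stages;
every subcommand is byte-reproducible for a fixed `--seed`.

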