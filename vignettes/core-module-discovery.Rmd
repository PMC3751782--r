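---
title: "Cross-tissue core expression module discovery with coremod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue core expression module discovery with coremod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremod)
```

## The problem

Expression studies of stress models (for instance the mouse social-defeat
paradigm, a widely used animal model for post-traumatic stress) often span
several tissues — blood plus multiple brain regions — and several
exposure/recovery conditions. Two questions recur: which biological
processes respond to the treatment *in common* across tissues, and can a
compact, robust set of modules inferred in an accessible tissue (blood) be
validated as discriminative in the tissues of interest (brain)? `coremod`
implements a complete pipeline for this: time-effect deconvolution,
pathway-activity module inference, cross-tissue validation by consensus
feature elimination, core-module aggregation, and projection onto a
protein–protein interaction (PPI) network, together with the supporting
differential-expression and enrichment machinery.

## The model and the pipeline

### Time-effect deconvolution

Samples come from four exposure/recovery conditions collected at different
animal ages, so condition effects confound the treatment effect. Assuming
log-additive effects, each gene's log2 expression is modeled as

$$ y \;=\; \alpha_{\mathrm{defeat}}\cdot
   \mathbf{1}[\text{class}=\text{defeat}] \;+\; \beta_{j(\text{sample})}
   \;+\; \varepsilon, $$

one design row per replicate: a defeated sample in condition $j$
contributes $(1, e_j)$, a control sample $(0, e_j)$. The over-determined
system is solved per gene by ordinary least squares (`fit_time_model()`),
per tissue, matching the per-tissue normalization of the inputs. There is
no separate intercept, so each $\beta_j$ absorbs the gene's baseline
together with the condition (age/recovery) effect; subtracting
$\hat\beta_{j}$ from every sample (`adjust_expression()`) leaves the
*time-standardized* matrix in which control samples have expectation 0 and
defeated samples expectation $\hat\alpha$. All downstream classification
uses this matrix. When a condition lacks one class the design can lose
identifiability; the fit then falls back to minimum-norm least squares and
warns. `average_time_curve()` summarizes each gene's per-condition
response as the difference of class means of log2 expression (the log2
ratio of geometric means), the quantity drawn in module heat maps.

### Differential expression and enrichment

`moderated_t_test()` implements the empirical-Bayes moderated t: per-gene
pooled variances $s^2$ (d degrees of freedom) are shrunk toward a prior
$(d_0, s_0^2)$ estimated by matching the first two moments of $\log s^2$
to a scaled-F model, and the moderated statistic is referred to a t
distribution on $d + d_0$ degrees of freedom. The moment matching uses a
Newton inversion of the trigamma function; when the observed spread of
$\log s^2$ does not exceed its sampling noise, $d_0 = \infty$ and every
gene receives the common variance. The implementation is independent of
limma, which the test suite uses as an oracle (agreement to ~1e-15 on
seeded fixtures).

Gene-set enrichment uses iterative Group Analysis (iGA): with a term's
member ranks $r_1 < \dots < r_n$ in the significance-ordered gene list,
$PC(j) = P(X \ge j)$ for $X \sim \mathrm{Hypergeom}(N, n, r_j)$, minimized
over $j$. The minimum over data-chosen cutoffs is not a p-value, so
significance comes from a permutation null of the gene order. For
sub-pathway analysis the $s$ most significant members are scored for
$s = 3..10$ and the best size kept; the permutation null re-applies the
same best-over-sizes selection so that the selection step is accounted
for. Permutation p-values use the add-one convention
$p = (1+b)/(1+B)$, with resolution floor $1/(B+1)$; under the null a
term's member positions are a uniform random rank subset, which is how
the null is drawn. Benjamini–Hochberg FDR (`bh_fdr()`) and pairwise
hypergeometric overlap tests between tissues (`overlap_test()`,
equivalent to one-sided Fisher) complete the layer.

### Candidate modules: greedy CORG aggregation

For each pathway, member genes are ranked by moderated t — descending for
an up-regulated candidate, ascending for down — and a prefix is grown one
gene at a time. The activity of a $k$-gene prefix is the arithmetic mean
of the members' z-scored expressions, $y_k = (x_1 + \dots + x_k)/k$, and
gene $k+1$ is kept only when $|t(y_{k+1})|$ *strictly* exceeds
$|t(y_k)|$; ties stop growth, as does the 25-gene cap. Both directions
are grown and the better final $|t|$ wins; this deterministic rule
subsumes any "dominant direction" heuristic. Candidates from all pathways
(filtered to 3–200 members present, removing bulky pathways) are
deduplicated by member set and the top 100 by $|t|$ retained.

Two numerical choices deserve note. First, the divisor is $k$, not the
$\sqrt{k}$ of the original condition-responsive-genes formulation;
`sqrt_k` scaling changes only the magnitude of the activity, not the
membership, but the arithmetic mean is what the pipeline defines.
Second, the t-statistic *inside* the greedy loop is the plain pooled t of
the activity vector, not the moderated t. The empirical-Bayes prior is
calibrated to single-gene variances; a $k$-gene average has variance
roughly $\sigma^2/k$, so moderating its t with the gene-level prior pins
the denominator at the single-gene prior variance and erases exactly the
variance reduction that justifies aggregation — in practice growth then
freezes at one or two genes. Gene *ordering* still uses the moderated t;
an `activity_prior` argument restores the moderated variant for
comparison.

### Validation: consensus feature elimination

Candidate modules are validated per tissue pair. Every candidate's
activity is regenerated in the validation tissue from its fixed member
set, giving a samples × modules feature matrix. An ensemble of 250 groups
× 500 ridge-regularized LDA classifiers
($w = (\Sigma_{\mathrm{pooled}} + \lambda I)^{-1}(\mu_1 - \mu_0)$) is
evaluated; each classifier contributes its test AUC (Mann–Whitney), test
error at the midpoint threshold, and its normalized absolute weight
vector $|w|/\|w\|_2$. Each group ranks features by mean normalized
weight and votes for its bottom feature; the feature with the most votes
(ties: worse mean rank, then lexicographic) is removed, and the loop
stops at the first crossing of the mean-AUC threshold 0.75 (or returns
an empty set after exhaustion). Feature count decreases by exactly one
per round, and the whole trace is reproducible from the seed.

Where the classifiers train and test matters more than any other design
choice here. Training and testing *within* the validation tissue makes
the weight consensus adaptively retain whatever features accidentally
separate that tissue's few samples; on pure-noise data the ensemble AUC
then drifts past 0.75 and dozens of "modules" survive — the procedure
loses its null. `coremod` therefore trains each classifier on a
stratified random two-thirds subsample of the *inference* tissue and
scores it on an independent stratified subsample of the *validation*
tissue: a module survives only if the discrimination learned in the
inference tissue genuinely transfers. Under label permutation the
transfer AUC sits at 0.5 and elimination runs to exhaustion, returning
the empty set — the behavior a validation procedure must have. The
standalone `eliminate_features()` keeps within-matrix train/test splits
when no test cohort is supplied.

The default ridge is $0.1\,\mathrm{tr}(\Sigma)/p$ — 10% of the average
within-class feature variance, a conventional shrinkage magnitude for
regularized discriminant analysis. A much smaller ridge merely makes the
covariance invertible; near $p \approx n$ it leaves the weight vector
dominated by noise directions of the ill-conditioned covariance matrix,
which visibly degrades both held-out AUC and the weight-consensus
ranking the elimination depends on.

The reported "mean AUC / mean error of both tissues" is the average of
the validation-evaluated ensemble (which also drives the stopping rule)
and an inference-tissue ensemble evaluated on the final feature set.

### Core modules and the PPI network

A validated module — identified by pathway name plus exact member set —
is *core* when it survives in at least half of the validation tissues
(ceiling rule: 4 of 7 qualifies, 3 of 7 does not). Core modules are
projected onto the PPI network as the induced subgraph on their gene
union; an edge is `within_module` when its endpoints share at least one
module, `between_module` otherwise, and nodes carry the gene's
$\hat\alpha$ from the inference tissue as the expression annotation.

## The synthetic study generator

`simulation_config()` / `generate_study()` emit multi-tissue studies from
exactly the generative form the time model assumes:
baseline $+\ \beta_{g,j}$ $+\ \mathbf{1}[\text{defeat}]\,\alpha_g$
$+\ N(0, \sigma^2)$, with $\alpha_g = \Delta \cdot \text{direction}$ for
members of planted modules active in that tissue and 0 otherwise. The
default configuration is the package's standard test fixture: 2 tissues ×
4 conditions × 10 mice per class per condition, 1000 genes, five planted
10-gene modules (alternating direction) with $\Delta = 1$ log2 unit and
noise $\sigma = 0.5$ — per-gene effects comparable to a clear microarray
hit, and roughly 6-SD separation at the 10-gene activity level.
Condition effects are drawn $N(0, 0.5^2)$ per gene and condition,
comparable in size to the treatment effect (age effects in recovery-time
designs are of the same order as treatment effects, which is what makes
deconvolution necessary at all); baselines are $N(8, 1.5^2)$ to mimic
log2 intensities and are purely cosmetic. Because the time model has no
intercept, the recorded ground truth exposes `expected_beta = baseline +
beta_time`, which is what a correct fit returns. Annotations embed each
planted module in a larger pathway (sizes 10–30) among decoy pathways,
planted-module GO terms among null terms (sizes 5–50), and a PPI graph
with 0.5 within-module versus 0.01 background edge density.

What the generator does *not* emulate: probe-level/two-color structure,
correlated background co-expression, heavy-tailed noise, batch effects
beyond the modeled condition effects, or realistic pathway overlap.
Passing recovery tests therefore demonstrate correctness of the
machinery under its stated model, not performance on real microarray
data.

## Problem sizes and numerical conventions

The test and acceptance runs use scaled-down settings chosen as the
package's standard desk-scale configuration: ensembles of 25 groups × 50
classifiers (the consensus is already stable there on the fixture;
larger ensembles change little), 200 permutations for enrichment nulls
(resolution floor 1/201), 20-seed replication for recovery rates, and
top-20 candidate lists over 40 generated pathways. Full-scale defaults
(250 × 500, 1000 permutations, top-100) remain the function defaults.

Conventions: "more than half missing" is strict (a probe missing exactly
half its values survives); KNN imputation uses the plain mean of k = 10
nearest probes by Euclidean distance over co-observed samples;
quantile normalization averages tied values over the corresponding
reference quantiles and is applied per tissue; DEG calling is
threshold-inclusive (p ≤ 0.05); ranking ties break by |t| then gene id;
greedy growth requires strict improvement; elimination votes break ties
by worse mean rank then lexicographic id. All stochastic steps consume a
single user-provided seed, and every CLI subcommand is byte-reproducible
for a fixed seed.

## Known limitations

- The greedy prefix rule stops at the first non-improvement; with few
  samples the selection-inflated gap of early genes makes late additions
  dilutive, so modules rarely reach the 25-gene cap unless signal is
  strong and samples many. This mirrors the method's definition, not a
  defect.
- With small validation cohorts the stopping threshold is still a random
  variable; the cross-cohort scheme removes the adaptive-selection bias
  but cannot remove finite-sample AUC noise.
- Eq.-style deconvolution assumes additive, class-independent condition
  effects; interaction effects (condition-specific treatment response)
  are averaged into $\alpha$.
- Module identity across tissues is exact member-set equality; near-equal
  modules from correlated pathways are counted separately.
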