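---
title: "Cross-tissue co-expression module signatures: methods and design"
author: "CoExSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue co-expression module signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoExSig)
```

## The problem

Neurodegenerative diseases such as Huntington's disease (HD) unfold in
brain tissue that cannot be sampled in living patients, while blood is
easily accessible. Transcriptome changes in the two tissues rarely
involve the *same* genes, but they may involve the same biological
*functions*, executed by different gene products. CoExSig implements a
pipeline that searches for such shared functional disease signatures:
it groups genes into co-expression modules per tissue, annotates each
module with function and disease concepts mined from a document corpus,
scores every blood-brain module pair by how many annotations they
share, and asks whether that sharing exceeds what randomly composed
modules of the same sizes would achieve.

## Module detection

Per tissue, modules come from a weighted correlation network analysis:

1. **Correlation.** Pearson correlation $r_{ij}$ between all gene pairs
   across samples. Zero-variance genes are dropped on ingestion.
2. **Soft-threshold adjacency.** Unsigned by default,
   $a_{ij} = |r_{ij}|^\beta$ (a signed variant
   $((1+r_{ij})/2)^\beta$ is available behind a flag). The power
   $\beta$ is a user input, chosen under the scale-free-topology
   assumption; `scaleFreeFit()` reports the signed $R^2$ of the
   log-log degree fit to validate a choice but never auto-selects.
3. **Topological overlap.** $\mathrm{TOM}_{ij} =
   (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
   which credits shared network neighbourhoods, not just direct edges.
4. **Branch cut.** Average-linkage clustering on $1-\mathrm{TOM}$;
   connected branches below `cutHeight` with at least `minModuleSize`
   genes become modules. With `deepSplit` $\ge 1$ a branch is split
   recursively when the drop from its merge height $h$ to its taller
   sub-branch exceeds $(0.25/\mathrm{deepSplit})\,h$ and both halves
   meet `minModuleSize`; larger `deepSplit` therefore never yields
   fewer modules.
5. **Leftover adoption.** A gene outside every module joins the module
   with the highest mean TOM to its members only if that mean exceeds
   both the gene's mean TOM to all non-members *and* a cohesion floor
   of $1-{}$`cutHeight`. The floor is this package's design choice: the
   member/non-member comparison alone is scale-free, so a pure-noise
   gene would be adopted by whichever module it is accidentally closest
   to, and planted-module benchmarks then cannot distinguish signal
   from adoption noise. With the floor, unassigned background stays
   unassigned (the `unassigned` pool) unless it is genuinely connected.
6. **Eigengene merging.** The module eigengene is the first principal
   component of the per-gene z-scored module submatrix across samples,
   unit norm, with its sign fixed so the correlation with the module's
   mean expression profile is non-negative (PCA sign is otherwise
   arbitrary and would break reproducibility). Modules whose eigengene
   dissimilarity $1-\mathrm{cor}$ falls below `MEDissThres` are merged
   iteratively, closest pair first, recomputing after every merge; the
   procedure is idempotent.

Module-trait association is the Pearson correlation of each eigengene
with each trait, with two-sided p-values from the exact t distribution
on $n-2$ degrees of freedom. A module counts as disease-associated when
any trait cell has $p < 0.05$; no multiplicity adjustment is applied at
this stage, mirroring the per-cell reading of module-trait heatmaps. A
constant trait yields an undefined correlation, reported as $r =$ NA
and $p = 1$ with a warning.

`networkParams()` ships presets for the reference HD blood and four brain
region networks (soft powers 9/9/3/5/5, `minModuleSize` 15, `deepSplit`
0 for blood and 2 for brain, `cutHeight` 0.995/0.999, `MEDissThres`
0.30 for blood and 0.0001 — effectively no merging — for brain).

## Concept profiles and module annotation

The corpus is a set of documents, each a bag of concept identifiers
(gene concepts plus annotation concepts in four semantic categories:
biological process, cellular component, molecular function, disease or
syndrome). For every concept occurring in at least `minDocs` (default
5) documents, a *concept profile* is built: the vector of symmetric
uncertainty coefficients

$$U(X,Y) = \frac{2\,I(X;Y)}{H(X)+H(Y)} \in [0,1]$$

between the owner's document-occurrence indicator and that of every
concept it co-occurs with at least once (owner excluded, zero weights
dropped). Entropies are computed in bits; the base cancels in the
ratio. $0\log 0 := 0$, and $U := 0$ when $H(X)+H(Y)=0$. Only direct
co-occurrence enters a profile; *indirect* relations surface when two
profiles are matched by their inner product over shared concepts.

A module is annotated against a concept set by scoring every
annotation concept with the sum of gene-profile/annotation-profile
inner products over the module's genes (genes without a profile
contribute zero and are logged), and keeping the top `K = 20` per
category. Ties are broken by concept id ascending — the original
procedure is silent on ties, but the permutation null requires a
deterministic rule. Zero-score annotations are dropped unless
`keepZeroScores` is set; with a rich corpus there are always at least
`K` positive candidates, so the flag only matters for degenerate
corpora.

## Pair scoring and significance

For $n$ blood modules $A_i$ and $m$ brain modules $B_j$, the observed
score $S_{ij}$ is the number of overlapping annotations in the two
top-20 lists (per category; scores are ignored, only membership
counts). A gene-overlap baseline scores pairs by shared mapped gene
identifiers and runs through exactly the same permutation machinery.

The null distribution: for $k = 1,\dots,K_A$ and $l = 1,\dots,K_B$
(default 100 each), random module sets are drawn by permuting the
tissue's full gene universe (assigned plus unassigned genes — the more
conservative choice) and slicing consecutive blocks of the original
module sizes, so random modules are disjoint and replicate the
partition structure exactly. Every random module is annotated exactly
like a real one, and $S_{ijkl}$ is computed for all pairs and all
$(k,l)$ — $K_A \times K_B = 10{,}000$ null scores per pair at the
defaults. The same random sets serve every semantic category and the
gene-overlap baseline.

Raw p-values use the conservative counting rule
$p_{ij} = (1 + \#\{(k,l): S_{ijkl} \ge S_{ij}\})/(1+R)$ with
$R = K_A K_B$: ties count as extreme, zero p-values are impossible, and
reaching $p < 1/R$ requires the observed score to beat every
permutation. Familywise error across the $n \times m$ comparisons is
controlled by Westfall-Young step-down minP: the same $p(\cdot)$
function is applied to each null score within its pair's null row
(so a single pair's adjusted p equals its raw p exactly); hypotheses
are ordered by raw p, the $h$-th adjusted p is the (+1-smoothed)
fraction of replicates whose minimum per-replicate p over hypotheses
$h,\dots,H$ falls at or below the raw p, and a running maximum enforces
monotonicity. The implementation is checked against an independent
brute-force enumeration in the test suite.

Because overlap scores are small integers, heavy ties make minP
conservative; the strict significance level is therefore set at 10 %,
with a "gray zone" up to 50 % flagged as marginal. A **strict
signature** is a pair with adjusted $p \le 0.10$ whose two modules are
each trait-associated; a **marginal signature** satisfies the same
trait condition with adjusted $p \in (0.10, 0.50]$. Each analysis is
fully per-category: thresholds, nulls and signature calls never pool
across the four categories, so the familywise guarantee is also
per-category (the union of four 10 % families is not itself a 10 %
family).

## The synthetic generator

Real studies at the scale of the reference HD blood (NGS, ~100 samples)
and brain (microarray, ~80 samples) datasets cannot be shipped or
downloaded at desk scale, so validation rests on a generator with
known ground truth.

**Expression.** Each planted module has one latent factor per sample —
the factor plays the role the eigengene plays in detection, which makes
recovery well-defined. Traits are HD-flavoured: balanced binary carrier
status, CAG repeat 40-53 in carriers and 17-28 in controls, motor score
increasing with CAG, TFC decreasing with motor score. Factors are
constructed so the *empirical* factor-trait correlations equal the
configured targets exactly (the residual component is orthogonalized
against the targeted traits and the combination rescaled); only the
eigengene-vs-factor gap and detection noise separate measured
module-trait correlations from their targets. Targets of magnitude 1
with nonzero gene noise, and jointly infeasible target combinations
($\rho^\top R^{-1}\rho > 1$), are rejected. Module genes are
`factor + N(0, noiseSd)` with unit loadings; background genes are pure
noise.

**Corpus.** Documents draw every concept independently at a base rate
(default 0.02). For every planted function, a small set of theme
documents additionally mentions the function's member genes and its
annotation concepts with probability 0.3; the number of theme
documents is sized so each planted gene-annotation pair co-occurs at
`enrichment` times the background rate. Theme documents also couple
the function's concepts to each other, which is what lets the
inner-product matching (which only sees *shared* profile support) pick
the signal up — exactly the indirect-relation mechanism the profile
matching is designed around. Every concept is topped up to the
`docsPerConcept` floor (default 5) so it earns a profile. Modules in
different tissues sharing a `functionId` get the same annotation
concepts but disjoint, tissue-prefixed gene concepts: the shared
biology is functional, never gene-identity.

**What the generator does not emulate:** count distributions of NGS
data, microarray probe effects, normalization artefacts, correlated
background genes, hub-gene topology inside modules, realistic
literature (citation skew, polysemy, category imbalance). Passing
tests therefore demonstrate the statistical machinery — recovery,
calibration, error control — under a clean factor model, not
performance on any real dataset.

## Standard study conditions

Two scenarios are fixed once and used everywhere (tests and the
acceptance script):

* `strongScenario()`: 3 modules per tissue (20/15/15 genes; trait
  effects carrier 0.6, CAG 0.5, motor 0.4), the first two module pairs
  linked across tissues by shared functions, 30 background genes, 60
  samples, noise sd 0.5; 3000-document corpus, enrichment 5, 10
  function concepts per category, 80 background concepts per category.
* `globalNullScenario()`: 2 private-function modules per tissue,
  enrichment 1 (no planted literature signal), 40 samples, 800
  documents — the matching no-signal condition.

Network parameters for synthetic data are soft power 6,
`minModuleSize` 15, `deepSplit` 2, `cutHeight` 0.97, `MEDissThres`
0.15; the reference per-network presets target real-data TOM scales,
while 0.97 sits between the synthetic within-module and between-module
dissimilarity bands. Validation problem sizes: familywise error is
estimated over 200 global-null pipelines and planted-pair recovery
over 50 strong-scenario pipelines, both at a reduced
$K_A = K_B = 20$ permutation design; the full $100\times100$ design is
exercised once for its cardinality. These sizes keep the whole
validation suite in the minutes range on one CPU while leaving the
binomial error of the estimated rates well inside the asserted
margins.

## Numerical choices and degenerate inputs

* Permutation p-values and adjusted p-values use $+1$ smoothing
  throughout; all p-values lie in $(0,1]$ and adjusted $\ge$ raw by
  construction.
* Dendrogram heights are passed through a running maximum before
  cutting: exact dissimilarity ties can produce float-level height
  inversions that `cutree` rejects.
* `minModuleSize` larger than the gene count yields a single
  all-unassigned pool with a warning; an all-zero adjacency is an
  error for the scale-free fit; a constant-connectivity network
  reports fit 0 with a warning.
* Ineligible concepts (fewer than `minDocs` documents) have *no*
  profile — distinct from an eligible concept with an empty profile —
  and contribute zero wherever a profile is expected.
* Random sub-seeds for the two tissues' permutation sets are derived
  from the pipeline seed by fixed offsets, so reruns are bit-identical
  and the gene- and annotation-overlap nulls share their random
  module sets.

## Limitations

The branch cut is a deliberate simplification of the reference
dynamic-hybrid tree-cut (no PAM stage); analyses of this kind report that
the split sensitivity has little effect on module composition, and the
package's contract is planted-module recovery rather than label-exact
replication of any particular implementation. Annotation scoring uses
raw summed similarities (no normalization by module size — ranking
within a module is unaffected) and ignores ontology hierarchy.
Cross-tissue eigengene correlation and module-preservation statistics
are out of scope.
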