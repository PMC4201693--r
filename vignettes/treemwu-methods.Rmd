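---
title: "Risk-group trees and Mann-Whitney tests for joint SNP association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-group trees and Mann-Whitney tests for joint SNP association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemwu)
```

## The model

treemwu tests whether a *set* of SNPs is jointly associated with a
case-control phenotype, allowing high-order gene-gene interaction, without
testing interaction terms one pair at a time.  The building block is the
likelihood ratio of a multi-locus risk group: subjects are partitioned into
groups $G$ by their genotypes at a few selected SNPs, and each subject in
group $G$ receives the score

$$LR = \frac{P(G \mid D)}{P(G \mid \bar D)},$$

the ratio of the group's frequency among cases to its frequency among
controls.  Joint association is then tested with the Mann-Whitney U
statistic on these scores,

$$U = \frac{1}{N_D N_{\bar D}} \sum_{i=1}^{N_D} \sum_{j=1}^{N_{\bar D}}
      \psi(LR_i, LR_j), \qquad
  \psi(a, b) = \begin{cases} 1 & a > b \\ 0.5 & a = b \\ 0 & a < b
  \end{cases},$$

which is identically the AUC of the LR score.  Its variance uses the
two-sample component (placement) form
$$\mathrm{Var}(U) = \frac{1}{N_D(N_D - 1)} \sum_i (\bar\psi_{i\cdot} - U)^2
 + \frac{1}{N_{\bar D}(N_{\bar D} - 1)} \sum_j (\bar\psi_{\cdot j} - U)^2,$$
and $Z = (U - 0.5)/\sqrt{\mathrm{Var}(U)}$ is standard normal under the
null.  `mwu()` computes all of this in $O(n \log n)$ with average ranks;
the test suite verifies exact agreement with the naive double sum.

## The two search engines

**LRMW** (`lrmw()`) grows a forward-selection risk-group tree.  At each
level it scans every remaining SNP and every allowed genotype partition
(dominant $\{0\}|\{1,2\}$, recessive $\{0,1\}|\{2\}$, and with `hz = TRUE`
also heterozygote-vs-homozygotes $\{1\}|\{0,2\}$), applies the split to
*all* current risk groups simultaneously, and keeps the pair that maximizes
the MWU of the resulting plug-in LR assignment.  Depth $d$ therefore yields
at most $2^d$ groups, one new SNP per level.  The depth is chosen by
stratified 10-fold cross-validation: each fold's tree is evaluated on the
held-out tenth at every depth prefix, and the depth with the highest mean
validation U wins (ties to the shallower model).

The shared level-wise split — the same (SNP, partition) refining every
group, rather than per-node CART-style splits — is a deliberate design
choice: it matches the method's $2^d$-group structure and keeps the model
interpretable as a genotype cross-classification.  Whether per-node
heterogeneous splits would help is untested here and out of scope.

**TAMW** (`tamw()`) targets architectures with many weak signals that a
single greedy tree cannot capture.  It grows a large number of trees, each
on a bootstrap sample and restricted to a random subset of `mtry` SNPs,
applies each tree to its out-of-bag (OOB) subjects, and averages the OOB
scores per subject:
$$LR^{assem}_i = \sum_{j=1}^{T_i} LR_{i,j} / T_i,$$
where $T_i$ counts the trees for which subject $i$ was out of bag.  The
MWU of the assembled score is the joint test.  The tree depth is fixed by a
burn-in: the first `burnin` trees are scored at every depth in
`depth_grid` (prefixes of the same trees, since forward selection nests),
and the depth with the best accumulated OOB U is used for the rest of the
ensemble.

## Honest significance

Both engines select their model on the data, so the in-sample p-value is
optimistic; `lrmw()` labels it as such.  Two honest routes are provided:

* `split_evaluate()` (default route, fraction 0.5): fit on a stratified
  training half, score the untouched test half, and use the normal
  approximation there.  This mirrors standard practice of reporting
  test-set p-values for selected models; the 0.5 fraction is a convention
  of this package.
* `permutation_test()`: permute phenotype labels and re-run the *entire*
  pipeline — including cross-validation or burn-in — per permutation, with
  the add-one estimate $p = (1 + \#\{U^{perm} \ge U\})/(1 + B)$.  Correct
  but expensive; the test suite explicitly guards that the refit happens
  every permutation.

P-values are one-sided upper by default: the LR scores are constructed on
the training data to rank cases above controls, so the alternative of
interest is $U > 0.5$.  `--two-sided` / `sided = "two"` is available.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `min_group_size` | 10 subjects | "small number of samples" stopping rule; 10 keeps leaf LRs estimable |
| `smoothing` | 0.5 | additive (Haldane-Anscombe style) smoothing of leaf LRs; 0 reproduces the raw plug-in ratio but is undefined for zero-control leaves (`likelihood_ratio()` then errors; the tree search represents the ratio as `+Inf`) |
| `max_depth` (LRMW) | 10 | generous upper bound for CV to prune; real-data fits of this model family typically select 6-7 |
| `n_folds` | 10 | standard CV granularity, stratified |
| `n_trees` (TAMW) | 500 | "large number of bootstrap samples"; tests use 100-200 at desk scale |
| `mtry` | `round(sqrt(n_snps))` | random-forest convention for de-correlating trees |
| `burnin` | 50 | depth tuning from the first 50 bootstrap samples |
| `depth_grid` | 2:6 | shallow ensembles; OOB averaging supplies the complexity |
| `hz` | off | adds the $\{1\}|\{0,2\}$ partition when heterozygote effects are plausible |

## Numerical choices and degenerate inputs

* A split is accepted only if it increases training U by more than 1e-12
  (floating-point guard); ties among equal-U candidates go to the lowest
  SNP index, then the partition order of `enumerate_partitions()`, so runs
  are bit-reproducible given the data, parameters and seed.
* Subjects missing the chosen SNP at a level are frozen at their pre-split
  group: they keep that group's LR for scoring and leave the refined
  groups' counts.  Routing a new subject works the same way, and a subject
  whose genotype combination was never seen in training falls back to the
  parent group's LR and is flagged.  An all-missing subject sits at the
  root with LR 1.
* Monomorphic SNPs need no special casing: no partition refines any group,
  so no strict U increase is possible and they are never selected.
* `Var(U) = 0` (all placements equal — all-tied scores, or perfect
  separation) is reported as a degenerate statistic with `Z = NA` and
  p-value 1 rather than dividing by zero.
* All randomness (fold shuffles, bootstrap draws, SNP subsets,
  permutations, splits) flows from explicit seeds; TAMW derives one stream
  per tree from the master seed so results do not depend on the order in
  which trees are grown.

## The synthetic-data generator

`simulate_cc()` emulates the study conditions the methods were designed
for, so that every pipeline is testable without external genotype data.
Genotypes are drawn at Hardy-Weinberg proportions and linkage equilibrium
(the latter deliberately, so oracles stay exact); disease status follows a
penetrance model and case/control genotype distributions are obtained by
Bayes' rule:

* `null`: phenotype independent of all genotypes.
* `marginal`: one causal SNP, dominant penetrances (defaults
  $f_0 = 0.05$, $f_{carrier} = 0.15$, MAF 0.3).
* `epistatic_pair`: two interacting SNPs (MAF 0.25, prevalence 0.1) whose
  joint "carrier at both loci" class raises risk; penetrances are solved
  in closed form so the oracle AUC of the true risk score is exactly the
  requested 0.75 (two-class AUC $= 0.5 + (a - b)/2$ with
  $a = P(\text{high} \mid D)$, $b = P(\text{high} \mid \bar D)$).  The
  per-SNP marginals are moderate; the joint effect is what a depth-2 tree
  must find.
* `many_weak`: 50 causal SNPs with per-allele odds ratios drawn from
  [1.1, 1.2] under a log-additive logistic model, prevalence 0.1, sampled
  prospectively by rejection.  This is the regime where the ensemble is
  expected to beat the single tree.  Its oracle AUC comes from a numeric
  convolution of the polygenic score distribution on a 5e-4 grid
  (near-exact; the nine-class oracles are exact enumerations).

What the generator does *not* emulate: linkage disequilibrium, population
stratification, genotyping batch effects, covariates, and dosage
uncertainty.  Passing tests therefore demonstrate correctness of the
statistics and search under idealized sampling, not robustness to
real-data confounding.

## Problem sizes used by the test suite

The replicate-based checks run at desk scale, chosen once: null
calibration uses 500 replicates of n = 400 with 100 null SNPs (LRMW at
`max_depth = 10`; TAMW at 100 trees, burn-in 25, grid 2:4); signal
recovery uses 50 replicates of n = 1000 with the epistatic pair among 100
SNPs; the regime comparison uses 50 replicates per architecture of
n = 2000 with 500 SNPs (TAMW at 200 trees).  `scripts/acceptance.R`
re-runs the same pipelines at these scales from a caller-supplied seed.

## Known limitations

* Genome-scale inputs (hundreds of thousands of SNPs) are supported by the
  bit-packed storage but the search loops are tuned for desk-scale
  correctness, not for multi-hour genome-wide runs.
* The CV depth grid evaluates prefixes of each fold's deepest tree rather
  than regrowing a tree per depth; this is exact for forward selection's
  nested models and much cheaper, but means a fold's tree that stops early
  contributes its deepest model to all larger depths.
* `optimal_depth` is the argmax of the CV curve; in rare cases the final
  full-data tree stops shallower (no admissible split), and the realized
  depth is reported alongside.
* The permutation route refits everything and is priced accordingly; for
  ensembles it is best reserved for small candidate panels.
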