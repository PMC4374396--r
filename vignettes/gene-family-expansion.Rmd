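---
title: "Testing clade-specific gene family expansion with birth-death models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clade-specific gene family expansion with birth-death models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famshift)
```

## The question

Gene families grow by duplication and shrink by loss. Under neutral
evolution both happen at steady per-copy rates, so large families in
one clade can arise by chance alone. famshift asks whether a family's
size in a focal clade is *too large for chance*: whether the data
require a clade-specific increase in the duplication rate. The worked
example shipped with the package is the classic case of amino acid
transporters (the APC and AAAP superfamilies) in Sternorrhyncha — sap
feeding insects whose bacterial endosymbionts provision essential
amino acids, creating selection for amino-acid transport capacity at
the symbiotic interface.

Three complementary analyses are implemented, mirroring the standard
toolbox of the field:

1. **Model fitting** (`fit_bd()`): a linear birth-death model of copy
   number evolution along a dated species tree, with nested variants
   that allow the duplication rate λ, and optionally a separate loss
   rate μ, to shift on a designated branch set. Nested fits are
   compared by likelihood-ratio tests (`lr_test()`), with χ² or
   parametric-bootstrap p-values (`simulated_null_lrt()`), and by AIC.
2. **Reconciliation** (`lca_reconcile()`): embedding an observed gene
   tree into the species tree by LCA mapping to count duplications and
   losses per species branch.
3. **Simulation null test** (`run_null_test()`): gene ("guest") trees
   simulated along the chronogram under neutral rates give empirical
   null distributions of the clade's duplications D, losses L and net
   expansion k = D − L; observed values are scored by one-sided
   empirical p-values.

## The model

Each gene copy duplicates at rate λ and is lost at rate μ (per gene
per Myr); zero copies is absorbing — a lost family cannot re-arise,
because there is no innovation/immigration term. The number of
descendants of a single copy after time *t* is modified-geometric:

$$P(0) = \alpha,\qquad
  P(c \ge 1) = (1-\alpha)(1-\beta)\beta^{\,c-1},$$

with
$\alpha = \mu(e^{(\lambda-\mu)t}-1)/(\lambda e^{(\lambda-\mu)t}-\mu)$,
$\beta = (\lambda/\mu)\,\alpha$, and
$\alpha = \beta = \lambda t/(1+\lambda t)$ in the tied case
$\lambda=\mu$. Transitions from *s* copies are the *s*-fold
convolution. Numerically the package builds transition matrices by
repeated convolution rather than by the textbook closed-form sum over
binomial coefficients: the closed form alternates in sign once
$\alpha+\beta>1$ (i.e. for rate × time products of order one) and
loses all precision there, while the convolution is non-negative
throughout and exact to machine precision; `α`, `β` are evaluated via
`expm1` so the λ→μ limit is continuous. The family likelihood is
computed by Felsenstein pruning over the copy-number state space
`0..cmax`, for all families simultaneously.

Tunable parameters that matter:

* **Rates** λ, μ (per gene per Myr). Bounded in `[1e-10, 10]` during
  fitting; empirically, transporter-like families sit near `1e-3`.
* **Truncation** `cmax` (default: max observed count + 20). The
  convolution is exact for retained states, so `cmax` only needs to
  dominate plausible interior counts; `adaptive_cmax()` grows it until
  transition rows lose less than `1e-10` mass.
* **Root policy.** The root count is unobserved. The default is a
  uniform prior on `1..cmax` (the example families are universally
  present, so a zero root is excluded); `"fixed"` conditions on a
  known count (used throughout the oracle tests, where it makes
  generator and model match exactly); `"uniform_surviving"`
  additionally conditions on the family surviving anywhere, for data
  sets that exclude extinct families.
* **Model structures.** `single_lambda` (tied λ=μ, 1 parameter),
  `multi_lambda` (tied, separate focal-clade rate, 2),
  `single_lambda_mu` (free λ, μ, 2), `multi_lambda_mu` (both shifting,
  4). The focal set conventionally includes the clade's stem branch —
  `mrca_branches(..., include_stem = TRUE)` — so a shift applies from
  the clade's origin; a flag excludes it.

Optimisation is Brent's method for one parameter and Nelder-Mead on
the log-rate scale for more, with a warm start from the nested tied
fit (which also guarantees that a richer model never scores below its
null beyond optimiser noise), one deterministic start at `1e-3`, and
seeded log-uniform random starts (5 in total by default). Tiny
negative LR statistics (optimiser noise above `-1e-6`) are clamped to
zero.

## Reconciliation conventions

`lca_reconcile()` maps each gene node to the LCA of its descendants'
species. A node is a duplication when its mapping equals a child's
mapping; losses along a gene edge $(u,v)$ number
$\mathrm{path}(M(u),M(v)) - 1 + [u\ \mathrm{dup}]$, each assigned to
the species branch on which the vanished copy lived. The LCA mapping
minimises duplications and losses simultaneously, so the weighted cost
(defaults 1.5 per duplication, 1.0 per loss, the conventional
weights) is reporting-only. Losses above the gene root are not
counted — events are read from the root's mapping downward.
Duplications mapped to the species root are recorded under the root
label, which no clade branch set contains by default.

## The simulation null

`simulate_guest()` runs the same birth-death process generatively:
one lineage (configurable) enters at the host root, waits exponential
times to duplicate or die along each branch, and splits at every host
speciation; every event is logged with its host branch and absolute
time. There is no conditioning on survival by default (switching it
on is reported, since it shifts the null distributions), no horizontal
transfer, and losses of a subtree's last copy are ordinary logged
events. `run_null_test()` repeats this `N` times (1000 by default),
counts events inside the focal branch set, and reports
$p = (1 + \#\{\text{replicates at least as extreme}\})/(N+1)$ — the
plus-one estimator, which cannot report an impossible zero and
reproduces the characteristic `p = 0.002` granularity of
1000-replicate studies. Duplications and net expansion are tested
upper-tailed; losses are reported in both tails, because an expansion
can reflect either surplus duplications or a deficit of losses and
the two explanations are worth separating.

## Ancestral counts

`sankoff_counts()` reconstructs ancestral family sizes by linear-cost
(Wagner) parsimony over `0..cmax`: the minimum total |change| is
unique, and point estimates are made deterministic by a preorder
tie-break that picks the optimal state closest to the parent's chosen
state (smallest optimal state at the root, biasing ties toward the
more parsimonious-looking smaller ancestral complement). Asymmetric
per-unit costs (e.g. 1.5/1.0) are available to mirror reconciliation
weights. `ml_ancestral_counts()` gives the model-based alternative:
the marginal posterior mode per node under fitted rates, ties to the
smallest count. This pair covers, in spirit, the
parsimony-versus-likelihood duality of the established count-based
tools; it is a documented analog, not a re-implementation of any of
them.

## What the generators emulate — and what they do not

`yule_tree()` draws pure-birth chronograms of configurable depth;
`simulate_count_matrix()` evolves family counts with optional
clade-restricted shifts, recording true rates; `simulate_guest()`
provides event-level ground truth. Defaults encode the regime of the
motivating data: 13 taxa, tree depth of a few hundred Myr, rates near
`1e-3` per gene per Myr, shifts of 3–11×, and a root complement of
5–15 copies (drawn uniformly), the size range of well-populated
transporter families. What the generators deliberately do not emulate:
among-family rate variation, annotation error in leaf counts (no
error model — the motivating study's counts were conservatively
collapsed), gene conversion, and horizontal transfer. Passing tests
therefore demonstrate the machinery is correct under the stated model,
not that real data satisfy that model.

The packaged 13-taxon chronogram reproduces the published topology
for the example species, but its node ages are synthetic placeholders
(root ≈ 390 Myr, Sternorrhyncha MRCA ≈ 250 Myr, a plausible
Permian-to-present span); exact published ages are not available, so
absolute rates estimated on it are illustrative. The sternorrhynchan
interior is fixed to ((aphid, mealybug), (whitefly, psyllid)); the
published text does not resolve it, and no packaged result depends on
that choice.

## Numerical and design choices

* Branch identity is the child node's label; unlabeled internal nodes
  get deterministic labels hashed from their sorted descendant leaf
  sets, so branch sets are stable across runs and serialisations.
* Ultrametricity is checked with a tolerance relative to depth
  (`1e-6 ×` depth) because published chronograms carry rounding error;
  failing trees are flagged and refused only by the likelihood.
* Counts tables are species-as-columns; a transposed file is detected
  by matching taxon names against the paired tree and re-oriented
  with a message.
* All stochastic functions take a `seed` and are bit-reproducible;
  pipeline drivers derive per-stage seeds from one master seed.
* Problem sizes in the shipped validation suite were chosen to give
  stable Monte-Carlo verdicts at modest cost: 10,000 replicates for
  simulator closed forms, 500 datasets × 1000 families for the χ²
  calibration of the LRT, 20 repetitions for shift detection, and 10
  pipeline runs × 1000 null replicates for the end-to-end power and
  calibration checks.

## Known limitations

* No gain/innovation term and no among-family rate variation; families
  absent at the root cannot be modelled.
* The LCA reconciliation assumes rooted binary trees on both sides and
  does not rearrange weakly supported edges.
* The uniform root prior is a pragmatic default, not an estimate; with
  few families the fitted μ can soak up root-prior misfit, which is
  why the calibration studies pin the root.
* p-values from `N` replicates cannot go below `1/(N+1)`; claims such
  as `p < 1e-4` require correspondingly more replicates.
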