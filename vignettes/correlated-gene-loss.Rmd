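---
title: "Correlated gene loss, rate covariation and interactor filtering: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated gene loss, rate covariation and interactor filtering: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecoev)
```

This package implements three statistical procedures that together ask
whether a set of genes forms a functional unit: a phylogenetic test of
correlated, irreversible gene loss; evolutionary rate covariation (ERC)
with a pathway-mean permutation test; and spectral-count enrichment
filters for calling protein interactors from BioID and
co-immunoprecipitation mass spectrometry. The motivating biology is the
MCM8IP–MCM8–MCM9 module of homologous recombination, but every function is
generic over trees, trait matrices, branch-rate tables and count tables.

## The irreversible-loss model of co-occurrence

Gene presence/absence across species is modeled as a continuous-time
Markov chain running along a rooted, time-calibrated phylogeny. Because
the traits are strict orthologs, a lineage that has lost a gene cannot
regain it: all gain rates are fixed at zero, and the chain only ever moves
toward absence.

Under the **independent model**, gene 1 and gene 2 are lost at rates
$\beta_1$ and $\beta_2$ regardless of one another, and the joint
likelihood is the product of two two-state chains (two free parameters).
Under the **dependent model**, the state space is the four joint presence
states $(1,1), (1,0), (0,1), (0,0)$ and each gene's loss rate splits
according to the partner's presence, giving the four free rates

* $q_{42}$: loss of gene 1 while gene 2 is present,
* $q_{43}$: loss of gene 2 while gene 1 is present,
* $q_{31}$: loss of gene 1 after gene 2 is already absent,
* $q_{21}$: loss of gene 2 after gene 1 is already absent,

with $(0,0)$ absorbing. The independent model is the submodel with
$q_{42} = q_{31}$ and $q_{43} = q_{21}$ — this factorization identity is
asserted numerically in the test suite. The models are compared with a
likelihood-ratio statistic $\Lambda = 2(\ln L_{dep} - \ln L_{ind})$
referred to a $\chi^2$ distribution with $4 - 2 = 2$ degrees of freedom;
low p-values indicate that losses of the two genes travel together.

Tip likelihoods are computed by the standard post-order pruning recursion,
with transition matrices $P(t) = e^{Qt}$ obtained by scaling-and-squaring
matrix exponential in compiled code. We deliberately avoid the closed-form
eigendecomposition of the loss generator: it degenerates when rate sums
coincide (e.g. $q_{42} + q_{43} = q_{31}$), exactly the region a numerical
optimizer likes to cross. The closed forms instead serve as independent
oracles in the tests, alongside brute-force enumeration over internal-node
states on small trees.

**Root treatment.** The root state is fixed at present (single trait) or
both-present (pair). With all gain rates zero this is the only
non-degenerate choice: any other root state assigns probability zero to a
dataset in which either gene is observed anywhere. A stem branch above the
crown root, if present in the Newick input, is ignored; the likelihood
conditions on the crown state. Missing tip states (`?` in the input,
`NA` internally) enter as all-ones partial likelihoods — unobserved, never
absent.

**Optimization.** Rates are optimized on the log scale within
$[10^{-6}, 10^{3}]$ per unit mean branch length (internally rescaled by
the mean branch length so the bounds are meaningful on any time scale).
The two independent-model rates are each profiled by bounded Brent search,
with the bounds themselves evaluated so boundary optima (a gene never
lost) are found exactly. The four dependent-model rates use multi-start
L-BFGS-B, 25 starts by default: the first start is always the
independent-model estimate — which guarantees the nested-likelihood
ordering $\ln L_{dep} \ge \ln L_{ind}$ up to optimizer tolerance — and the
rest are seeded log-uniform draws. A negative $\Lambda$ beyond $10^{-6}$
triggers a warning (it can only mean the dependent optimizer failed) and
is clipped to zero. Several gene pairs are typically reported with raw
p-values, as is conventional when a handful of named pairs is tested; a
Bonferroni factor is available via `n_comparisons`.

## Evolutionary rate covariation

ERC starts from per-gene branch lengths estimated on a fixed species
topology, together with a genome-average (reference) length per branch. A
gene's branch-specific relative rate is its length divided by the
reference; each gene's rate profile is then mean-centered and unit-scaled
over its own observed branches. The transformation is not restated by
every study that uses ERC; ratio-to-reference plus per-gene
standardization is used here because it preserves the defining statistic —
the correlation coefficient of branch-specific rates — while making it
invariant to per-gene scale. A Spearman option is provided for robustness
to heavy-tailed rate errors; Pearson is the default.

ERC between two genes is the Pearson correlation of their profiles over
shared branches (at least 3, else undefined). The pathway statistic is the
mean ERC between a focal gene and a gene set, and its significance comes
from a permutation null: substitute a random focal gene drawn from the
background pool — all profiled genes except the focal gene and the
pathway — and recompute the set mean. The reported p-value is the fraction
of null means at least as large as the observed one, ties included; the
bias-corrected $(k+1)/(N+1)$ estimate is always reported alongside,
because $k/N$ can return an exact zero, which is an artifact of finite
resampling. Draws are made with replacement in all cases: a single,
well-defined exchangeable null is preferable to switching schemes with
pool size, and with genome-scale pools the distinction is immaterial.
Excluding the tested entities from the pool avoids trivially inflating the
null; both exclusions are configurable.

## Interactor filtering from spectral counts

Proximity labeling (BioID) and co-immunoprecipitation followed by mass
spectrometry produce, after upstream protein identification at 1% FDR
(consumed here as an input table, never recomputed), per-protein
unique-peptide and total-spectral-count values for bait and control
pulldowns. The filter retains a protein isoform when

1. its bait unique-peptide counts clear a floor (default 2), either in
   some bait replicate or in every bait replicate, and
2. its bait count statistic — total or replicate-average of total spectral
   counts — is at least `min_fold` times the control statistic
   (inclusive, so 9 vs 3 passes a 3-fold cut).

A control statistic of zero with positive bait counts passes as
infinitely enriched, flagged as such; genuine hits are routinely absent
from control pulldowns, so a hard ratio would discard the strongest
signals. A pseudocount alternative (`pseudocount = 0.5`) is available for
analysts who prefer finite folds. Endogenously biotinylated carboxylases
are removed in BioID mode (the shipped list covers PC, PCCA, PCCB, MCCC1,
MCCC2, ACACA, ACACB and is editable), and isoforms are collapsed to gene
level — a gene is a hit when at least one isoform passes, with gene-symbol
grouping by default and accession-prefix grouping as an option. Raising
either threshold can only remove genes; this monotonicity is asserted as a
property test. Experiments are intersected at gene level with full Venn
region counts.

## What the simulators emulate — and what they do not

The synthetic-data module generates every input the pipeline consumes, so
all claims above are exercised without downloads.

* **Trees** are Yule (pure-birth): the simplest process with controllable
  depth, sufficient because the co-occurrence test conditions on the tree
  rather than its generating process. Real species trees are neither
  ultrametric in estimate nor clock-like in error; passing tests on Yule
  trees says nothing about topology misspecification.
* **Traits** are simulated forward along branches by exponential waiting
  times between allowed loss transitions, the exact generative counterpart
  of the fitted models. Ascertainment (species chosen for genome quality)
  is not emulated.
* **Branch rates** put log-normal multiplicative noise (default SD 0.3 on
  the log scale) around the reference lengths, with a per-branch latent
  factor shared by a designated gene block so that within-block log-rate
  correlation equals a target $\rho$; on the rate scale the realized ERC
  is close to $\rho$ for moderate noise. Real rate estimates have
  branch-length-dependent error and shared-tree covariance that this
  construction ignores.
* **Spectral counts** are negative binomial (dispersion 0.5 by default —
  overdispersion is the norm in spectral counting) around per-protein
  log-normal baselines, with true interactors' bait means multiplied by a
  fold change and peptides increasing with counts. Contaminant structure
  beyond the carboxylase class is not modeled.

Calibration studies in the tests and the acceptance script use these
conditions: 40-tip trees with loss rates 0.3 for the type-I study of the
LRT (500 replicates; the $\chi^2$ reference is asymptotic, and the
observed rejection rate is checked against the exact binomial 95% band
around 0.05 rather than asserted equal to it); 200-tip trees with rates
0.2/0.4 for recovery; and, for ERC calibration, a background of 1000
profiled genes with a focal-plus-10-gene pathway over 30 branches. The
background size matters: permutation p-values of the $k/N$ form inherit
the rank discreteness of the pool, and with only a few dozen background
genes the chance of $p < 0.05$ is about $3/50 = 0.06$ even under a perfect
null. A genome-scale background — the setting in which pathway ERC is
actually used, with permutations over thousands of random genes — makes
that discreteness negligible, which is why 1000 genes is the default study
condition here.

## Numerical conventions and edge cases

* Branch lengths are absolute time (TimeTree-style); only the product
  rate × length is identifiable, so the unit is a labeling convention.
* Newick round trips preserve lengths to at least 12 significant digits;
  pruning a tree to a taxon subset preserves all patristic distances
  among retained tips to $10^{-9}$.
* `transition_matrix` is validated against the closed form
  $e^{-\beta t}$ and the semigroup property $P(s)P(t) = P(s+t)$.
* Likelihood impossibilities (data incompatible with the root state)
  return `-Inf` rather than an error, so optimizers can step away.
* Conditional likelihoods are rescaled during the post-order pass to
  avoid underflow on deep trees.
* Refitting a dependent model from its own returned estimates reproduces
  the optimum within $10^{-6}$ log-likelihood units.

## A worked synthetic example

```{r example, eval = FALSE}
tree <- simulate_yule_tree(150, birth_rate = 1, seed = 42)
gen <- pair_loss_generator(q42 = 0.05, q43 = 0.05, q31 = 1.2, q21 = 1.2)
traits <- simulate_trait_pair(tree, gen, seed = 43)
lrt_cooccurrence(tree, traits, "gene1", "gene2",
                 coev_opts(restarts = 10, seed = 1))
```

Here each gene is lost 24 times faster once its partner is gone; with 150
tips the dependent model is normally preferred decisively. The
command-line interface (`inst/cli/genecoev`) exposes the same
functionality as `fit-cooccurrence`, `erc`, `erc-permtest`,
`filter-interactome` and the three `simulate-*` subcommands, each emitting
a JSON run report with input digests and the seed used.

## Known limitations

* No Bayesian mode, no gain rates, no hidden-rate (covarion) models, and
  at most two traits jointly.
* ERC consumes precomputed branch-length tables; it does not align
  proteins or estimate branch lengths from sequences.
* The permutation null treats profiled genes as exchangeable; shared-tree
  covariance among null genes is not modeled.
* The interactome module implements spectral-count filtering only — no
  peptide-spectrum matching, FDR control or label-free quantification.
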