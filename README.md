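# genecoev

Three complementary computational lines of evidence that a set of genes
works as a unit, implemented as one tested R package:

1. **Correlated gene loss.** Gene presence/absence across a species
   phylogeny is modeled as an irreversible continuous-time Markov chain
   (gains impossible, losses only). An *independent* model gives each gene
   its own loss rate (β₁, β₂); a nested *dependent* model lets each gene's
   loss rate differ according to the partner's presence (q₄₂, q₄₃, q₃₁,
   q₂₁ over the joint states (1,1), (1,0), (0,1), (0,0), with (0,0)
   absorbing). The models are compared by a likelihood-ratio test,
   Λ = 2(lnL_dep − lnL_ind) against χ² with 2 degrees of freedom; small
   p-values mean the genes tend to be lost together.
2. **Evolutionary rate covariation (ERC).** Branch-specific relative
   rates — per-gene branch lengths divided by a genome-average reference,
   then standardized per gene — are correlated between genes; the
   pathway-level statistic is the mean ERC between a focal gene and a
   gene set, tested against a permutation null of random focal genes.
3. **Interactome filtering.** Putative protein interactors are called
   from BioID / co-IP spectral-count tables by a unique-peptide floor and
   an inclusive fold-enrichment cut over matched controls, with
   carboxylase exclusion, isoform collapsing to gene level, and Venn
   intersection across experiments.

A synthetic-data module generates every input type (Yule trees, paired
loss traits, block-correlated branch rates, negative-binomial spectral
counts) with mandatory seeds, so the whole pipeline is testable offline.
The intended users are molecular evolution and proteomics analysts
studying gene modules such as MCM8IP–MCM8–MCM9 in homologous
recombination.

## Worked example

```r
library(genecoev)

tree   <- simulate_yule_tree(150, birth_rate = 1, seed = 42)
gen    <- pair_loss_generator(q42 = 0.05, q43 = 0.05, q31 = 1.2, q21 = 1.2)
traits <- simulate_trait_pair(tree, gen, seed = 43)
lrt_cooccurrence(tree, traits, "gene1", "gene2",
                 coev_opts(restarts = 10, seed = 1))
#> Correlated gene loss LRT: gene1 vs gene2
#>   lnL independent = -74.213652, lnL dependent = -54.479665
#>   LRT = 39.4680, df = 2, p = 2.689e-09
```

The simulation lost each gene 24× faster once its partner was gone
(q₃₁ = q₂₁ = 1.2 vs q₄₂ = q₄₃ = 0.05); the dependent fit recovers that
asymmetry (q̂₃₁ = 1.51, q̂₄₂ = 0.047) and the LRT rejects independent
loss at p ≈ 3 × 10⁻⁹. The same machinery on real data takes a Newick tree
(`parse_newick`) and a presence/absence table (`read_trait_matrix`, cells
`1`/`0`/`?`).

ERC on simulated block-correlated rates (focal gene + 10-gene pathway,
1000-gene background, ρ = 0.8):

```r
genes <- sprintf("g%04d", 1:1000); block <- genes[1:11]
blt <- simulate_branch_rates(30, genes, block, rho = 0.8, seed = 7)
pt  <- permutation_pvalue(block[1], block[-1], relative_rates(blt),
                          N = 10000, seed = 8)
#> Pathway-mean ERC permutation test (10000 draws, pool 989)
#>   observed mean ERC = 0.7201 over 10 genes
#>   p = 0 (bias-corrected 9.999e-05)
```

Interactor calling on the packaged 25-row fixture (≥2 peptides, ≥3-fold,
carboxylase excluded, isoforms collapsed) retains exactly 7 genes:

```r
tab <- read_spectral_counts(
  system.file("extdata", "toy_spectral_counts.tsv", package = "genecoev"),
  system.file("extdata", "toy_roles.yaml", package = "genecoev"))
enrichment_filter(tab)$genes
#> [1] "GENE1"  "GENE10" "GENE11" "GENE2"  "GENE5"  "GENE6"  "GENE7"
```

A command-line wrapper (`inst/cli/genecoev`) exposes the subcommands
`fit-cooccurrence`, `erc`, `erc-permtest`, `filter-interactome`,
`simulate-traits`, `simulate-erc` and `simulate-spectra`; every run emits
a JSON report with the configuration, md5 digests of the inputs, warnings
and the seed.

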