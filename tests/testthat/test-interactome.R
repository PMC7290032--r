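toy_table <- function() {
  read_spectral_counts(
    system.file("extdata", "toy_spectral_counts.tsv", package = "genecoev"),
    system.file("extdata", "toy_roles.yaml", package = "genecoev"))
}

test_that("the packaged fixture yields exactly its hand-tallied hits", {
  tab <- toy_table()
  expect_length(tab$accession, 25L)
  hits <- enrichment_filter(tab, min_unique_peptides = 2, min_fold = 3)
  expect_setequal(hits$genes, c("GENE1", "GENE2", "GENE5", "GENE6",
                                "GENE7", "GENE10", "GENE11"))
  expect_length(hits$genes, 7L)
  # the carboxylase never surfaces despite massive enrichment
  expect_false("PC" %in% hits$genes)
  # infinite enrichment is flagged
  ev <- hits$evidence
  expect_true(ev$infinite_enrichment[ev$gene == "GENE5"])
  expect_false(any(ev$infinite_enrichment[ev$gene != "GENE5"]))
})

test_that("fold and peptide thresholds are inclusive boundaries", {
  roles <- data.frame(sample = c("b1", "c1"),
                      role = c("bait", "control"), replicate = 1L)
  tab <- spectral_count_table(
    c("X1", "X2", "X3"), c("GA", "GB", "GC"),
    peptides = cbind(b1 = c(2L, 2L, 1L), c1 = c(0L, 0L, 0L)),
    counts = cbind(b1 = c(9L, 8L, 90L), c1 = c(3L, 3L, 1L)),
    roles = roles)
  hits <- enrichment_filter(tab, min_unique_peptides = 2, min_fold = 3)
  expect_identical(hits$genes, "GA")   # 9 >= 3x3 passes, 8 < 9 fails,
                                       # single peptide fails regardless
})

test_that("control-zero handling: infinite enrichment vs pseudocount", {
  roles <- data.frame(sample = c("b1", "c1"),
                      role = c("bait", "control"), replicate = 1L)
  tab <- spectral_count_table(
    c("X1", "X2"), c("GA", "GB"),
    peptides = cbind(b1 = c(3L, 3L), c1 = c(0L, 0L)),
    counts = cbind(b1 = c(1L, 0L), c1 = c(0L, 0L)),
    roles = roles)
  hits <- enrichment_filter(tab, min_fold = 3)
  expect_identical(hits$genes, "GA")  # bait > 0 over control 0 passes
  expect_true(hits$evidence$infinite_enrichment)
  # pseudocount mode: (1 + 0.5)/(0 + 0.5) = 3 passes inclusively but is
  # no longer flagged; an all-zero row still fails
  hits_pc <- enrichment_filter(tab, min_fold = 3, pseudocount = 0.5)
  expect_identical(hits_pc$genes, "GA")
  expect_false(hits_pc$evidence$infinite_enrichment)
  expect_length(enrichment_filter(tab, min_fold = 3,
                                  pseudocount = 1)$genes, 0L)
})

test_that("raising thresholds never adds genes (monotone filtering)", {
  for (s in 1:5) {
    sim <- simulate_spectral_counts(list(n_proteins = 150,
                                         n_true_interactors = 15,
                                         fold_change = 6, seed = s))
    base <- enrichment_filter(sim$table, 2, 3)
    for (fold in c(5, 8)) {
      expect_true(all(enrichment_filter(sim$table, 2, fold)$genes
                      %in% base$genes))
    }
    expect_true(all(enrichment_filter(sim$table, 4, 3)$genes
                    %in% base$genes))
    # each-replicate peptide rule is at least as strict as any-replicate
    expect_true(all(enrichment_filter(sim$table, 2, 3,
                                      peptide_rule = "each-replicate")$genes
                    %in% base$genes))
  }
})

test_that("isoform collapsing reduces to gene level", {
  tab <- toy_table()
  hits <- enrichment_filter(tab)
  expect_lte(length(hits$genes), length(tab$accession))
  # both GENE6 isoforms pass; one GENE7 isoform suffices
  ev <- hits$evidence
  expect_equal(ev$n_isoforms_passing[ev$gene == "GENE6"], 2L)
  expect_equal(ev$n_isoforms_passing[ev$gene == "GENE7"], 1L)
  expect_equal(ev$accession[ev$gene == "GENE7"], "P07-2")
  # accession-prefix grouping collapses P06-1/P06-2 as well
  hits2 <- enrichment_filter(tab, isoform_group = "accession-prefix")
  expect_length(hits2$genes, 7L)
})

test_that("experiment intersection computes Venn regions correctly", {
  v <- intersect_experiments(list(e1 = c("A", "B", "C"),
                                  e2 = c("B", "C", "D")))
  expect_identical(v$common, c("B", "C"))
  expect_equal(unname(v$regions[c("10", "01", "11")]), c(1L, 1L, 2L))

  same <- list(x = c("A", "B"), y = c("A", "B"), z = c("A", "B"))
  v3 <- intersect_experiments(same)
  expect_identical(v3$common, c("A", "B"))
  expect_equal(unname(v3$regions["111"]), 2L)
  expect_true(all(v3$regions[names(v3$regions) != "111"] == 0L))

  set.seed(404)
  universe <- sprintf("u%03d", 1:200)
  sets <- lapply(1:3, function(i) sample(universe, 50))
  names(sets) <- c("s1", "s2", "s3")
  v <- intersect_experiments(sets)
  # brute-force set algebra over the universe
  for (pat in names(v$regions)) {
    bits <- as.integer(strsplit(pat, "")[[1]])
    in_region <- vapply(universe, function(g) {
      all(vapply(1:3, function(i) (g %in% sets[[i]]) == (bits[i] == 1L),
                 TRUE))
    }, TRUE)
    expect_equal(unname(v$regions[pat]), sum(in_region))
  }
  expect_setequal(v$common, Reduce(intersect, sets))
})

test_that("degenerate and invalid inputs are rejected or warned", {
  roles <- data.frame(sample = c("b1", "c1"),
                      role = c("bait", "control"), replicate = 1L)
  empty <- spectral_count_table(character(0), character(0),
                                matrix(0L, 0, 2,
                                       dimnames = list(NULL, c("b1", "c1"))),
                                matrix(0L, 0, 2,
                                       dimnames = list(NULL, c("b1", "c1"))),
                                roles)
  expect_warning(res <- enrichment_filter(empty), "empty")
  expect_length(res$genes, 0L)
  expect_error(enrichment_filter(toy_table(), min_unique_peptides = 0),
               ">= 1")
  expect_error(enrichment_filter(toy_table(), min_fold = 0), "> 0")
  expect_error(spectral_count_table("X", "G",
                                    cbind(b1 = -1L, c1 = 0L),
                                    cbind(b1 = 1L, c1 = 0L), roles),
               "non-negative")
})
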