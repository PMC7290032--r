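# Spectral-count interactor calling: peptide floors, fold-enrichment over
# matched controls, carboxylase exclusion, isoform collapsing, and Venn
# intersection across experiments.

#' Construct a spectral-count table
#'
#' Per-protein unique-peptide and total-spectral-count matrices across the
#' samples of one pulldown experiment, with a role map assigning each sample
#' to bait or control and a technical-replicate index.
#'
#' @param accession character vector of protein accessions (isoform level).
#' @param gene character vector of gene symbols, same length.
#' @param peptides non-negative integer matrix, proteins x samples
#'   (unique peptides).
#' @param counts non-negative integer matrix, proteins x samples
#'   (total spectral counts).
#' @param roles data frame with columns `sample`, `role`
#'   (`"bait"`/`"control"`) and `replicate` (integer); `sample` must match
#'   the matrix column names.
#' @return an object of class `"spectral_count_table"`.
#' @export
spectral_count_table <- function(accession, gene, peptides, counts, roles) {
  accession <- as.character(accession)
  gene <- as.character(gene)
  peptides <- as.matrix(peptides)
  counts <- as.matrix(counts)
  stopifnot(length(accession) == length(gene),
            nrow(peptides) == length(accession),
            nrow(counts) == length(accession),
            identical(colnames(peptides), colnames(counts)))
  if (anyDuplicated(accession)) stop("duplicate accessions", call. = FALSE)
  if (any(peptides < 0) || any(counts < 0) ||
      any(peptides != round(peptides)) || any(counts != round(counts))) {
    stop("peptide and spectral counts must be non-negative integers",
         call. = FALSE)
  }
  roles <- as.data.frame(roles)
  stopifnot(all(c("sample", "role", "replicate") %in% colnames(roles)))
  if (!setequal(roles$sample, colnames(counts))) {
    stop("role map samples must match count columns", call. = FALSE)
  }
  if (!all(roles$role %in% c("bait", "control"))) {
    stop("sample roles must be 'bait' or 'control'", call. = FALSE)
  }
  if (!any(roles$role == "bait") || !any(roles$role == "control")) {
    stop("need at least one bait and one control sample", call. = FALSE)
  }
  storage.mode(peptides) <- "integer"
  storage.mode(counts) <- "integer"
  structure(list(accession = accession, gene = gene, peptides = peptides,
                 counts = counts, roles = roles),
            class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat("Spectral-count table:", length(x$accession), "proteins,",
      sum(x$roles$role == "bait"), "bait and",
      sum(x$roles$role == "control"), "control sample(s)\n")
  invisible(x)
}

#' Read a spectral-count table from TSV plus a role map
#'
#' The TSV must have columns `accession`, `gene`, then one `pep_<sample>`
#' and one `sc_<sample>` column per sample. The role map may be a data frame
#' (columns `sample`, `role`, `replicate`) or the path to a YAML file of the
#' form `samples: {<sample>: {role: bait, replicate: 1}, ...}`.
#'
#' @param file path to the TSV.
#' @param roles role map data frame or YAML path.
#' @return a `"spectral_count_table"`.
#' @export
read_spectral_counts <- function(file, roles) {
  raw <- utils::read.table(file, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "gene") %in% colnames(raw)))
  if (is.character(roles) && length(roles) == 1L) {
    cfg <- yaml::read_yaml(roles)
    if (is.null(cfg$samples)) stop("role YAML needs a 'samples' block",
                                   call. = FALSE)
    roles <- data.frame(
      sample = names(cfg$samples),
      role = vapply(cfg$samples, function(s) s$role, ""),
      replicate = vapply(cfg$samples, function(s) as.integer(s$replicate),
                         1L),
      stringsAsFactors = FALSE)
  }
  samples <- roles$sample
  pep_cols <- paste0("pep_", samples)
  sc_cols <- paste0("sc_", samples)
  absent <- setdiff(c(pep_cols, sc_cols), colnames(raw))
  if (length(absent)) stop("missing count columns: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  pep <- as.matrix(raw[, pep_cols, drop = FALSE])
  sc <- as.matrix(raw[, sc_cols, drop = FALSE])
  colnames(pep) <- colnames(sc) <- samples
  spectral_count_table(raw$accession, raw$gene, pep, sc, roles)
}

#' Write a spectral-count table as TSV
#'
#' @param table a `"spectral_count_table"`.
#' @param file output path.
#' @return `file`, invisibly. The role map is not written; keep it in its
#'   own YAML/data frame.
#' @export
write_spectral_counts <- function(table, file) {
  stopifnot(inherits(table, "spectral_count_table"))
  pep <- table$peptides
  sc <- table$counts
  colnames(pep) <- paste0("pep_", colnames(pep))
  colnames(sc) <- paste0("sc_", colnames(sc))
  df <- data.frame(accession = table$accession, gene = table$gene,
                   pep, sc, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Default carboxylase exclusion list
#'
#' Naturally biotinylated carboxylases bind streptavidin regardless of
#' proximity labeling and are excluded from BioID analyses. The defaults
#' cover the endogenously biotinylated human carboxylase subunits; pass a
#' modified vector to [enrichment_filter()] to edit the list.
#'
#' @return character vector of gene symbols.
#' @export
carboxylase_exclusions <- function() {
  c("PC", "PCCA", "PCCB", "MCCC1", "MCCC2", "ACACA", "ACACB")
}

#' Call enriched interactors from a spectral-count table
#'
#' A protein isoform is retained when (i) its bait unique-peptide counts
#' satisfy the peptide rule — at least `min_unique_peptides` in some bait
#' replicate (`"any-replicate"`) or in every bait replicate
#' (`"each-replicate"`) — and (ii) its bait count statistic is at least
#' `min_fold` times the control statistic, where the statistic is either the
#' total (`"total"`) or the replicate-average (`"replicate-average"`) of
#' total spectral counts. Fold comparisons are inclusive (`>=`). When the
#' control statistic is zero and the bait statistic is positive the fold
#' test passes with an infinite-enrichment flag (set `pseudocount = 0.5`
#' for a pseudocount alternative). Exclusion-list genes are removed, and
#' isoforms are collapsed to gene level: a gene is a hit when at least one
#' of its isoforms passes.
#'
#' @param table a `"spectral_count_table"`.
#' @param min_unique_peptides peptide floor (default 2).
#' @param min_fold minimum bait/control fold enrichment (default 3).
#' @param peptide_rule `"any-replicate"` or `"each-replicate"`.
#' @param count_rule `"total"` or `"replicate-average"`.
#' @param exclusions gene symbols removed before filtering (default the
#'   carboxylase list; use `character(0)` for co-IP experiments).
#' @param pseudocount added to both count statistics before the fold test
#'   (default 0, i.e. infinite-enrichment handling).
#' @param isoform_group `"gene"` (collapse by gene symbol, default) or
#'   `"accession-prefix"` (collapse by accession with any `-n` isoform
#'   suffix removed).
#' @param experiment experiment identifier stored in the result.
#' @return an object of class `"interactor_set"`: `experiment`, `genes`
#'   (sorted gene-level hits) and `evidence` (one row per hit with the best
#'   isoform's accession, peptides, count statistics, fold enrichment and
#'   infinite-enrichment flag).
#' @export
enrichment_filter <- function(table, min_unique_peptides = 2L, min_fold = 3,
                              peptide_rule = c("any-replicate",
                                               "each-replicate"),
                              count_rule = c("total", "replicate-average"),
                              exclusions = carboxylase_exclusions(),
                              pseudocount = 0,
                              isoform_group = c("gene", "accession-prefix"),
                              experiment = "experiment") {
  stopifnot(inherits(table, "spectral_count_table"))
  peptide_rule <- match.arg(peptide_rule)
  count_rule <- match.arg(count_rule)
  isoform_group <- match.arg(isoform_group)
  if (min_unique_peptides < 1L) stop("min_unique_peptides must be >= 1",
                                     call. = FALSE)
  if (min_fold <= 0) stop("min_fold must be > 0", call. = FALSE)
  if (length(table$accession) == 0L) {
    warning("empty spectral-count table; returning empty interactor set")
    return(structure(list(experiment = experiment, genes = character(0),
                          evidence = data.frame()),
                     class = "interactor_set"))
  }
  bait <- table$roles$sample[table$roles$role == "bait"]
  ctrl <- table$roles$sample[table$roles$role == "control"]
  pep_b <- table$peptides[, bait, drop = FALSE]
  pep_ok <- if (peptide_rule == "any-replicate") {
    apply(pep_b, 1L, max) >= min_unique_peptides
  } else {
    apply(pep_b, 1L, min) >= min_unique_peptides
  }
  stat <- function(m) {
    if (count_rule == "total") rowSums(m) else rowMeans(m)
  }
  bait_stat <- stat(table$counts[, bait, drop = FALSE])
  ctrl_stat <- stat(table$counts[, ctrl, drop = FALSE])
  if (pseudocount > 0) {
    fold <- (bait_stat + pseudocount) / (ctrl_stat + pseudocount)
    infinite <- rep(FALSE, length(fold))
    fold_ok <- fold >= min_fold
  } else {
    infinite <- ctrl_stat == 0 & bait_stat > 0
    fold <- ifelse(ctrl_stat > 0, bait_stat / ctrl_stat,
                   ifelse(bait_stat > 0, Inf, 0))
    fold_ok <- infinite | (ctrl_stat > 0 & bait_stat >= min_fold * ctrl_stat)
  }
  excluded <- table$gene %in% exclusions
  pass <- pep_ok & fold_ok & !excluded

  group <- switch(isoform_group,
                  "gene" = table$gene,
                  "accession-prefix" = sub("-[0-9]+$", "", table$accession))
  hit_groups <- unique(group[pass])
  if (length(hit_groups) == 0L) {
    return(structure(list(experiment = experiment, genes = character(0),
                          evidence = data.frame()),
                     class = "interactor_set"))
  }
  evidence <- do.call(rbind, lapply(hit_groups, function(g) {
    idx <- which(group == g & pass)
    best <- idx[which.max(fold[idx])]
    data.frame(gene = table$gene[best],
               accession = table$accession[best],
               n_isoforms = sum(group == g),
               n_isoforms_passing = length(idx),
               max_bait_peptides = max(pep_b[best, ]),
               bait_counts = bait_stat[best],
               control_counts = ctrl_stat[best],
               fold_enrichment = fold[best],
               infinite_enrichment = infinite[best],
               stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(evidence$gene))
  evidence <- evidence[order(evidence$gene), , drop = FALSE]
  rownames(evidence) <- NULL
  structure(list(experiment = experiment, genes = genes,
                 evidence = evidence),
            class = "interactor_set")
}

#' @export
print.interactor_set <- function(x, ...) {
  cat("Interactor set '", x$experiment, "': ", length(x$genes),
      " gene-level hits\n", sep = "")
  invisible(x)
}

#' Intersect interactor sets across experiments
#'
#' Computes the gene-level intersection of two or more experiments and the
#' cardinality of every exclusive Venn region.
#'
#' @param sets list of `"interactor_set"` objects (or plain character
#'   vectors of genes), length >= 2; names (or experiment ids) label the
#'   sets.
#' @return a list with `set_names`, `common` (genes in every set) and
#'   `regions`, a named integer vector over membership patterns (e.g. for
#'   three sets, `"110"` counts genes in the first two sets only).
#' @export
intersect_experiments <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  genes_by_set <- lapply(sets, function(s) {
    if (inherits(s, "interactor_set")) unique(s$genes)
    else unique(as.character(s))
  })
  nm <- names(sets)
  if (is.null(nm)) nm <- rep("", length(sets))
  for (i in seq_along(sets)) {
    if (nm[i] == "") {
      nm[i] <- if (inherits(sets[[i]], "interactor_set"))
        sets[[i]]$experiment else paste0("set", i)
    }
  }
  names(genes_by_set) <- nm
  universe <- unique(unlist(genes_by_set))
  member <- vapply(genes_by_set, function(g) universe %in% g,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  patterns <- apply(member, 1L, function(r) paste(as.integer(r),
                                                  collapse = ""))
  all_patterns <- apply(as.matrix(expand.grid(
    rep(list(c(1L, 0L)), length(sets)))), 1L,
    paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", length(sets)))
  regions <- vapply(all_patterns, function(p) sum(patterns == p), 0L)
  common <- sort(universe[rowSums(member) == length(sets)])
  list(set_names = nm, common = common, regions = regions,
       per_set_sizes = vapply(genes_by_set, length, 0L))
}
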