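#' Parse a Newick string into a rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' an ape `"phylo"` object with branch lengths in the units of the input
#' (time-calibrated trees are interpreted as absolute time, e.g. millions of
#' years; all model rates in this package are per unit branch length).
#' Unlabeled internal nodes receive stable generated ids `n1, n2, ...` in
#' ape's internal node numbering order. Any root edge length present in the
#' Newick string is carried along but ignored by the likelihood machinery:
#' the loss models condition on the state at the crown root.
#'
#' @param text a Newick string (branch lengths required for model fitting).
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_parentheses(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string: could not be parsed", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length in Newick input", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$node.label) || all(tree$node.label == "")) {
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  }
  tree
}

# Balanced-parenthesis pre-check so parse errors can name an offset.
.check_parentheses <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at character ", i,
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a phylogeny as a Newick string
#'
#' Branch lengths are written with enough significant digits that a
#' parse -> write -> parse round trip preserves topology, labels and lengths
#' to at least 12 significant digits.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to `file`.
#' @export
write_newick <- function(tree, file = NULL, digits = 14) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Restrict a phylogeny to a set of taxa
#'
#' Drops all other tips and suppresses the resulting degree-2 nodes, summing
#' their branch lengths, so root-to-tip path lengths and all pairwise
#' patristic distances among the retained taxa are unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) < 2L) {
    stop("at least 2 taxa must be retained", call. = FALSE)
  }
  ape::keep.tip(tree, taxa)
}

#' Construct a binary trait matrix
#'
#' Species-by-gene presence/absence data: 1 = present, 0 = absent,
#' `NA` = missing (unobserved, not absent). Missing states enter model
#' likelihoods as all-ones partial likelihoods.
#'
#' @param x a matrix coercible to integer with entries in `{0, 1, NA}`;
#'   rownames are species, colnames are genes.
#' @return an object of class `"trait_matrix"`.
#' @export
trait_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("trait matrix needs species rownames and gene colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate species labels", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate gene labels", call. = FALSE)
  }
  bad <- !(x %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("trait values must be 0, 1 or NA", call. = FALSE)
  structure(x, class = c("trait_matrix", "matrix"))
}

#' Read a species-by-gene presence/absence table
#'
#' Expects a header row of gene names and a first column of species labels.
#' Cell tokens are configurable; by default `1` = present, `0` = absent and
#' `?` = missing. Missing means unobserved, never absent.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (tab by default).
#' @param present,absent,missing tokens for the three states.
#' @return a `"trait_matrix"` with attribute `"tallies"`, a per-gene count
#'   of present/absent/missing cells.
#' @export
read_trait_matrix <- function(file, sep = "\t",
                              present = "1", absent = "0", missing = "?") {
  raw <- utils::read.table(file, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE)
  species <- raw[[1L]]
  if (anyDuplicated(species)) {
    stop("duplicate species row(s): ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(vals) <- species
  out <- matrix(NA_integer_, nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  out[vals == present] <- 1L
  out[vals == absent] <- 0L
  unknown <- matrix(!(vals %in% c(present, absent, missing)),
                    nrow(vals), ncol(vals))
  if (any(unknown)) {
    idx <- which(unknown, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary token '%s' at species '%s', gene '%s'",
                 vals[idx[1L], idx[2L]], rownames(vals)[idx[1L]],
                 colnames(vals)[idx[2L]]), call. = FALSE)
  }
  tm <- trait_matrix(out)
  tallies <- t(apply(out, 2L, function(g) {
    c(present = sum(g == 1L, na.rm = TRUE),
      absent = sum(g == 0L, na.rm = TRUE),
      missing = sum(is.na(g)))
  }))
  attr(tm, "tallies") <- tallies
  tm
}

#' Write a trait matrix as delimited text
#'
#' @param tm a `"trait_matrix"`.
#' @param file output path.
#' @param sep field separator.
#' @param missing token used for `NA` cells.
#' @export
write_trait_matrix <- function(tm, file, sep = "\t", missing = "?") {
  stopifnot(inherits(tm, "trait_matrix"))
  chr <- matrix(as.character(unclass(tm)), nrow(tm), ncol(tm),
                dimnames = dimnames(tm))
  chr[is.na(chr)] <- missing
  df <- data.frame(species = rownames(tm), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix:", nrow(x), "species x", ncol(x), "genes\n")
  t <- attr(x, "tallies")
  if (!is.null(t)) {
    cat("Per-gene tallies (present/absent/missing):\n")
    print(t)
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Construct a branch-length table
#'
#' Holds per-gene branch lengths on a fixed species-tree branch index,
#' together with a positive reference (genome-average) length per branch.
#' Branch-specific relative rates are the per-gene lengths divided by the
#' reference.
#'
#' @param branch_ids character vector of branch identifiers.
#' @param reference positive numeric reference length per branch.
#' @param gene_lengths numeric matrix, branches x genes; `NA` allowed,
#'   non-missing entries must be `>= 0`.
#' @return an object of class `"branch_length_table"`.
#' @export
branch_length_table <- function(branch_ids, reference, gene_lengths) {
  branch_ids <- as.character(branch_ids)
  reference <- as.numeric(reference)
  gene_lengths <- as.matrix(gene_lengths)
  stopifnot(length(branch_ids) == length(reference),
            nrow(gene_lengths) == length(branch_ids))
  if (anyDuplicated(branch_ids)) stop("duplicate branch ids", call. = FALSE)
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference branch lengths must all be positive", call. = FALSE)
  }
  if (any(gene_lengths < 0, na.rm = TRUE)) {
    stop("gene branch lengths must be >= 0 where present", call. = FALSE)
  }
  if (is.null(colnames(gene_lengths))) {
    stop("gene_lengths needs gene colnames", call. = FALSE)
  }
  rownames(gene_lengths) <- branch_ids
  structure(list(branch_ids = branch_ids, reference = reference,
                 gene_lengths = gene_lengths),
            class = "branch_length_table")
}

#' Read a branch-length table from TSV
#'
#' One row per branch; first column is the branch id, a `reference` column
#' holds the genome-average length, and every remaining column is one gene.
#' Empty cells or `NA` mark branches missing for a gene.
#'
#' @param file path to a TSV file.
#' @param sep field separator.
#' @return a `"branch_length_table"`.
#' @export
read_branch_length_table <- function(file, sep = "\t") {
  raw <- utils::read.table(file, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!("reference" %in% colnames(raw))) {
    stop("branch-length table must have a 'reference' column", call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  genes <- setdiff(colnames(raw)[-1L], "reference")
  branch_length_table(ids, raw[["reference"]],
                      as.matrix(raw[, genes, drop = FALSE]))
}

#' Write a branch-length table as TSV
#'
#' @param blt a `"branch_length_table"`.
#' @param file output path.
#' @export
write_branch_length_table <- function(blt, file) {
  stopifnot(inherits(blt, "branch_length_table"))
  df <- data.frame(branch_id = blt$branch_ids, reference = blt$reference,
                   blt$gene_lengths, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.branch_length_table <- function(x, ...) {
  cat("Branch-length table:", length(x$branch_ids), "branches x",
      ncol(x$gene_lengths), "genes\n")
  invisible(x)
}
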