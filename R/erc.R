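# Evolutionary rate covariation: branch-specific relative rates, pairwise
# correlations, pathway means and the permutation null.

#' Branch-specific relative evolutionary rates
#'
#' Converts a branch-length table into per-gene rate profiles:
#' `rate(g, b) = gene_length(g, b) / reference_length(b)`, then each gene's
#' profile is mean-centered and unit-scaled over its own non-missing
#' branches. Standardization makes the downstream correlation invariant to
#' per-gene scale (doubling a gene's branch lengths leaves its profile
#' unchanged). Profiles with fewer than `min_branches` non-missing entries
#' are dropped with a warning, as are profiles with zero rate variance.
#'
#' @param table a [branch_length_table()].
#' @param min_branches minimum number of non-missing branches a profile must
#'   have to be retained (default 10).
#' @param standardize center and scale each profile (default `TRUE`; raw
#'   ratios are returned otherwise, e.g. for rank-based correlation).
#' @return an object of class `"rate_profile_set"`: a list with
#'   `branch_ids` and `profiles` (branches x genes matrix, `NA` = missing).
#' @export
relative_rates <- function(table, min_branches = 10L, standardize = TRUE) {
  stopifnot(inherits(table, "branch_length_table"))
  rates <- table$gene_lengths / table$reference
  keep <- colSums(!is.na(rates)) >= min_branches
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " profile(s) with < ", min_branches,
            " non-missing branches: ",
            paste(colnames(rates)[!keep], collapse = ", "))
    rates <- rates[, keep, drop = FALSE]
  }
  if (ncol(rates) == 0L) stop("no usable rate profiles", call. = FALSE)
  if (standardize) {
    sds <- apply(rates, 2L, stats::sd, na.rm = TRUE)
    flat <- !is.na(sds) & sds == 0
    if (any(flat)) {
      warning("dropping ", sum(flat), " zero-variance profile(s): ",
              paste(colnames(rates)[flat], collapse = ", "))
      rates <- rates[, !flat, drop = FALSE]
    }
    rates <- scale(rates)
    attr(rates, "scaled:center") <- NULL
    attr(rates, "scaled:scale") <- NULL
  }
  structure(list(branch_ids = table$branch_ids, profiles = rates),
            class = "rate_profile_set")
}

#' @export
print.rate_profile_set <- function(x, ...) {
  cat("Rate profiles:", ncol(x$profiles), "genes over",
      length(x$branch_ids), "branches\n")
  invisible(x)
}

#' Pairwise evolutionary rate covariation
#'
#' ERC between two genes is the correlation coefficient of their
#' branch-specific relative rates over the branches where both are observed.
#' Undefined (returned as `NA` with a warning) when fewer than 3 branches
#' are shared or a profile has zero variance on the shared branches.
#'
#' @param a,b numeric rate profiles over the same branch index
#'   (`NA` = missing).
#' @param method `"pearson"` (default) or `"spearman"` for a rank-based
#'   alternative.
#' @return the correlation, with attribute `"n_shared"` (shared branch
#'   count).
#' @export
erc_pair <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  shared <- !is.na(a) & !is.na(b)
  n <- sum(shared)
  if (n < 3L) {
    warning("fewer than 3 shared branches; ERC undefined")
    return(structure(NA_real_, n_shared = n))
  }
  if (stats::sd(a[shared]) == 0 || stats::sd(b[shared]) == 0) {
    warning("zero variance on shared branches; ERC undefined")
    return(structure(NA_real_, n_shared = n))
  }
  structure(stats::cor(a[shared], b[shared], method = method), n_shared = n)
}

#' All-pairs ERC matrix
#'
#' @param profiles a `"rate_profile_set"`.
#' @param method correlation method, as in [erc_pair()].
#' @return an object of class `"erc_matrix"`: a list with `values`
#'   (symmetric correlation matrix, unit diagonal, `NA` where undefined) and
#'   `n_shared` (shared-branch counts per cell).
#' @export
erc_matrix <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles, "rate_profile_set"))
  m <- profiles$profiles
  vals <- suppressWarnings(
    stats::cor(m, use = "pairwise.complete.obs", method = method))
  n_shared <- crossprod(!is.na(m))
  vals[n_shared < 3L] <- NA_real_
  diag(vals) <- 1
  vals <- (vals + t(vals)) / 2  # enforce exact symmetry
  structure(list(values = vals, n_shared = n_shared), class = "erc_matrix")
}

#' @export
print.erc_matrix <- function(x, ...) {
  cat("ERC matrix over", ncol(x$values), "genes\n")
  invisible(x)
}

#' Mean ERC between a focal gene and a gene set
#'
#' The pathway-level statistic: the arithmetic mean of the defined pairwise
#' ERC values between the focal gene and each member of the set.
#'
#' @param focal focal gene label (must not be in `geneset`).
#' @param geneset nonempty character vector of gene labels.
#' @param m an `"erc_matrix"`.
#' @return a list with `mean_erc` and `n_genes` (number of contributing,
#'   non-missing pairs).
#' @export
group_mean_erc <- function(focal, geneset, m) {
  stopifnot(inherits(m, "erc_matrix"), length(geneset) >= 1L)
  if (focal %in% geneset) stop("focal gene must not be in the gene set",
                               call. = FALSE)
  labs <- colnames(m$values)
  if (!(focal %in% labs)) stop("focal gene not in ERC matrix", call. = FALSE)
  absent <- setdiff(geneset, labs)
  if (length(absent)) stop("gene-set members not in ERC matrix: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  v <- m$values[focal, geneset]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no defined ERC values between focal gene and gene set",
         call. = FALSE)
  }
  list(mean_erc = mean(v), n_genes = length(v))
}

#' Permutation test for pathway-mean ERC
#'
#' The observed statistic is the mean ERC between the focal gene and the
#' gene set. The null is built by repeatedly substituting a random focal
#' gene, drawn with replacement from the background pool (all profiled genes
#' excluding the focal gene and the gene set), and recomputing the set-mean
#' ERC. The reported p-value is the fraction of null means at least as large
#' as the observed one (ties count toward the numerator); a bias-corrected
#' `(k + 1) / (N + 1)` version is reported alongside.
#'
#' @param focal focal gene label.
#' @param geneset character vector of pathway gene labels.
#' @param profiles a `"rate_profile_set"` containing focal, gene set and
#'   background genes.
#' @param N number of permutation draws (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed integer seed making the draws reproducible.
#' @param method correlation method, as in [erc_pair()].
#' @return an object of class `"erc_permutation"`: `observed_mean_erc`,
#'   `null_means`, `p_value`, `p_value_corrected`, `seed`, `pool_size`,
#'   `n_draws`, `n_genes`.
#' @export
permutation_pvalue <- function(focal, geneset, profiles, N = 10000L,
                               seed = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles, "rate_profile_set"), N >= 1L)
  if (N < 100L) warning("N < 100 permutation draws gives a coarse p-value")
  genes <- colnames(profiles$profiles)
  if (!(focal %in% genes)) stop("focal gene not profiled", call. = FALSE)
  absent <- setdiff(geneset, genes)
  if (length(absent)) stop("gene-set members not profiled: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  pool <- setdiff(genes, c(focal, geneset))
  if (length(pool) < 1L) stop("background pool is empty", call. = FALSE)

  m <- profiles$profiles
  # correlations of every candidate focal gene against the gene set only
  cand <- c(focal, pool)
  cc <- suppressWarnings(
    stats::cor(m[, cand, drop = FALSE], m[, geneset, drop = FALSE],
               use = "pairwise.complete.obs", method = method))
  shared <- crossprod(!is.na(m[, cand, drop = FALSE]),
                      !is.na(m[, geneset, drop = FALSE]))
  cc[shared < 3L] <- NA_real_
  set_means <- rowMeans(cc, na.rm = TRUE)
  observed <- set_means[[focal]]
  if (is.nan(observed)) {
    stop("no defined ERC values between focal gene and gene set",
         call. = FALSE)
  }
  pool_means <- set_means[pool]
  pool_means <- pool_means[!is.nan(pool_means)]
  if (length(pool_means) == 0L) stop("background pool has no defined means",
                                     call. = FALSE)
  draws <- .with_seed(seed,
                      sample(pool_means, size = N, replace = TRUE))
  k <- sum(draws >= observed)
  structure(list(observed_mean_erc = observed,
                 null_means = unname(draws),
                 p_value = k / N,
                 p_value_corrected = (k + 1) / (N + 1),
                 seed = seed, pool_size = length(pool_means),
                 n_draws = N,
                 n_genes = sum(!is.na(cc[focal, ]))),
            class = "erc_permutation")
}

#' @export
print.erc_permutation <- function(x, ...) {
  cat(sprintf("Pathway-mean ERC permutation test (%d draws, pool %d)\n",
              x$n_draws, x$pool_size))
  cat(sprintf("  observed mean ERC = %.4f over %d genes\n",
              x$observed_mean_erc, x$n_genes))
  cat(sprintf("  p = %.4g (bias-corrected %.4g)\n",
              x$p_value, x$p_value_corrected))
  invisible(x)
}
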