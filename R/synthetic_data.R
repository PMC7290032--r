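# Seeded generators for every input the pipeline consumes: pure-birth
# trees, paired loss traits, correlated branch rates, spectral counts.
# All generators are pure functions of their arguments plus the seed.

#' Simulate a Yule (pure-birth) tree
#'
#' Lineages split at rate `birth_rate` each; the process starts from two
#' crown lineages and stops one exponential waiting time after the
#' `n_tips`-th lineage appears, so the expected tree depth is
#' `sum(1 / (birth_rate * k))` for `k = 2, ..., n_tips`. The result is a
#' rooted, ultrametric, binary `"phylo"` tree with tips `t1, ..., tn`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return a `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2L, birth_rate > 0)
  .with_seed(seed, {
    n <- as.integer(n_tips)
    # lineage records: parent internal node id, start time
    par <- c(n + 1L, n + 1L)
    start <- c(0, 0)
    next_node <- n + 2L
    t <- 0
    ep <- integer(0); ec <- integer(0); el <- numeric(0)
    k <- 2L
    while (k < n) {
      t <- t + stats::rexp(1L, birth_rate * k)
      i <- sample.int(k, 1L)
      m <- next_node; next_node <- next_node + 1L
      ep <- c(ep, par[i]); ec <- c(ec, m); el <- c(el, t - start[i])
      par <- c(par[-i], m, m)
      start <- c(start[-i], t, t)
      k <- k + 1L
    }
    t <- t + stats::rexp(1L, birth_rate * n)
    ep <- c(ep, par); ec <- c(ec, seq_len(n)); el <- c(el, t - start)
    tree <- structure(list(edge = cbind(ep, ec, deparse.level = 0),
                           edge.length = el,
                           Nnode = n - 1L,
                           tip.label = paste0("t", seq_len(n))),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

# Simulate one CTMC edge: state index after time t starting from s.
.sim_ctmc_edge <- function(Q, s, t) {
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) return(s)
    w <- stats::rexp(1L, rate)
    if (w >= t) return(s)
    t <- t - w
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(ncol(Q), 1L, prob = p)
  }
}

#' Forward-simulate paired loss traits on a tree
#'
#' Draws joint presence states down the tree from an all-present root by
#' sampling exponential waiting times for the allowed loss transitions of
#' the generator along each branch. With a [pair_loss_generator()] the
#' result is a two-gene [trait_matrix()]; a [single_loss_generator()] gives
#' a one-gene matrix.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param gen a `"loss_generator"`.
#' @param seed integer seed.
#' @param genes gene labels for the trait-matrix columns.
#' @return a `"trait_matrix"` of tip states.
#' @export
simulate_trait_pair <- function(tree, gen, seed = NULL,
                                genes = c("gene1", "gene2")) {
  stopifnot(inherits(tree, "phylo"), inherits(gen, "loss_generator"))
  .with_seed(seed, {
    post <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(post$tip.label)
    root <- n_tip + 1L
    root_state <- if (gen$kind == "independent-single") 1L else 4L
    state <- integer(n_tip + post$Nnode)
    state[root] <- root_state
    edges <- nrow(post$edge):1L  # reverse postorder = parents first
    for (i in edges) {
      p <- post$edge[i, 1L]
      c <- post$edge[i, 2L]
      state[c] <- .sim_ctmc_edge(gen$Q, state[p], post$edge.length[i])
    }
    tips <- state[seq_len(n_tip)]
    if (gen$kind == "independent-single") {
      m <- cbind(ifelse(tips == 1L, 1L, 0L))
      colnames(m) <- genes[1L]
    } else {
      lab <- gen$states[tips]  # "00","01","10","11"
      m <- cbind(as.integer(substr(lab, 1L, 1L)),
                 as.integer(substr(lab, 2L, 2L)))
      colnames(m) <- genes[1:2]
    }
    rownames(m) <- post$tip.label
    trait_matrix(m[tree$tip.label, , drop = FALSE])
  })
}

#' Simulate correlated branch-specific rates
#'
#' Builds a [branch_length_table()] whose genes carry log-normal
#' multiplicative rate noise around positive reference branch lengths.
#' Genes in `correlated_block` load on a shared per-branch latent factor so
#' that every within-block pair has log-rate correlation `rho`; all other
#' genes are independent. This is the rate structure that evolutionary rate
#' covariation is designed to detect.
#'
#' @param n_branches number of branches (>= 3).
#' @param genes character vector of gene labels.
#' @param correlated_block subset of `genes` sharing the latent factor.
#' @param rho within-block pairwise correlation of log rates, in `[0, 1]`
#'   (mutual negative correlation across a block has no common-factor
#'   representation).
#' @param seed integer seed.
#' @param rate_noise_sd standard deviation of the log-rate noise.
#' @param reference_meanlog,reference_sdlog log-normal parameters of the
#'   reference branch lengths.
#' @return a `"branch_length_table"`.
#' @export
simulate_branch_rates <- function(n_branches, genes,
                                  correlated_block = character(0),
                                  rho = 0, seed = NULL,
                                  rate_noise_sd = 0.3,
                                  reference_meanlog = 0,
                                  reference_sdlog = 0.5) {
  stopifnot(n_branches >= 3L, length(genes) >= 1L)
  if (!is.numeric(rho) || rho < -1 || rho > 1) {
    stop("rho must lie in [-1, 1]", call. = FALSE)
  }
  if (rho < 0) {
    stop("a shared-factor block cannot represent mutual negative ",
         "correlation; rho must be in [0, 1]", call. = FALSE)
  }
  absent <- setdiff(correlated_block, genes)
  if (length(absent)) stop("correlated_block members not in genes: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  .with_seed(seed, {
    reference <- stats::rlnorm(n_branches, reference_meanlog,
                               reference_sdlog)
    z <- stats::rnorm(n_branches)  # shared latent factor
    logmult <- sapply(genes, function(g) {
      eps <- stats::rnorm(n_branches)
      if (g %in% correlated_block) {
        rate_noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * eps)
      } else {
        rate_noise_sd * eps
      }
    })
    gene_lengths <- reference * exp(logmult)
    colnames(gene_lengths) <- genes
    branch_length_table(paste0("b", seq_len(n_branches)), reference,
                        gene_lengths)
  })
}

#' Simulate a spectral-count table with known true interactors
#'
#' Control counts follow a negative-binomial background around per-protein
#' log-normal baselines (overdispersion is the norm for spectral counting);
#' bait counts for a designated subset of true interactors are scaled by
#' `fold_change`. Unique-peptide counts grow with spectral counts, and
#' technical replicates are drawn independently. Truth labels are returned
#' for benchmarking [enrichment_filter()].
#'
#' @param cfg list with fields `n_proteins`, `n_true_interactors`,
#'   `fold_change` (> 1), `background_dispersion` (negative-binomial
#'   dispersion, default 0.5), `n_replicates` (default 2), `baseline_mean`
#'   (mean control count, default 10) and `seed`. Missing fields take the
#'   defaults.
#' @return a list with `table` (a `"spectral_count_table"`) and `truth`
#'   (gene symbols of the true interactors).
#' @export
simulate_spectral_counts <- function(cfg = list()) {
  d <- list(n_proteins = 200L, n_true_interactors = 10L, fold_change = 10,
            background_dispersion = 0.5, n_replicates = 2L,
            baseline_mean = 10, seed = NULL)
  d[names(cfg)] <- cfg
  stopifnot(d$n_proteins >= 1L,
            d$n_true_interactors >= 0L,
            d$n_true_interactors <= d$n_proteins,
            d$background_dispersion > 0, d$n_replicates >= 1L)
  if (d$n_true_interactors > 0L && d$fold_change <= 1) {
    stop("fold_change must be > 1 for true interactors", call. = FALSE)
  }
  .with_seed(d$seed, {
    n <- as.integer(d$n_proteins)
    gene <- sprintf("G%04d", seq_len(n))
    accession <- sprintf("SP%04d", seq_len(n))
    truth_idx <- sample.int(n, d$n_true_interactors)
    mu <- stats::rlnorm(n, log(d$baseline_mean), 0.7)
    size <- 1 / d$background_dispersion
    samples <- c(paste0("bait_r", seq_len(d$n_replicates)),
                 paste0("ctrl_r", seq_len(d$n_replicates)))
    counts <- matrix(0L, n, length(samples),
                     dimnames = list(NULL, samples))
    mu_bait <- mu
    mu_bait[truth_idx] <- mu[truth_idx] * d$fold_change
    for (r in seq_len(d$n_replicates)) {
      counts[, paste0("bait_r", r)] <- stats::rnbinom(n, size = size,
                                                      mu = mu_bait)
      counts[, paste0("ctrl_r", r)] <- stats::rnbinom(n, size = size,
                                                      mu = mu)
    }
    peptides <- matrix(0L, n, length(samples),
                       dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      sc <- counts[, j]
      peptides[, j] <- ifelse(sc > 0L,
                              pmin(sc, 1L + stats::rpois(n, sc / 3)),
                              0L)
    }
    roles <- data.frame(
      sample = samples,
      role = rep(c("bait", "control"), each = d$n_replicates),
      replicate = rep(seq_len(d$n_replicates), 2L),
      stringsAsFactors = FALSE)
    list(table = spectral_count_table(accession, gene, peptides, counts,
                                      roles),
         truth = sort(gene[truth_idx]))
  })
}
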