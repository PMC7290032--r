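# Independent oracles and small generators used across the suite.

# Brute-force likelihood: sum over every assignment of states to the free
# internal nodes (root fixed), with transition matrices from Matrix::expm —
# a route fully independent of the package's pruning kernel.
brute_force_loglik <- function(tree, partials, Q, root_state) {
  tree <- ape::reorder.phylo(tree, "postorder")
  k <- ncol(Q)
  n <- length(tree$tip.label)
  Plist <- lapply(seq_len(nrow(tree$edge)), function(i) {
    as.matrix(Matrix::expm(Q * tree$edge.length[i]))
  })
  free <- setdiff((n + 1L):(n + tree$Nnode), n + 1L)
  grid <- if (length(free)) {
    as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  } else {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  }
  total <- 0
  for (r in seq_len(nrow(grid))) {
    s <- integer(n + tree$Nnode)
    s[n + 1L] <- root_state
    if (length(free)) s[free] <- grid[r, ]
    p <- 1
    for (i in seq_len(nrow(tree$edge))) {
      a <- tree$edge[i, 1L]
      b <- tree$edge[i, 2L]
      p <- p * if (b <= n) {
        sum(Plist[[i]][s[a], ] * partials[b, ])
      } else {
        Plist[[i]][s[a], s[b]]
      }
    }
    total <- total + p
  }
  log(total)
}

random_pair_generator <- function() {
  do.call(pair_loss_generator, as.list(stats::runif(4, 0.05, 2)) |>
            stats::setNames(c("q42", "q43", "q31", "q21")))
}

# Random tip states for a pair of genes, with optional missingness.
random_pair_states <- function(tree, p_missing = 0.1) {
  n <- length(tree$tip.label)
  m <- matrix(sample(0:1, 2L * n, replace = TRUE), n, 2L,
              dimnames = list(tree$tip.label, c("gene1", "gene2")))
  miss <- matrix(stats::runif(2L * n) < p_missing, n, 2L)
  m[miss] <- NA_integer_
  m
}

# Map independent-model rates onto the dependent parameterization.
independent_as_dependent_start <- function(beta1, beta2, floor = 1e-9) {
  c(q42 = max(beta1, floor), q43 = max(beta2, floor),
    q31 = max(beta1, floor), q21 = max(beta2, floor))
}
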