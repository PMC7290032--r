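#' @useDynLib genecoev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- loss generators --------------------------------------------------------

#' Irreversible single-trait loss generator
#'
#' Two-state continuous-time Markov chain over `{present, absent}` with loss
#' rate `beta` (per unit branch length) and gain rate fixed at zero, so the
#' absent state is absorbing. This is the per-gene building block of the
#' independent model of paired gene loss.
#'
#' @param beta non-negative loss rate.
#' @return an object of class `"loss_generator"`.
#' @examples
#' g <- single_loss_generator(1)
#' transition_matrix(g, log(2))["present", "present"]  # 0.5
#' @export
single_loss_generator <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta < 0) stop("loss rate must be >= 0", call. = FALSE)
  Q <- matrix(c(-beta, beta,
                0,     0), 2L, 2L, byrow = TRUE,
              dimnames = list(c("present", "absent"),
                              c("present", "absent")))
  structure(list(kind = "independent-single",
                 rates = c(beta = beta), Q = Q,
                 states = c("present", "absent")),
            class = "loss_generator")
}

#' Irreversible paired-trait loss generator
#'
#' Four-state chain over the joint presence states of two genes, in the
#' conventional ordering 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1) where the
#' pair is (gene1, gene2). The four free loss rates are
#' \describe{
#'   \item{q42}{loss of gene 1 while gene 2 is present, (1,1) -> (0,1)}
#'   \item{q43}{loss of gene 2 while gene 1 is present, (1,1) -> (1,0)}
#'   \item{q31}{loss of gene 1 while gene 2 is absent, (1,0) -> (0,0)}
#'   \item{q21}{loss of gene 2 while gene 1 is absent, (0,1) -> (0,0)}
#' }
#' All gain rates (q12, q13, q24, q34) are identically zero, so (0,0) is
#' absorbing. When `q42 = q31` and `q43 = q21` the chain factorizes into two
#' independent single-trait loss chains.
#'
#' @param q42,q43,q31,q21 non-negative loss rates, per unit branch length.
#' @return an object of class `"loss_generator"`.
#' @export
pair_loss_generator <- function(q42, q43, q31, q21) {
  r <- c(q42 = q42, q43 = q43, q31 = q31, q21 = q21)
  stopifnot(all(is.finite(r)))
  if (any(r < 0)) stop("loss rates must be >= 0", call. = FALSE)
  states <- c("00", "01", "10", "11")
  Q <- matrix(0, 4L, 4L, dimnames = list(states, states))
  Q["11", "01"] <- q42
  Q["11", "10"] <- q43
  Q["10", "00"] <- q31
  Q["01", "00"] <- q21
  diag(Q) <- -rowSums(Q)
  structure(list(kind = "dependent-pair", rates = r, Q = Q, states = states),
            class = "loss_generator")
}

#' @export
print.loss_generator <- function(x, ...) {
  cat("Loss generator (", x$kind, ")\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' Transition probability matrix of a loss generator
#'
#' `P(t) = exp(Qt)` computed by scaling-and-squaring matrix exponential.
#'
#' @param gen a `"loss_generator"`.
#' @param t non-negative elapsed time (branch length).
#' @return a row-stochastic matrix with the generator's state labels.
#' @export
transition_matrix <- function(gen, t) {
  stopifnot(inherits(gen, "loss_generator"), is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t < 0) stop("t must be a non-negative real",
                                   call. = FALSE)
  P <- ctmc_transition_cpp(gen$Q, t)
  dimnames(P) <- dimnames(gen$Q)
  P
}

# ---- tip partial likelihoods ------------------------------------------------

# Single trait: values in {1, 0, NA}; rows over states (present, absent).
.partials_single <- function(states) {
  n <- length(states)
  p <- matrix(1, n, 2L)
  p[which(states == 1L), 2L] <- 0
  p[which(states == 0L), 1L] <- 0
  p
}

# Pair: g1, g2 in {1, 0, NA}; columns over joint states 00, 01, 10, 11.
# A state is compatible when every observed gene matches its digit.
.partials_pair <- function(g1, g2) {
  n <- length(g1)
  s1 <- c(0L, 0L, 1L, 1L)  # gene1 digit per joint state
  s2 <- c(0L, 1L, 0L, 1L)
  p <- matrix(1, n, 4L)
  for (j in 1:4) {
    p[, j] <- ifelse(!is.na(g1) & g1 != s1[j], 0, 1) *
      ifelse(!is.na(g2) & g2 != s2[j], 0, 1)
  }
  p
}

# Postorder bookkeeping shared by likelihood calls: returns edge matrix,
# lengths and root id with tips ordered as tree$tip.label.
.postorder <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, edge_length = tree$edge.length,
       n_tip = length(tree$tip.label), n_node = tree$Nnode,
       root = length(tree$tip.label) + 1L, tip_label = tree$tip.label)
}

.loglik <- function(post, partials, Q, root_state_idx) {
  pruning_loglik_cpp(post$edge, post$edge_length, partials, post$n_node,
                     Q, post$root, root_state_idx)
}

#' Pruning log-likelihood of tip states under a loss generator
#'
#' Computes the log-probability of observed tip states given the tree, the
#' generator and a fixed root state, by the post-order conditional-likelihood
#' (pruning) recursion. Missing states (`NA`) contribute all-ones partial
#' likelihoods. Returns `-Inf` only when the data are impossible under the
#' model (e.g. a gene present at a tip descending from a lineage forced
#' absent).
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param tip_states for a single-trait generator, a vector in `{1, 0, NA}`
#'   named by tip label; for a pair generator, a 2-column matrix
#'   (gene1, gene2) with species rownames and entries in `{1, 0, NA}`.
#' @param gen a `"loss_generator"`.
#' @param root_state state label at which the root is fixed; defaults to
#'   present / both-present, the only non-degenerate choice when gains are
#'   impossible.
#' @return the log-likelihood (a non-positive real, or `-Inf`).
#' @export
pruning_loglik <- function(tree, tip_states, gen,
                           root_state = if (gen$kind == "independent-single")
                             "present" else "11") {
  stopifnot(inherits(tree, "phylo"), inherits(gen, "loss_generator"))
  if (!(root_state %in% gen$states)) {
    stop("unknown root state '", root_state, "'", call. = FALSE)
  }
  post <- .postorder(tree)
  if (gen$kind == "independent-single") {
    if (is.null(names(tip_states))) {
      stop("tip_states must be named by tip label", call. = FALSE)
    }
    miss <- setdiff(names(tip_states), post$tip_label)
    if (length(miss)) stop("tips not in tree: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    st <- tip_states[post$tip_label]
    if (any(!(st %in% c(0L, 1L, NA)))) {
      stop("unknown state token; states must be 1, 0 or NA", call. = FALSE)
    }
    partials <- .partials_single(as.integer(st))
  } else {
    tip_states <- as.matrix(tip_states)
    if (is.null(rownames(tip_states)) || ncol(tip_states) != 2L) {
      stop("pair tip_states must be a 2-column matrix with species rownames",
           call. = FALSE)
    }
    miss <- setdiff(rownames(tip_states), post$tip_label)
    if (length(miss)) stop("tips not in tree: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    m <- tip_states[post$tip_label, , drop = FALSE]
    if (any(!(m %in% c(0L, 1L, NA)))) {
      stop("unknown state token; states must be 1, 0 or NA", call. = FALSE)
    }
    partials <- .partials_pair(as.integer(m[, 1L]), as.integer(m[, 2L]))
  }
  .loglik(post, partials, gen$Q, match(root_state, gen$states))
}

# ---- model fitting ----------------------------------------------------------

#' Fitting options for the loss models
#'
#' @param restarts number of optimizer starts for the dependent model; the
#'   first start is always the independent-model estimate (which guarantees
#'   the nested likelihood ordering), the rest are seeded random draws.
#' @param seed integer seed for the random restarts (`NULL` = use the
#'   current RNG stream).
#' @param start optional named vector of rates used as the single start
#'   (for the dependent model: `q42`, `q43`, `q31`, `q21`).
#' @param lower,upper rate bounds, per unit mean branch length; rates are
#'   internally rescaled by the mean branch length for conditioning.
#' @param factr `optim` L-BFGS-B convergence control (tolerance about
#'   `factr * .Machine$double.eps` in log-likelihood units).
#' @return a list of options.
#' @export
coev_opts <- function(restarts = 25L, seed = NULL, start = NULL,
                      lower = 1e-6, upper = 1e3, factr = 1e7) {
  stopifnot(restarts >= 1L, lower > 0, upper > lower)
  list(restarts = as.integer(restarts), seed = seed, start = start,
       lower = lower, upper = upper, factr = factr)
}

# Align a trait matrix and tree for a gene pair; returns pruned postorder
# tree info plus the two integer state vectors in tip order.
.align_pair <- function(tree, traits, gene1, gene2) {
  stopifnot(inherits(traits, "trait_matrix"))
  for (g in c(gene1, gene2)) {
    if (!(g %in% colnames(traits))) {
      stop("gene '", g, "' not in trait matrix", call. = FALSE)
    }
  }
  common <- intersect(tree$tip.label, rownames(traits))
  if (length(common) < 3L) {
    stop("fewer than 3 species shared by tree and trait matrix",
         call. = FALSE)
  }
  tree <- prune_to_taxa(tree, common)
  g1 <- unclass(traits)[tree$tip.label, gene1]
  g2 <- unclass(traits)[tree$tip.label, gene2]
  if (sum(!is.na(g1)) < 3L || sum(!is.na(g2)) < 3L) {
    stop("fewer than 3 non-missing species after pruning", call. = FALSE)
  }
  list(tree = tree, post = .postorder(tree), g1 = g1, g2 = g2,
       mbl = mean(tree$edge.length))
}

# Maximize a single-trait loss likelihood over log(beta * mbl) by Brent
# search, comparing against both bounds so boundary optima are kept.
.fit_single_trait <- function(post, states, mbl, opts) {
  partials <- .partials_single(states)
  Q2 <- function(beta) matrix(c(-beta, beta, 0, 0), 2L, 2L, byrow = TRUE)
  nll <- function(lr) -.loglik(post, partials, Q2(exp(lr) / mbl), 1L)
  lo <- log(opts$lower)
  hi <- log(opts$upper)
  o <- stats::optimize(nll, c(lo, hi), tol = 1e-9)
  cand <- rbind(c(o$minimum, o$objective), c(lo, nll(lo)), c(hi, nll(hi)))
  best <- cand[which.min(cand[, 2L]), ]
  list(beta = exp(best[1L]) / mbl, logLik = -best[2L])
}

#' Fit the independent model of paired gene loss
#'
#' Two free parameters: the loss rate of gene 1 (`beta1`) and of gene 2
#' (`beta2`). Each trait evolves as an irreversible two-state loss chain with
#' the root fixed at present, and the joint log-likelihood is the sum of the
#' two single-trait log-likelihoods, each maximized by bounded Brent search.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param traits a `"trait_matrix"` containing both genes.
#' @param gene1,gene2 gene column names.
#' @param opts a [coev_opts()] list.
#' @return an object of class `"loss_fit"` with elements `model`, `rates`
#'   (`beta1`, `beta2`), `logLik`, per-trait log-likelihoods,
#'   `n_restarts_converged` and `optimizer_status`.
#' @export
fit_independent <- function(tree, traits, gene1, gene2, opts = coev_opts()) {
  al <- .align_pair(tree, traits, gene1, gene2)
  if (!is.null(opts$start)) {
    b <- opts$start
    l1 <- .loglik(al$post, .partials_single(al$g1),
                  single_loss_generator(b[["beta1"]])$Q, 1L)
    l2 <- .loglik(al$post, .partials_single(al$g2),
                  single_loss_generator(b[["beta2"]])$Q, 1L)
    f1 <- list(beta = b[["beta1"]], logLik = l1)
    f2 <- list(beta = b[["beta2"]], logLik = l2)
  } else {
    f1 <- .fit_single_trait(al$post, al$g1, al$mbl, opts)
    f2 <- .fit_single_trait(al$post, al$g2, al$mbl, opts)
  }
  structure(list(model = "independent",
                 genes = c(gene1, gene2),
                 rates = c(beta1 = f1$beta, beta2 = f2$beta),
                 logLik = f1$logLik + f2$logLik,
                 logLik_by_trait = c(f1$logLik, f2$logLik),
                 n_restarts_converged = 1L,
                 optimizer_status = "ok",
                 n_species = length(al$tree$tip.label)),
            class = "loss_fit")
}

#' Fit the dependent model of paired gene loss
#'
#' Four free parameters dividing each gene's loss rate according to the
#' presence of the other gene: `q42`, `q43` (loss of gene 1 / gene 2 while
#' the partner is present) and `q31`, `q21` (loss while the partner is
#' absent). The joint 4-state likelihood is maximized over log-rates by
#' multi-start bounded quasi-Newton (L-BFGS-B); the first start is the
#' independent-model estimate, so the fitted log-likelihood can never fall
#' below the independent one by more than optimizer tolerance.
#'
#' @inheritParams fit_independent
#' @return an object of class `"loss_fit"` with rate estimates `q42`, `q43`,
#'   `q31`, `q21`.
#' @export
fit_dependent <- function(tree, traits, gene1, gene2, opts = coev_opts()) {
  al <- .align_pair(tree, traits, gene1, gene2)
  partials <- .partials_pair(al$g1, al$g2)
  mbl <- al$mbl
  qmat <- function(r) {  # r = natural-scale rates (q42, q43, q31, q21)
    Q <- matrix(0, 4L, 4L)
    Q[4L, 2L] <- r[1L]; Q[4L, 3L] <- r[2L]
    Q[3L, 1L] <- r[3L]; Q[2L, 1L] <- r[4L]
    diag(Q) <- -rowSums(Q)
    Q
  }
  nll <- function(par) -.loglik(al$post, partials, qmat(exp(par) / mbl), 4L)
  lo <- log(opts$lower); hi <- log(opts$upper)
  clamp <- function(x) pmin(pmax(x, lo), hi)

  starts <- list()
  if (!is.null(opts$start)) {
    s <- opts$start[c("q42", "q43", "q31", "q21")]
    starts[[1L]] <- clamp(log(pmax(s, opts$lower / mbl) * mbl))
  } else {
    f1 <- .fit_single_trait(al$post, al$g1, mbl, opts)
    f2 <- .fit_single_trait(al$post, al$g2, mbl, opts)
    b <- pmax(c(f1$beta, f2$beta), opts$lower / mbl)
    starts[[1L]] <- clamp(log(c(b[1L], b[2L], b[1L], b[2L]) * mbl))
    if (opts$restarts > 1L) {
      rand <- .with_seed(opts$seed, matrix(
        stats::runif(4L * (opts$restarts - 1L), log(0.01), log(10)),
        ncol = 4L))
      for (i in seq_len(opts$restarts - 1L)) starts[[i + 1L]] <- rand[i, ]
    }
  }

  best <- NULL
  conv <- 0L
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = opts$factr, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0L) conv <- conv + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("dependent-model optimization failed from every start",
                          call. = FALSE)
  status <- if (conv > 0L) "ok" else "no-start-converged"
  rates <- exp(best$par) / mbl
  names(rates) <- c("q42", "q43", "q31", "q21")
  structure(list(model = "dependent",
                 genes = c(gene1, gene2),
                 rates = rates,
                 logLik = -best$value,
                 n_restarts_converged = conv,
                 optimizer_status = status,
                 n_species = length(al$tree$tip.label)),
            class = "loss_fit")
}

#' @export
print.loss_fit <- function(x, ...) {
  cat(sprintf("%s loss model for (%s, %s): lnL = %.6f over %d species\n",
              x$model, x$genes[1L], x$genes[2L], x$logLik, x$n_species))
  print(signif(x$rates, 6))
  if (x$optimizer_status != "ok") {
    cat("optimizer status:", x$optimizer_status, "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test of correlated gene loss
#'
#' Fits the independent and dependent irreversible-loss models and compares
#' them with a likelihood-ratio test: the statistic is
#' `2 * (lnL_dependent - lnL_independent)` (clipped at zero, with a warning
#' when the pre-clip value falls below `-1e-6`, which signals optimization
#' failure) and the p-value is the upper tail of the chi-square distribution
#' with 2 degrees of freedom (4 dependent minus 2 independent parameters).
#' A low p-value rejects independent loss in favor of correlated loss.
#'
#' @inheritParams fit_independent
#' @param n_comparisons optional Bonferroni correction factor applied to the
#'   p-value (default 1, i.e. raw p-values as when a handful of gene pairs
#'   are reported individually).
#' @return an object of class `"cooccurrence_test"` with `lnL_independent`,
#'   `lnL_dependent`, `statistic`, `df = 2`, `p.value` and the two fits.
#' @export
lrt_cooccurrence <- function(tree, traits, gene1, gene2, opts = coev_opts(),
                             n_comparisons = 1L) {
  fi <- fit_independent(tree, traits, gene1, gene2, opts)
  fd <- fit_dependent(tree, traits, gene1, gene2, opts)
  lambda <- 2 * (fd$logLik - fi$logLik)
  if (lambda < -1e-6) {
    warning(sprintf(
      "negative LRT statistic (%.3g): dependent-model optimization failed to reach the independent optimum",
      lambda))
  }
  lambda <- max(lambda, 0)
  p <- stats::pchisq(lambda, df = 2L, lower.tail = FALSE)
  p <- min(1, p * n_comparisons)
  structure(list(genes = c(gene1, gene2),
                 lnL_independent = fi$logLik,
                 lnL_dependent = fd$logLik,
                 statistic = lambda, df = 2L, p.value = p,
                 fit_independent = fi, fit_dependent = fd),
            class = "cooccurrence_test")
}

#' @export
print.cooccurrence_test <- function(x, ...) {
  cat("Correlated gene loss LRT:", x$genes[1L], "vs", x$genes[2L], "\n")
  cat(sprintf("  lnL independent = %.6f, lnL dependent = %.6f\n",
              x$lnL_independent, x$lnL_dependent))
  cat(sprintf("  LRT = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
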