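test_that("transition matrices match closed forms and boundary cases", {
  gp <- pair_loss_generator(0.3, 0.7, 1.1, 0.2)
  expect_equal(transition_matrix(gp, 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  # (0,0) is absorbing
  P <- transition_matrix(gp, 3.7)
  expect_equal(unname(P["00", ]), c(1, 0, 0, 0), tolerance = 1e-12)
  # single trait closed form: P(present -> present) = exp(-beta t)
  gs <- single_loss_generator(1)
  expect_equal(transition_matrix(gs, log(2))["present", "present"], 0.5,
               tolerance = 1e-10)
  for (t in c(0.1, 1, 5)) {
    expect_equal(transition_matrix(gs, t)["present", "present"], exp(-t),
                 tolerance = 1e-10)
  }
  expect_error(transition_matrix(gs, -1), "non-negative")
  expect_error(single_loss_generator(-0.1), ">= 0")
  expect_error(pair_loss_generator(-1, 1, 1, 1), ">= 0")
})

test_that("transition matrices are row-stochastic and form a semigroup", {
  set.seed(101)
  for (i in 1:20) {
    gen <- random_pair_generator()
    s <- runif(1, 0, 2)
    t <- runif(1, 0, 2)
    Ps <- transition_matrix(gen, s)
    Pt <- transition_matrix(gen, t)
    Pst <- transition_matrix(gen, s + t)
    expect_lt(max(abs(rowSums(Ps) - 1)), 1e-10)
    expect_true(all(Ps >= -1e-12 & Ps <= 1 + 1e-12))
    expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-8)
  }
})

test_that("pruning likelihood matches closed forms on tiny trees", {
  tr <- parse_newick("(A:1,B:1);")
  gs <- single_loss_generator(1)
  # one observed tip on a unit branch, the other missing: lnL = -beta * t
  expect_equal(pruning_loglik(tr, c(A = 1, B = NA), gs), -1,
               tolerance = 1e-12)
  # beta = 0 and all tips present: probability 1
  expect_equal(pruning_loglik(tr, c(A = 1, B = 1),
                              single_loss_generator(0)), 0)
  # impossible data: a gene present cannot descend from an absent root
  gp <- pair_loss_generator(1, 1, 1, 1)
  m <- rbind(A = c(1L, 1L), B = c(1L, 1L))
  expect_identical(pruning_loglik(tr, m, gp, root_state = "00"), -Inf)
  expect_error(pruning_loglik(tr, c(A = 1, Z = 0), gs), "Z")
  expect_error(pruning_loglik(tr, c(A = 2, B = 1), gs), "state token")
})

test_that("pruning equals brute-force enumeration over internal states", {
  skip_if_not_installed("Matrix")
  set.seed(202)
  for (i in 1:25) {
    n <- sample(3:6, 1L)
    tr <- simulate_yule_tree(n, 1)
    gen <- random_pair_generator()
    m <- random_pair_states(tr, p_missing = 0.15)
    lnl <- pruning_loglik(tr, m, gen)
    partials <- genecoev:::.partials_pair(m[tr$tip.label, 1L],
                                          m[tr$tip.label, 2L])
    oracle <- brute_force_loglik(tr, partials, gen$Q, root_state = 4L)
    if (is.finite(oracle)) {
      expect_lt(abs(lnl - oracle) / abs(oracle), 1e-10)
    } else {
      expect_identical(lnl, -Inf)
    }
    # single trait too
    gs <- single_loss_generator(runif(1, 0.05, 2))
    st <- m[, 1L]
    lnl1 <- pruning_loglik(tr, st, gs)
    partials1 <- genecoev:::.partials_single(st[tr$tip.label])
    oracle1 <- brute_force_loglik(tr, partials1, gs$Q, root_state = 1L)
    expect_lt(abs(lnl1 - oracle1) / max(abs(oracle1), 1), 1e-10)
  }
})

test_that("independent fit handles boundaries and is label-symmetric", {
  tr <- simulate_yule_tree(40, 1, seed = 5)
  m <- matrix(1L, 40, 2, dimnames = list(tr$tip.label, c("a", "b")))
  fit <- fit_independent(tr, trait_matrix(m), "a", "b")
  expect_lt(fit$rates[["beta1"]], 1e-3)
  expect_gt(fit$logLik, -1e-3)

  gp <- pair_loss_generator(0.4, 0.2, 0.4, 0.2)
  tm <- simulate_trait_pair(tr, gp, seed = 9, genes = c("a", "b"))
  f12 <- fit_independent(tr, tm, "a", "b")
  f21 <- fit_independent(tr, tm, "b", "a")
  expect_equal(f12$logLik, f21$logLik, tolerance = 1e-8)
  expect_equal(unname(f12$rates), unname(rev(f21$rates)), tolerance = 1e-6)
})

test_that("dependent lnL equals independent lnL at the factorization point", {
  set.seed(303)
  for (i in 1:10) {
    tr <- simulate_yule_tree(sample(20:60, 1L), 1)
    gen <- random_pair_generator()
    tm <- simulate_trait_pair(tr, gen)
    fi <- fit_independent(tr, tm, "gene1", "gene2")
    start <- independent_as_dependent_start(fi$rates[["beta1"]],
                                            fi$rates[["beta2"]])
    fd <- fit_dependent(tr, tm, "gene1", "gene2",
                        coev_opts(start = start))
    # evaluating at (not refitting from) the factorization point requires a
    # direct likelihood call; the constrained optimum can only improve on it
    gen_fact <- pair_loss_generator(start[["q42"]], start[["q43"]],
                                    start[["q31"]], start[["q21"]])
    lnl_fact <- pruning_loglik(tr, unclass(tm), gen_fact)
    expect_lt(abs(lnl_fact - fi$logLik), 1e-8)
    expect_gte(fd$logLik, fi$logLik - 1e-6)
  }
})

test_that("refitting from the returned estimates reproduces the optimum", {
  tr <- simulate_yule_tree(60, 1, seed = 77)
  tm <- simulate_trait_pair(tr, pair_loss_generator(0.2, 0.5, 0.8, 0.3),
                            seed = 78)
  fd <- fit_dependent(tr, tm, "gene1", "gene2",
                      coev_opts(restarts = 10, seed = 1))
  re <- fit_dependent(tr, tm, "gene1", "gene2",
                      coev_opts(start = fd$rates))
  expect_equal(re$logLik, fd$logLik, tolerance = 1e-6)
  expect_lte(fd$logLik, 0)
})

test_that("dependent fit recovers rates near zero for all-present data", {
  tr <- simulate_yule_tree(30, 1, seed = 12)
  m <- matrix(1L, 30, 2, dimnames = list(tr$tip.label, c("a", "b")))
  fd <- fit_dependent(tr, trait_matrix(m), "a", "b",
                      coev_opts(restarts = 3, seed = 2))
  expect_gt(fd$logLik, -1e-3)
  expect_lt(max(fd$rates[c("q42", "q43")]), 1e-3)
})

test_that("the LRT is zero when the dependent model is held at the independent optimum", {
  tr <- simulate_yule_tree(50, 1, seed = 31)
  tm <- simulate_trait_pair(tr, pair_loss_generator(0.3, 0.3, 0.3, 0.3),
                            seed = 32)
  fi <- fit_independent(tr, tm, "gene1", "gene2")
  start <- independent_as_dependent_start(fi$rates[["beta1"]],
                                          fi$rates[["beta2"]])
  gen_fact <- pair_loss_generator(start[["q42"]], start[["q43"]],
                                  start[["q31"]], start[["q21"]])
  lnl_fact <- pruning_loglik(tr, unclass(tm), gen_fact)
  lambda <- max(0, 2 * (lnl_fact - fi$logLik))
  expect_equal(lambda, 0, tolerance = 1e-8)
  expect_equal(stats::pchisq(lambda, 2, lower.tail = FALSE), 1)
})

test_that("strong asymmetric dependence is detected and rates ordered", {
  set.seed(404)
  qhat <- replicate(12, {
    tr <- simulate_yule_tree(150, 1)
    gen <- pair_loss_generator(q42 = 0.05, q43 = 0.3, q31 = 1.0, q21 = 0.3)
    tm <- simulate_trait_pair(tr, gen)
    fd <- fit_dependent(tr, tm, "gene1", "gene2",
                        coev_opts(restarts = 5, seed = 1))
    fd$rates[c("q42", "q31")]
  })
  expect_gt(median(qhat["q31", ]), median(qhat["q42", ]))
})

test_that("lrt_cooccurrence returns a coherent result object", {
  tr <- simulate_yule_tree(80, 1, seed = 55)
  gen <- pair_loss_generator(q42 = 0.05, q43 = 0.05, q31 = 1.5, q21 = 1.5)
  tm <- simulate_trait_pair(tr, gen, seed = 56)
  res <- lrt_cooccurrence(tr, tm, "gene1", "gene2",
                          coev_opts(restarts = 5, seed = 3))
  expect_s3_class(res, "cooccurrence_test")
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_equal(res$statistic,
               max(0, 2 * (res$lnL_dependent - res$lnL_independent)))
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  # Bonferroni option scales the p-value
  res3 <- lrt_cooccurrence(tr, tm, "gene1", "gene2",
                           coev_opts(restarts = 3, seed = 4),
                           n_comparisons = 3L)
  expect_lte(res3$p.value, 1)
  expect_gte(res3$p.value, res$p.value)
})
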