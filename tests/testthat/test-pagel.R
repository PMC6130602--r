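test_that("single-trait pruning likelihood matches closed-form limits", {
  t2 <- read_newick("(A:0,B:0);")
  # zero branch lengths: transitions impossible, root state must match tips
  expect_equal(loglik_single_trait(t2, c(A = 1, B = 1), 1, 1), log(0.5),
               tolerance = 1e-6)
  # saturated branches: tips independent, stationary 1/2 each
  tn <- read_newick("((A:1e6,B:1e6):1e6,(C:1e6,D:1e6):1e6);")
  x <- c(A = 1, B = 0, C = 1, D = 0)
  expect_equal(loglik_single_trait(tn, x, 1, 1), 4 * log(0.5), tolerance = 1e-6)
  expect_error(loglik_single_trait(t2, c(A = 1), 1, 1), "no state for tip")
  expect_error(loglik_single_trait(t2, c(A = 1, B = 1), -1, 1), "rates")
})

test_that("pruning equals enumeration over internal states (2- and 4-state)", {
  skip_if_not_installed("Matrix")
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    tr <- random_tree(n, seed = 200 + rep)
    x <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
    y <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
    a1 <- runif(1, 0.1, 2); b1 <- runif(1, 0.1, 2)
    expect_equal(loglik_single_trait(tr, x, a1, b1, zero_floor = 0),
                 enum_loglik2(tr, x, a1, b1), tolerance = 1e-10)
    q <- runif(8, 0.05, 2)
    dm <- dependent_model(q[1], q[2], q[3], q[4], q[5], q[6], q[7], q[8])
    expect_equal(loglik_dependent(tr, x, y, dm, zero_floor = 0),
                 enum_loglik4(tr, x, y, dm), tolerance = 1e-10)
  }
})

test_that("independence-structured dependent model factorises over traits", {
  tr <- random_tree(6, seed = 5)
  set.seed(6)
  x <- setNames(rbinom(6, 1, 0.5), tr$tip.label)
  y <- setNames(rbinom(6, 1, 0.5), tr$tip.label)
  im <- independent_model(0.5, 0.8, 1.2, 0.3)
  l_sum <- loglik_single_trait(tr, x, 0.5, 0.8, zero_floor = 0) +
    loglik_single_trait(tr, y, 1.2, 0.3, zero_floor = 0)
  l_dep <- loglik_dependent(tr, x, y, as_dependent(im), zero_floor = 0)
  expect_equal(l_dep, l_sum, tolerance = 1e-9)
  # zero branch lengths, all tips (1,1): uniform root prior over 4 states
  t2 <- read_newick("(A:0,B:0);")
  expect_equal(loglik_dependent(t2, c(A = 1, B = 1), c(A = 1, B = 1),
                                as_dependent(im)), log(0.25), tolerance = 1e-6)
})

test_that("likelihood is invariant to child order and trait swap", {
  tr <- random_tree(6, seed = 17)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  set.seed(18)
  x <- setNames(rbinom(6, 1, 0.5), tr$tip.label)
  y <- setNames(c(1, 0, 1, 1, 0, 0), tr$tip.label)
  q <- runif(8, 0.1, 2)
  dm <- dependent_model(q[1], q[2], q[3], q[4], q[5], q[6], q[7], q[8])
  expect_equal(loglik_dependent(tr, x, y, dm), loglik_dependent(tr2, x, y, dm),
               tolerance = 1e-10)
  # swapping x and y with the corresponding rate relabelling
  dm_swap <- dependent_model(q12 = q[2], q13 = q[1], q21 = q[5], q24 = q[6],
                             q31 = q[3], q34 = q[4], q42 = q[8], q43 = q[7])
  expect_equal(loglik_dependent(tr, y, x, dm_swap),
               loglik_dependent(tr, x, y, dm), tolerance = 1e-10)
})

test_that("ML fitting recovers generating rates on a large tree", {
  tree <- simulate_tree(400, seed = 21)
  truth <- independent_model(1.5, 0.8, 0.6, 1.1)
  pr <- simulate_pair(tree, truth, seed = 22)
  fit <- fit_independent(tree, pr$x, pr$y, pagel_options(restarts = 3, seed = 1))
  rel_err <- abs(fit$model$rates - truth$rates) / truth$rates
  expect_lt(max(rel_err), 0.5)
  # fitted optimum beats random probes of the likelihood surface
  set.seed(33)
  for (k in 1:20) {
    probe <- exp(runif(4, log(1e-2), log(1e2)))
    ll <- loglik_single_trait(tree, pr$x, probe[1], probe[2]) +
      loglik_single_trait(tree, pr$y, probe[3], probe[4])
    expect_gte(fit$loglik, ll - 1e-6)
  }
})

test_that("constant traits hit the rate boundary and are flagged", {
  tree <- simulate_tree(20, seed = 8)
  x <- setNames(rep(1L, 20), tree$tip.label)
  y <- setNames(rbinom(20, 1, 0.5), tree$tip.label)
  fit <- fit_independent(tree, x, y, pagel_options(restarts = 2, seed = 1))
  expect_true(fit$boundary)
})

test_that("the LRT has 4 degrees of freedom and respects nesting", {
  expect_identical(n_free_params(dependent_model(1, 1, 1, 1, 1, 1, 1, 1)) -
                     n_free_params(independent_model(1, 1, 1, 1)), 4L)
  tree <- simulate_tree(40, seed = 31)
  for (s in 1:4) {
    pr <- simulate_pair(tree, independent_model(1, 1, 1, 1), seed = 40 + s)
    res <- lrt_pair(tree, pr$x, pr$y, pagel_options(restarts = 2, seed = s))
    expect_gte(res$LR, 0)
    expect_gte(res$lnL_dep, res$lnL_indep - 1e-6)
    expect_identical(res$df, 4L)
    expect_equal(res$p_value, pchisq(res$LR, 4, lower.tail = FALSE))
  }
})

test_that("perfectly correlated traits give a decisive LR", {
  tree <- simulate_tree(74, seed = 1)
  pr <- simulate_pair(tree, independent_model(1, 1, 1, 1), seed = 9)
  res <- lrt_pair(tree, pr$x, pr$x, pagel_options(restarts = 3, seed = 1))
  expect_gt(res$LR, qchisq(0.99, 4))  # 13.28
})

test_that("dual-transition entries of the dependent generator are exactly zero", {
  Q <- rate_matrix(dependent_model(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  expect_identical(unname(Q[cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))]), rep(0, 4))
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-15)
})

test_that("all-pairs LR matrix is symmetric, order-invariant and resumable", {
  tree <- simulate_tree(25, seed = 51)
  pm <- simulate_profile_set(tree, n_profiles = 5, blocks = c(2),
                             noise = 0.1, seed = 52)
  opts <- pagel_options(restarts = 1, seed = 3)
  lr <- all_pairs_lrt(pm, tree, opts)
  expect_identical(sum(!is.na(lr[upper.tri(lr)])), 10L)
  expect_equal(lr, t(lr), tolerance = 0)
  expect_equal(unname(diag(lr)), rep(max(lr[upper.tri(lr)]), 5))

  # chunked evaluation gives the identical matrix
  pairs <- t(combn(5, 2))
  lr_a <- all_pairs_lrt(pm, tree, opts, pairs = pairs[1:5, ])
  lr_b <- all_pairs_lrt(pm, tree, opts, pairs = pairs[6:10, ])
  merged <- ifelse(is.na(lr_a), lr_b, lr_a)
  diag(merged) <- diag(lr)
  expect_equal(as.vector(merged), as.vector(lr), tolerance = 0)

  # checkpoint resume skips completed pairs and reproduces the matrix
  ck <- tempfile(fileext = ".tsv")
  lr_c1 <- all_pairs_lrt(pm, tree, opts, checkpoint = ck, pairs = pairs[1:4, ])
  expect_identical(nrow(read.table(ck, header = TRUE, sep = "\t")), 4L)
  lr_c2 <- all_pairs_lrt(pm, tree, opts, checkpoint = ck)
  expect_equal(as.vector(lr_c2), as.vector(lr), tolerance = 0)

  # constant profiles are excluded with a message
  mat <- cbind(pm$mat[, 1:3], allon = rep(1L, 25))
  rownames(mat) <- rownames(pm$mat)
  expect_message(all_pairs_lrt(profile_matrix(mat), tree, opts),
                 "constant profile")
})
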