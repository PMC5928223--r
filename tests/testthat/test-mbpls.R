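test_that("preprocessing balances block sums of squares and centres columns", {
  bs <- random_block_set(15, c(4, 18), seed = 1)
  pp <- preprocess_blocks(bs)
  ss <- vapply(pp$blocks$blocks, function(b) sum(b^2), numeric(1))
  expect_lt(diff(range(ss)) / mean(ss), 1e-9)
  mu <- unlist(lapply(pp$blocks$blocks, colMeans))
  expect_true(all(abs(mu) < 1e-10))
  # single-variable blocks: block factor 1, pure autoscaling
  one <- random_block_set(10, c(1, 1), seed = 2)
  ppo <- preprocess_blocks(one)
  expect_equal(unname(ppo$model$block_factors), c(1, 1))
  expect_equal(ppo$blocks$blocks$block1[, 1],
               drop(scale(one$blocks$block1)), ignore_attr = TRUE)

  cb <- block_set(list(a = cbind(x = rnorm(8), bad = rep(2, 8))))
  expect_error(preprocess_blocks(cb), "bad")
  nab <- block_set(list(a = cbind(x = c(1, NA, 3, 4))))
  expect_error(preprocess_blocks(nab), "complete-case")
})

test_that("block_set validates shared samples and unique names", {
  m1 <- matrix(rnorm(6), 3, dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  m2 <- m1[c(2, 1, 3), ]
  expect_error(block_set(list(x = m1, y = m2)), "sample ids")
  dup <- matrix(rnorm(6), 3, dimnames = list(c("a", "b", "c"), c("v", "v")))
  expect_error(block_set(list(x = dup)), "duplicate variable")
})

test_that("multiblock super scores equal single-matrix PLS and are orthogonal", {
  for (s in 1:5) {
    bs <- random_block_set(20, c(3, 6, 2), seed = 20 + s)
    y <- random_two_class_y(20, seed = 40 + s)
    fit <- fit_mbpls(bs, y, n_components = 3)
    # orthogonality of successive super scores
    g <- crossprod(fit$T)
    expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
    # block importances sum to one per component
    expect_equal(unname(rowSums(fit$block_importance)), rep(1, 3),
                 tolerance = 1e-12)
    # reference: plain NIPALS PLS on the preprocessed concatenation
    pp <- preprocess_blocks(bs)
    X <- do.call(cbind, pp$blocks$blocks)
    Y <- scale(as.numeric(y == levels(y)[2]))
    ref <- nipals_pls_scores(X, Y, 3)
    for (a in 1:3) {
      expect_gt(abs(stats::cor(fit$T[, a], ref[, a])), 1 - 1e-8)
    }
  }
})

test_that("the multiblock fit agrees with an external PLS implementation", {
  skip_if_not_installed("mixOmics")
  bs <- random_block_set(25, c(4, 7), seed = 99)
  y <- random_two_class_y(25, seed = 98)
  fit <- fit_mbpls(bs, y, n_components = 2)
  pp <- preprocess_blocks(bs)
  X <- do.call(cbind, pp$blocks$blocks)
  Y <- scale(as.numeric(y == levels(y)[2]))
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    expect_gt(abs(stats::cor(fit$T[, a], ref$variates$X[, a])), 1 - 1e-8)
  }
})

test_that("single and dummy Y codings give the same components", {
  bs <- random_block_set(18, c(5, 3), seed = 7)
  y <- random_two_class_y(18, seed = 8)
  f1 <- fit_mbpls(bs, y, 2, y_coding = "single")
  f2 <- fit_mbpls(bs, y, 2, y_coding = "dummy")
  for (a in 1:2) {
    expect_gt(abs(stats::cor(f1$T[, a], f2$T[, a])), 1 - 1e-10)
  }
  expect_equal(f1$block_importance, f2$block_importance, tolerance = 1e-8)
})

test_that("a zero block receives (near) zero importance", {
  withr::with_seed(21, {
    n <- 12
    live <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
    dead <- matrix(0, n, 3, dimnames = list(NULL, paste0("z", 1:3)))
    bs <- block_set(list(live = live, dead = dead))
    y <- factor(rep(c("a", "b"), 6))
    fit <- fit_mbpls(bs, y, 1, preprocess = FALSE)
    expect_lt(fit$block_importance[1, "dead"], 1e-20)
  })
})

test_that("model refits are bitwise deterministic", {
  bs <- random_block_set(16, c(4, 4), seed = 31)
  y <- random_two_class_y(16, seed = 32)
  f1 <- fit_mbpls(bs, y, 2)
  f2 <- fit_mbpls(bs, y, 2)
  expect_identical(f1$T, f2$T)
  expect_identical(f1$W, f2$W)
})

test_that("explained variance behaves across informative and null designs", {
  # one strongly informative variable: component 1 captures most of Y
  withr::with_seed(22, {
    y <- factor(rep(c("a", "b"), each = 15))
    informative <- as.numeric(y == "b") + rnorm(30, 0, 0.05)
    bs <- block_set(list(main = cbind(sig = informative,
                                      noise = rnorm(30))))
    fit <- fit_mbpls(bs, y, 2)
    expect_gt(fit$explained_y_variance[1], 0.5)
    ev <- explained_variance(fit)
    expect_true(all(ev$y_fraction >= 0))
    expect_lte(max(ev$y_cumulative), 1 + 1e-9)
    expect_lte(max(ev$x_cumulative), 1 + 1e-9)
  })
  # coin-flip labels explain less than planted labels, on average
  null_ev <- vapply(1:25, function(s) {
    bs <- random_block_set(40, c(5, 5), seed = 700 + s)
    y <- random_two_class_y(40, seed = 800 + s)
    fit_mbpls(bs, y, 1)$explained_y_variance[1]
  }, numeric(1))
  planted_ev <- vapply(1:25, function(s) {
    withr::with_seed(900 + s, {
      y <- factor(rep(c("a", "b"), each = 20))
      sig <- as.numeric(y == "b") * 2 + rnorm(40)
      bs <- block_set(list(b1 = cbind(sig = sig, n1 = rnorm(40)),
                           b2 = matrix(rnorm(80), 40,
                                       dimnames = list(NULL, c("n2", "n3")))))
      fit_mbpls(bs, y, 1)$explained_y_variance[1]
    })
  }, numeric(1))
  expect_gt(mean(planted_ev), mean(null_ev))
})

test_that("component selection follows the prefix 10% rule", {
  expect_equal(select_components(c(0.4, 0.15, 0.05)), 2)
  expect_equal(select_components(c(0.4)), 1)
  expect_equal(select_components(c(0.05, 0.3)), 1)  # prefix-based
  expect_equal(select_components(c(0.05, 0.04)), 1) # never below 1
  expect_equal(select_components(c(0.3, 0.2, 0.2, 0.05), 0.1), 3)
})

test_that("VIP matches its closed form and normalization identity", {
  # equal weights: every VIP is exactly 1
  p <- 5
  eq <- fake_mbpls_model(matrix(rep(1 / sqrt(p), p), ncol = 1,
                                dimnames = list(paste0("v", 1:p), NULL)),
                         ssy = 0.4)
  expect_equal(unname(vip_scores(eq, 1)), rep(1, p))
  # p = 2, w = (0.8, 0.6): VIP = sqrt(2 * w^2)
  two <- fake_mbpls_model(matrix(c(0.8, 0.6), ncol = 1,
                                 dimnames = list(c("a", "b"), NULL)),
                          ssy = 0.5)
  expect_equal(unname(vip_scores(two, 1)), c(sqrt(2 * 0.64), sqrt(2 * 0.36)),
               tolerance = 1e-9)
  # sum of squared VIPs equals p on fitted models
  for (s in 1:5) {
    bs <- random_block_set(15, c(3, 4, 6), seed = 50 + s)
    y <- random_two_class_y(15, seed = 60 + s)
    fit <- fit_mbpls(bs, y, 2)
    for (A in 1:2) {
      v <- vip_scores(fit, A)
      expect_equal(sum(v^2), length(v), tolerance = 1e-8)
    }
  }
})

test_that("variable selection is strict at the VIP threshold", {
  # a model where both variables carry identical weight: VIP exactly 1,
  # which the strict > rule must not select
  withr::with_seed(23, {
    t1 <- rnorm(12)
    X <- cbind(a = t1, b = t1)
    mdl <- fake_mbpls_model(matrix(rep(1 / sqrt(2), 2), ncol = 1,
                                   dimnames = list(c("a", "b"), NULL)),
                            ssy = 0.5)
    mdl$X_preprocessed <- X
    mdl$T <- matrix(t1, ncol = 1)
    mdl$variable_block <- c(a = "blk", b = "blk")
    rep <- select_variables(mdl)
    expect_equal(rep$vip, c(1, 1), tolerance = 1e-12)
    expect_false(any(rep$selected))
    expect_true(all(rep$displayed))  # |correlation| = 1 > 0.3
  })
})

test_that("null variables are selected at well below coin-flip rates", {
  rates <- vapply(1:50, function(s) {
    bs <- random_block_set(20, c(4, 4), seed = 1000 + s)
    y <- random_two_class_y(20, seed = 1100 + s)
    fit <- fit_mbpls(bs, y, 2)
    mean(select_variables(fit)$selected)
  }, numeric(1))
  expect_lt(mean(rates), 0.5)
})

test_that("Mann-Whitney post-hoc p-values are exact where tractable", {
  sep <- block_set(list(b = matrix(c(1:9, 101:109), ncol = 1,
                                   dimnames = list(NULL, "v"))))
  y <- rep(c("g1", "g2"), each = 9)
  res <- mann_whitney_posthoc(sep, y)
  expect_equal(res$p_value, 2 / choose(18, 9), tolerance = 1e-12)
  expect_equal(res$band, "**")

  tiny <- block_set(list(b = matrix(c(1, 2), ncol = 1,
                                    dimnames = list(NULL, "v"))))
  expect_equal(mann_whitney_posthoc(tiny, c("a", "b"))$p_value, 1)

  # ties fall back to the corrected normal approximation without error
  tied <- block_set(list(b = matrix(rep(c(1, 1, 2, 2), 6), ncol = 1,
                                    dimnames = list(NULL, "v"))))
  pt <- mann_whitney_posthoc(tied, rep(c("a", "b"), 12))$p_value
  expect_true(pt >= 0 && pt <= 1)
  expect_error(mann_whitney_posthoc(sep, rep("g1", 18)), "two classes")
})

test_that("post-hoc p-values are calibrated under exchangeable samples", {
  pvals <- vapply(1:500, function(s) {
    withr::with_seed(2000 + s, {
      b <- block_set(list(x = matrix(rnorm(24), ncol = 1,
                                     dimnames = list(NULL, "v"))))
      mann_whitney_posthoc(b, rep(c("a", "b"), each = 12))$p_value
    })
  }, numeric(1))
  # rank-sum p-values are discrete, so ties are expected in the KS input
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("significance bands follow the report legend", {
  expect_equal(significance_band(c(0.005, 0.03, 0.07, 0.2)),
               c("**", "*", "§", "ns"))
  # band bounds are strict: p = 0.1 earns no band, p = 0.05 only the weak one
  expect_equal(significance_band(c(0.1, 0.05, 0.01)), c("ns", "§", "*"))
})
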