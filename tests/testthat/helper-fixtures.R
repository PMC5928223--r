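# Shared fixtures: random block sets and a plain single-matrix NIPALS PLS
# used as the independent reference for the multiblock fit.

random_block_set <- function(n, p_per_block, seed) {
  withr::with_seed(seed, {
    blocks <- lapply(seq_along(p_per_block), function(i) {
      matrix(rnorm(n * p_per_block[i]), n,
             dimnames = list(sprintf("s%02d", seq_len(n)),
                             sprintf("b%d_v%d", i, seq_len(p_per_block[i]))))
    })
    names(blocks) <- sprintf("block%d", seq_along(p_per_block))
    block_set(blocks)
  })
}

random_two_class_y <- function(n, seed) {
  withr::with_seed(seed, factor(sample(rep(c("A", "B"), length.out = n))))
}

# Textbook NIPALS PLS on one matrix: returns the score matrix only.
# Serves as the single-block reference the multiblock super scores must match.
nipals_pls_scores <- function(X, Y, ncomp, tol = 1e-12, max_iter = 1000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, 1]
    t_old <- rep(Inf, nrow(X))
    iter <- 0
    repeat {
      iter <- iter + 1
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      q <- crossprod(Y, tt)
      q <- q / sqrt(sum(q^2))
      u <- Y %*% q
      if (sum((tt - t_old)^2) < tol^2 * sum(tt^2) || iter >= max_iter) break
      t_old <- tt
    }
    p <- crossprod(X, tt) / sum(tt^2)
    cc <- crossprod(Y, tt) / sum(tt^2)
    X <- X - tt %*% t(p)
    Y <- Y - tt %*% t(cc)
    Tm[, a] <- tt
  }
  Tm
}

# Minimal model stub for direct-formula VIP checks.
fake_mbpls_model <- function(W, ssy) {
  structure(list(W = W, explained_y_variance = ssy,
                 n_components = ncol(W)),
            class = "mbpls")
}
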