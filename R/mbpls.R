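#' Construct a named set of predictor blocks
#'
#' A `block_set` holds several samples-x-variables matrices over the same
#' samples in the same order: the X of a multiblock PLS discriminant
#' analysis. The canonical four blocks are biological determinants,
#' stimulated saliva, resting saliva and microbiota family abundances.
#'
#' @param blocks named list of numeric matrices with identical rownames
#'   (sample ids) in identical order; variable names unique within a block.
#' @return An object of class `"block_set"`.
#' @export
block_set <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)),
            all(nzchar(names(blocks))))
  if (anyDuplicated(names(blocks))) stop("duplicate block names")
  blocks <- lapply(blocks, as.matrix)
  n <- nrow(blocks[[1]])
  ids <- rownames(blocks[[1]])
  if (is.null(ids)) {
    ids <- if (n > 0) paste0("sample", seq_len(n)) else character(0)
    if (n > 0) blocks <- lapply(blocks, function(b) { rownames(b) <- ids; b })
  }
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!identical(rownames(b) %||% character(0), ids) &&
        !(nrow(b) == 0 && n == 0)) {
      stop(sprintf("block '%s' does not share the common sample ids/order", nm))
    }
    if (ncol(b) > 0 && anyDuplicated(colnames(b))) {
      stop(sprintf("duplicate variable names in block '%s'", nm))
    }
    if (is.null(colnames(b)) && ncol(b) > 0) {
      colnames(b) <- paste0(nm, "_v", seq_len(ncol(b)))
      blocks[[nm]] <- b
    }
  }
  structure(list(blocks = blocks, sample_ids = ids,
                 block_names = names(blocks)),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("Block set: %d samples, %d blocks\n", length(x$sample_ids),
              length(x$blocks)))
  for (nm in x$block_names) {
    cat(sprintf("  %s: %d variables\n", nm, ncol(x$blocks[[nm]])))
  }
  invisible(x)
}

#' Centre, autoscale and block-balance predictor blocks
#'
#' Each variable is mean-centred and scaled to unit variance, then each block
#' is divided by the square root of its variable count. After this step every
#' block has the same total sum of squares, so a 18-variable microbiota block
#' cannot dominate a 4-variable clinical block merely by being wider.
#'
#' @param blocks a `block_set` with >= 2 samples and no constant or missing
#'   variables.
#' @return list with `blocks` (transformed `block_set`) and `model`
#'   (class `"preprocess_model"`: per-variable `means` and `scales`, per-block
#'   `block_factors`).
#' @export
preprocess_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "block_set"))
  n <- length(blocks$sample_ids)
  if (n < 2) stop("preprocessing requires at least 2 samples")
  means <- list(); scales <- list(); factors <- numeric(0)
  out <- blocks$blocks
  for (nm in blocks$block_names) {
    b <- blocks$blocks[[nm]]
    if (anyNA(b)) {
      stop(sprintf(
        "block '%s' contains missing values; apply a complete-case filter first",
        nm))
    }
    mu <- colMeans(b)
    sdv <- apply(b, 2, stats::sd)
    if (any(sdv == 0)) {
      stop(sprintf("constant variable(s) in block '%s': %s", nm,
                   paste(colnames(b)[sdv == 0], collapse = ", ")))
    }
    f <- sqrt(ncol(b))
    out[[nm]] <- sweep(sweep(b, 2, mu, "-"), 2, sdv * f, "/")
    means[[nm]] <- mu; scales[[nm]] <- sdv; factors[nm] <- f
  }
  list(blocks = block_set(out),
       model = structure(list(means = means, scales = scales,
                              block_factors = factors),
                         class = "preprocess_model"))
}

# Code a two-class factor as centred, unit-variance Y columns.
code_y <- function(y, coding = c("single", "dummy")) {
  coding <- match.arg(coding)
  y <- factor(y)
  if (nlevels(y) != 2) stop("discriminant analysis requires exactly two classes")
  ind <- as.numeric(y == levels(y)[2])
  Y <- if (coding == "single") cbind(ind) else cbind(1 - ind, ind)
  Y <- scale(Y, center = TRUE, scale = TRUE)
  if (coding == "dummy") Y <- Y / sqrt(2)  # block-balance the two columns
  attr(Y, "levels") <- levels(y)
  Y
}

#' Fit a multiblock PLS discriminant model
#'
#' Fits MB-PLS-DA by NIPALS on the preprocessed concatenated super-matrix
#' (the super-score form of multiblock PLS, whose super scores and weights
#' coincide with ordinary PLS on the concatenation). Per component the super
#' weight vector is iterated with the Y score to convergence, the super score
#' is `t = X w`, block scores come from the partition of `w` over blocks,
#' `X` is deflated by `t`, and the share of squared super weight falling in
#' each block gives that block's importance for the component. The class
#' factor is coded as a single centred indicator column by default; the
#' two-column dummy coding gives identical scores up to sign.
#'
#' @param blocks a `block_set` (raw; preprocessing is applied internally
#'   unless `preprocess = FALSE`).
#' @param y two-class factor (or coercible), one label per sample.
#' @param n_components number of components to extract.
#' @param y_coding `"single"` (default) or `"dummy"`.
#' @param preprocess apply [preprocess_blocks()] first (default TRUE).
#' @param tol NIPALS convergence tolerance on the super score.
#' @param max_iter maximum NIPALS iterations per component.
#' @return An object of class `"mbpls"`: list with super scores `T`
#'   (samples x components), unit-norm super weights `W` (variables x
#'   components, deflated coordinates), X loadings `P`, y loadings `c_y`,
#'   `block_weights`, `block_scores` and `block_importance` (components x
#'   blocks, rows summing to 1), `explained_y_variance` and
#'   `explained_x_variance` (fractions per component), the variable-to-block
#'   map, class levels, and the preprocessing model.
#' @export
fit_mbpls <- function(blocks, y, n_components = 2,
                      y_coding = c("single", "dummy"), preprocess = TRUE,
                      tol = 1e-12, max_iter = 1000) {
  stopifnot(inherits(blocks, "block_set"), n_components >= 1)
  y_coding <- match.arg(y_coding)
  if (length(y) != length(blocks$sample_ids)) {
    stop("y must have one label per sample")
  }
  pp <- if (preprocess) preprocess_blocks(blocks) else
    list(blocks = blocks, model = NULL)
  X <- do.call(cbind, pp$blocks$blocks)
  var_block <- rep(pp$blocks$block_names,
                   vapply(pp$blocks$blocks, ncol, integer(1)))
  var_names <- unlist(lapply(pp$blocks$blocks, colnames), use.names = FALSE)
  colnames(X) <- var_names
  Y <- code_y(y, y_coding)
  n <- nrow(X); p <- ncol(X)
  A <- n_components

  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  Tm <- matrix(0, n, A); Wm <- matrix(0, p, A); Pm <- matrix(0, p, A)
  Cy <- matrix(0, ncol(Y), A)
  ssy_frac <- ssx_frac <- numeric(A)
  Xd <- X; Yd <- Y
  for (a in seq_len(A)) {
    u <- Yd[, 1]
    t_old <- rep(Inf, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop(sprintf("component %d: X exhausted (zero weights)", a))
      w <- w / nw
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)
      q <- q / sqrt(sum(q^2))
      u <- Yd %*% q
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      if (iter >= max_iter) {
        stop(sprintf("NIPALS failed to converge on component %d after %d iterations",
                     a, iter))
      }
      t_old <- tt
    }
    t2 <- sum(tt^2)
    pl <- crossprod(Xd, tt) / t2
    cy <- crossprod(Yd, tt) / t2
    ssx_before <- sum(Xd^2); ssy_before <- sum(Yd^2)
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(cy)
    ssx_frac[a] <- (ssx_before - sum(Xd^2)) / ssx0
    ssy_frac[a] <- (ssy_before - sum(Yd^2)) / ssy0
    Tm[, a] <- tt; Wm[, a] <- w; Pm[, a] <- pl; Cy[, a] <- cy
  }
  rownames(Tm) <- blocks$sample_ids
  colnames(Tm) <- colnames(Wm) <- colnames(Pm) <- paste0("comp", seq_len(A))
  rownames(Wm) <- rownames(Pm) <- var_names

  bn <- pp$blocks$block_names
  block_importance <- matrix(0, A, length(bn),
                             dimnames = list(paste0("comp", seq_len(A)), bn))
  for (a in seq_len(A)) {
    block_importance[a, ] <- vapply(bn, function(nm) {
      sum(Wm[var_block == nm, a]^2)
    }, numeric(1))
  }
  block_weights <- lapply(pp$blocks$block_names, function(nm) {
    Wm[var_block == nm, , drop = FALSE]
  })
  names(block_weights) <- pp$blocks$block_names
  block_scores <- lapply(pp$blocks$block_names, function(nm) {
    wb <- block_weights[[nm]]
    xb <- pp$blocks$blocks[[nm]]
    sapply(seq_len(A), function(a) {
      nb <- sqrt(sum(wb[, a]^2))
      if (nb == 0) rep(0, n) else xb %*% (wb[, a] / nb)
    })
  })
  names(block_scores) <- pp$blocks$block_names

  structure(
    list(n_components = A, T = Tm, W = Wm, P = Pm, c_y = Cy,
         block_weights = block_weights, block_scores = block_scores,
         block_importance = block_importance,
         explained_y_variance = ssy_frac, explained_x_variance = ssx_frac,
         variable_block = stats::setNames(var_block, var_names),
         X_preprocessed = X, y = factor(y), y_levels = attr(Y, "levels"),
         y_coding = y_coding, preprocess_model = pp$model,
         block_names = pp$blocks$block_names),
    class = "mbpls"
  )
}

#' @export
print.mbpls <- function(x, ...) {
  cat(sprintf("MB-PLS-DA model: %d samples, %d variables in %d blocks, %d components\n",
              nrow(x$T), nrow(x$W), length(x$block_names), x$n_components))
  cat("  explained Y variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_y_variance), collapse = ", "),
      "\n")
  inv <- x$block_importance[1, ]
  cat("  block importance (comp 1):",
      paste(sprintf("%s %.2f", names(inv), inv), collapse = ", "), "\n")
  invisible(x)
}

#' Explained variance per component
#'
#' @param model a fitted `"mbpls"` model.
#' @return data frame with per-component fractions of X and Y sum of squares
#'   and their cumulative values.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "mbpls"))
  data.frame(component = seq_len(model$n_components),
             x_fraction = model$explained_x_variance,
             y_fraction = model$explained_y_variance,
             x_cumulative = cumsum(model$explained_x_variance),
             y_cumulative = cumsum(model$explained_y_variance))
}

#' Choose the number of interpretable components
#'
#' Returns the largest A such that every component up to A explains at least
#' `min_fraction` of the Y variance (prefix rule; minimum 1). With the
#' default 10% rule, Y-variance fractions of 40%, 15%, 5% give A = 2.
#'
#' @param model a fitted `"mbpls"` model, or a numeric vector of per-component
#'   Y-variance fractions.
#' @param min_fraction smallest acceptable per-component Y fraction (default
#'   0.10).
#' @return integer number of components to interpret (>= 1).
#' @export
select_components <- function(model, min_fraction = 0.10) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  frac <- if (inherits(model, "mbpls")) model$explained_y_variance else
    as.numeric(model)
  ok <- frac >= min_fraction
  a <- if (!ok[1]) 0L else {
    runs <- rle(ok)
    runs$lengths[1]
  }
  max(1L, as.integer(a))
}

#' Variable importance in the projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over components
#' `a <= A`, where `p` is the total number of variables across blocks,
#' `w_a` the unit-norm super weights and `SSY_a` the Y variance explained by
#' component a. The squared VIPs average to 1, so 1 is the natural selection
#' threshold; the default uses the first component only.
#'
#' @param model a fitted `"mbpls"` model.
#' @param n_components_used number of components aggregated (default 1).
#' @return named numeric vector of VIP scores (one per variable).
#' @export
vip_scores <- function(model, n_components_used = 1) {
  stopifnot(inherits(model, "mbpls"), n_components_used >= 1,
            n_components_used <= model$n_components)
  A <- n_components_used
  p <- nrow(model$W)
  ssy <- model$explained_y_variance[seq_len(A)]
  if (sum(ssy) == 0) return(stats::setNames(rep(0, p), rownames(model$W)))
  w2 <- model$W[, seq_len(A), drop = FALSE]^2
  stats::setNames(sqrt(p * as.numeric(w2 %*% ssy) / sum(ssy)),
                  rownames(model$W))
}

#' Correlation loadings of variables on the super scores
#'
#' Pearson correlation between each (preprocessed) variable and the super
#' scores of the first `n_components` components; the display rule keeps
#' variables whose maximum absolute correlation loading exceeds 0.3.
#'
#' @param model a fitted `"mbpls"` model.
#' @param n_components components to report (default min(2, A)).
#' @return matrix variables x components of correlations.
#' @export
correlation_loadings <- function(model,
                                 n_components = min(2L, model$n_components)) {
  stopifnot(inherits(model, "mbpls"))
  stats::cor(model$X_preprocessed,
             model$T[, seq_len(n_components), drop = FALSE])
}

#' VIP-based discriminant variable selection
#'
#' Combines VIP on the first component (selection rule: VIP strictly greater
#' than `vip_threshold`) with correlation loadings on components 1-2
#' (display rule: max |loading| strictly greater than `loading_threshold`).
#'
#' @param model a fitted `"mbpls"` model.
#' @param vip_threshold VIP selection threshold (default 1).
#' @param loading_threshold correlation-loading display threshold
#'   (default 0.3).
#' @param n_components_used components aggregated in the VIP (default 1).
#' @return data frame with `block`, `variable`, `vip`, `loading_comp1`,
#'   `loading_comp2` (NA for one-component models), `selected`, `displayed`.
#' @export
select_variables <- function(model, vip_threshold = 1,
                             loading_threshold = 0.3,
                             n_components_used = 1) {
  stopifnot(inherits(model, "mbpls"), vip_threshold > 0, loading_threshold > 0)
  vip <- vip_scores(model, n_components_used)
  ld <- correlation_loadings(model)
  l2 <- if (ncol(ld) >= 2) ld[, 2] else rep(NA_real_, nrow(ld))
  max_ld <- pmax(abs(ld[, 1]), abs(l2), na.rm = TRUE)
  data.frame(block = unname(model$variable_block),
             variable = names(vip),
             vip = unname(vip),
             loading_comp1 = unname(ld[, 1]),
             loading_comp2 = unname(l2),
             selected = unname(vip > vip_threshold),
             displayed = unname(max_ld > loading_threshold),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney post-hoc tests on block variables
#'
#' Two-sided Wilcoxon rank-sum tests of each (raw) block variable between the
#' two classes: exact p-values when the combined sample size is at most 20
#' and the data are tie-free, otherwise the normal approximation with tie and
#' continuity correction. No multiplicity adjustment is applied. Significance
#' bands follow [significance_band()].
#'
#' @param blocks a `block_set` of raw (untransformed) variables.
#' @param y two-class label per sample; both classes must be non-empty.
#' @param variables optional character vector restricting the report.
#' @return data frame with `block`, `variable`, `p_value`, `band`.
#' @export
mann_whitney_posthoc <- function(blocks, y, variables = NULL) {
  stopifnot(inherits(blocks, "block_set"))
  y <- factor(y)
  if (nlevels(y) != 2) stop("two classes required")
  if (any(table(y) < 1)) stop("each class needs at least 1 sample")
  rows <- list()
  for (nm in blocks$block_names) {
    b <- blocks$blocks[[nm]]
    for (v in colnames(b)) {
      if (!is.null(variables) && !v %in% variables) next
      x1 <- b[y == levels(y)[1], v]
      x2 <- b[y == levels(y)[2], v]
      n_tot <- length(x1) + length(x2)
      use_exact <- n_tot <= 20 && !anyDuplicated(c(x1, x2))
      p <- suppressWarnings(
        stats::wilcox.test(x1, x2, exact = use_exact,
                           correct = !use_exact)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        block = nm, variable = v, p_value = min(p, 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$band <- significance_band(out$p_value)
  out
}
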