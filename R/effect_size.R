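#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic and its chi-square p-value; errors when fewer than two classes
#' are present.
#'
#' @param values numeric vector.
#' @param classes class label per observation (>= 2 distinct classes).
#' @return list with `statistic` and `p_value`.
#' @export
kw_test <- function(values, classes) {
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("kw_test requires at least two classes")
  fit <- stats::kruskal.test(values, classes)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Two-class LDA effect-size screen for differential taxa
#'
#' A two-class, no-subclass analogue of the LEfSe procedure: per-sample
#' abundances are rescaled to sum to one million, each taxon is screened with
#' a Kruskal-Wallis test, and taxa passing the screen receive an effect size
#' equal to the mean over `n_boot` within-class bootstrap rounds of
#' `log10(|difference of class means|)` on the per-million scale, floored at
#' zero. A taxon is reported as discriminant when its screen p-value is below
#' `alpha` and its effect size is at least `lda_cutoff` (defaults 0.05 and
#' 2.0). The effect size is a class-mean contrast, not the full one-vs-all
#' LDA of the original tool; with two balanced classes the two agree closely
#' in scale.
#'
#' @param abundance samples-x-taxa matrix of counts or proportions (rows are
#'   rescaled to 1e6 internally).
#' @param classes two-class label per sample; each class needs >= 2 samples.
#' @param alpha Kruskal-Wallis significance threshold.
#' @param lda_cutoff log10 effect-size cutoff.
#' @param n_boot bootstrap rounds for the effect size.
#' @param seed optional integer seed for the bootstrap.
#' @return data frame with one row per taxon: `taxon`, `kw_p`,
#'   `lda_score_log10` (NA when the screen fails), `enriched_class`, `passed`.
#' @export
effect_size_lda <- function(abundance, classes, alpha = 0.05,
                            lda_cutoff = 2.0, n_boot = 30, seed = NULL) {
  m <- if (inherits(abundance, "feature_table")) abundance$counts else
    as.matrix(abundance)
  classes <- factor(classes)
  if (nlevels(classes) != 2) {
    stop("effect_size_lda supports exactly two classes (no subclass stage)")
  }
  if (any(table(classes) < 2)) stop("each class needs at least 2 samples")
  stopifnot(nrow(m) == length(classes), n_boot >= 1)

  totals <- rowSums(m)
  if (any(totals == 0)) stop("samples with zero total abundance")
  scaled <- m / totals * 1e6
  idx <- split(seq_len(nrow(scaled)), classes)
  lv <- levels(classes)

  with_seed(seed, {
    res <- lapply(seq_len(ncol(scaled)), function(j) {
      x <- scaled[, j]
      p <- if (stats::var(x) == 0) 1 else
        stats::kruskal.test(x, classes)$p.value
      mu <- vapply(idx, function(i) mean(x[i]), numeric(1))
      enriched <- lv[which.max(mu)]
      lda <- NA_real_
      if (p < alpha) {
        boots <- vapply(seq_len(n_boot), function(b) {
          d <- mean(x[sample(idx[[2]], length(idx[[2]]), replace = TRUE)]) -
            mean(x[sample(idx[[1]], length(idx[[1]]), replace = TRUE)])
          log10(abs(d))
        }, numeric(1))
        lda <- max(0, mean(boots[is.finite(boots)], na.rm = TRUE))
        if (!is.finite(lda)) lda <- 0
      }
      data.frame(taxon = colnames(scaled)[j] %||% paste0("taxon", j),
                 kw_p = p, lda_score_log10 = lda, enriched_class = enriched,
                 passed = isTRUE(p < alpha && lda >= lda_cutoff),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Per-taxon linear regression against a covariate
#'
#' Ordinary least-squares regression of each taxon's abundance on a
#' continuous covariate (BMI, or log10 detection threshold), with Pearson r
#' and its two-sided t-test p-value, plus Spearman's rho.
#'
#' @param abundance samples-x-taxa numeric matrix (e.g. relative abundances).
#' @param covariate numeric vector, one value per sample; must not be
#'   constant; >= 3 paired observations required.
#' @return data frame with `taxon`, `slope`, `intercept`, `r`, `p_value`,
#'   `spearman_rho`.
#' @export
taxa_covariate_regression <- function(abundance, covariate) {
  m <- as.matrix(abundance)
  stopifnot(nrow(m) == length(covariate))
  if (nrow(m) < 3) stop("at least 3 paired observations required")
  if (stats::var(covariate) == 0) stop("covariate is constant")
  res <- lapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    fit <- stats::lm(y ~ covariate)
    co <- stats::coef(fit)
    if (stats::var(y) == 0) {
      r <- 0; p <- 1; rho <- 0
    } else {
      ct <- stats::cor.test(covariate, y)
      r <- unname(ct$estimate)
      p <- ct$p.value
      rho <- stats::cor(covariate, y, method = "spearman")
    }
    data.frame(taxon = colnames(m)[j] %||% paste0("taxon", j),
               slope = unname(co["covariate"]),
               intercept = unname(co["(Intercept)"]),
               r = r, p_value = p, spearman_rho = rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bray-Curtis principal coordinates ordination
#'
#' Computes Bray-Curtis dissimilarities on per-sample relative abundances
#' (via [vegan::vegdist()]) and embeds them by classical metric
#' multidimensional scaling (eigendecomposition of the double-centred
#' `-D^2/2` matrix). Axes are ordered by decreasing eigenvalue; negative
#' eigenvalues are dropped from the explained fractions. A Euclidean
#' alternative on the raw matrix is available through `method`.
#'
#' @param abundance samples-x-taxa matrix of counts or proportions (rows are
#'   normalised to proportions first when `method = "bray"`).
#' @param n_axes number of ordination axes requested.
#' @param method `"bray"` (default) or `"euclidean"`.
#' @return An object of class `"ordination"`: list with `coordinates`
#'   (samples x axes), `explained_fraction` per returned axis,
#'   `dissimilarity_name` and `eigenvalues`.
#' @export
bray_curtis_pcoa <- function(abundance, n_axes = 2,
                             method = c("bray", "euclidean")) {
  method <- match.arg(method)
  m <- if (inherits(abundance, "feature_table")) abundance$counts else
    as.matrix(abundance)
  if (nrow(m) < 2) stop("ordination requires at least 2 samples")
  if (method == "bray") {
    ra <- relative_abundance(m)
    d <- vegan::vegdist(ra, method = "bray")
  } else {
    d <- stats::dist(m)
  }
  k_max <- nrow(m) - 1
  fit <- suppressWarnings(stats::cmdscale(d, k = k_max, eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    n_pos, n_pos))
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(
    list(coordinates = coords,
         explained_fraction = fit$eig[seq_len(n_axes)] / sum(fit$eig[pos]),
         dissimilarity_name = if (method == "bray") "bray_curtis" else
           "euclidean",
         eigenvalues = fit$eig),
    class = "ordination"
  )
}
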