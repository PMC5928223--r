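#' Construct a sample-by-feature count table
#'
#' The raw form of the microbiome block: non-negative integer counts with
#' samples in rows and features (OTUs or taxa) in columns, optionally carrying
#' a taxonomy lineage table (one row per feature, rank columns such as
#' `phylum` ... `genus`, with `"unclassified"` placeholders kept as labels).
#'
#' @param counts numeric matrix of non-negative integers, samples x features,
#'   with unique row and column names.
#' @param lineage optional data frame with a `feature_id` column matching
#'   `colnames(counts)` plus one column per taxonomic rank.
#' @return An object of class `"feature_table"`: list with `counts` and
#'   `lineage`.
#' @export
feature_table <- function(counts, lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- paste0("feature", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (ncol(counts) > 0 && anyDuplicated(colnames(counts))) {
    stop("duplicate feature ids")
  }
  if (length(counts) > 0) {
    if (any(!is.finite(counts)) || any(counts < 0)) {
      stop("counts must be finite and non-negative")
    }
    if (any(abs(counts - round(counts)) > 1e-8)) {
      stop("counts must be integers")
    }
  }
  storage.mode(counts) <- "double"
  if (!is.null(lineage)) {
    stopifnot(is.data.frame(lineage), "feature_id" %in% names(lineage))
    if (!setequal(lineage$feature_id, colnames(counts))) {
      stop("lineage feature_ids must match count table features")
    }
    lineage <- lineage[match(colnames(counts), lineage$feature_id), ,
                       drop = FALSE]
    rownames(lineage) <- NULL
  }
  structure(list(counts = counts, lineage = lineage), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features, total count %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$lineage)) {
    cat("  lineage ranks:",
        paste(setdiff(names(x$lineage), "feature_id"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Remove low-count features
#'
#' Drops features whose total count over all samples falls below `min_total`
#' (default 3, the sequencing-error filter removing OTUs with fewer than
#' 3 sequences in the whole data set). The sample set is unchanged.
#'
#' @param table a `feature_table`.
#' @param min_total minimum total count for a feature to be retained (>= 0).
#' @return a filtered `feature_table`.
#' @export
filter_low_count_otus <- function(table, min_total = 3) {
  stopifnot(inherits(table, "feature_table"), min_total >= 0)
  if (ncol(table$counts) == 0) return(table)
  keep <- colSums(table$counts) >= min_total
  lineage <- table$lineage
  if (!is.null(lineage)) lineage <- lineage[keep, , drop = FALSE]
  feature_table(table$counts[, keep, drop = FALSE], lineage)
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Sums counts over features sharing the same label at the requested rank.
#' `"unclassified"` labels are retained as taxa in their own right.
#'
#' @param table a `feature_table` with a lineage.
#' @param rank name of a lineage column (e.g. `"family"`).
#' @return a `feature_table` whose features are the distinct rank labels.
#' @export
aggregate_to_rank <- function(table, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$lineage) || !rank %in% names(table$lineage)) {
    stop(sprintf("rank '%s' not present in lineage", rank))
  }
  labels <- as.character(table$lineage[[rank]])
  taxa <- unique(labels)
  out <- vapply(taxa, function(tx) {
    rowSums(table$counts[, labels == tx, drop = FALSE])
  }, numeric(nrow(table$counts)))
  out <- matrix(out, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), taxa))
  feature_table(out,
                lineage = data.frame(feature_id = taxa, rank_label = taxa,
                                     stringsAsFactors = FALSE))
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total. Samples with zero total are
#' returned as all-zero rows and flagged in the `"zero_rows"` attribute.
#'
#' @param table a `feature_table`, or a samples-x-taxa numeric matrix.
#' @return numeric matrix of proportions (rows sum to 1 except flagged zero
#'   rows), with attribute `zero_rows` (logical per sample).
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  totals <- rowSums(m)
  zero <- totals == 0
  out <- m / ifelse(totals == 0, 1, totals)
  attr(out, "zero_rows") <- zero
  out
}

#' Shannon diversity index of one sample
#'
#' `H = -sum(p_i * log(p_i))` over the positive proportions of a single
#' sample's counts, in nats by default; pass `base = 2` for bits.
#'
#' @param counts non-negative numeric vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return the Shannon index.
#' @examples
#' shannon_index(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_index <- function(counts, base = exp(1)) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all-zero sample: Shannon index undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity of a feature table
#'
#' @param table a `feature_table` or counts matrix.
#' @inheritParams shannon_index
#' @return named numeric vector, one Shannon index per sample.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  apply(m, 1, shannon_index, base = base)
}

#' Rarefaction curve for one sample
#'
#' For each requested depth, subsamples the sample's reads without
#' replacement `n_reps` times and averages the number of distinct features
#' observed.
#'
#' @param counts non-negative integer vector for one sample.
#' @param depths subsampling depths, each `<= sum(counts)`.
#' @param n_reps number of random subsamples per depth.
#' @param seed optional integer seed.
#' @return data frame with columns `depth` and `mean_observed`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 10, seed = NULL) {
  stopifnot(is.numeric(counts), all(counts >= 0), n_reps >= 1)
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds sample total count")
  if (any(depths < 1)) stop("depths must be >= 1")
  reads <- rep.int(seq_along(counts), counts)
  with_seed(seed, {
    mean_obs <- vapply(depths, function(d) {
      mean(vapply(seq_len(n_reps), function(r) {
        length(unique(sample(reads, d))) }, numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, mean_observed = mean_obs)
  })
}
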