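#' Read a sample-by-feature count table from TSV
#'
#' Expects a tab-separated file with a header row, the sample id in the first
#' column and one non-negative integer count column per feature.
#'
#' @param path file path.
#' @return a `feature_table` (without lineage; see [read_lineage()]).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("empty table")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate feature id(s)")
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at row '%s', column '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' @param table a `feature_table`.
#' @param path output path; first column `sample_id`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature lineage sidecar table
#'
#' @param path TSV with a `feature_id` column and one column per rank.
#' @return data frame suitable for the `lineage` slot of [feature_table()].
#' @export
read_lineage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) stop("lineage table needs a feature_id column")
  df
}

#' Read a per-subject numeric table (metadata or saliva block) from TSV
#'
#' @param path TSV with the subject id in the first column.
#' @return data frame with a `subject_id` column.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject id(s)")
  df
}

write_subject_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `metadata.tsv`, `counts.tsv`, `saliva_resting.tsv`,
#' `saliva_stimulated.tsv` and `truth.json` (the planted effects). All tables
#' are tab-separated with a header row and the subject id first.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subject_table(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_feature_table(cohort$microbiome_counts, file.path(dir, "counts.tsv"))
  for (nm in c("resting", "stimulated")) {
    b <- cohort$blocks$blocks[[paste0(nm, "_saliva")]]
    df <- data.frame(subject_id = rownames(b), b, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_subject_table(df, file.path(dir, paste0("saliva_", nm, ".tsv")))
  }
  jsonlite::write_json(
    lapply(cohort$truth, function(e) unclass(e)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Assemble the four predictor blocks from per-subject tables
#'
#' Inner-joins metadata, the two saliva tables and the family-level
#' microbiome table on subject id; subjects missing from any table are
#' dropped with a message (complete-case analysis). The microbiota block is
#' the family relative abundances of the listed families, in list order.
#'
#' @param metadata data frame with `subject_id` plus the clinical columns
#'   `BMI`, `Waist`, `Blood_LPS`, `Age`.
#' @param stimulated,resting saliva data frames (`subject_id` + variables).
#' @param counts a `feature_table` of family-level counts (samples =
#'   subjects).
#' @param families families forming the microbiota block (default the
#'   18-family inventory); families absent from `counts` are filled with
#'   zeros with a warning.
#' @return a `block_set` with blocks `biological_determinants`,
#'   `stimulated_saliva`, `resting_saliva`, `microbiota`.
#' @export
assemble_blocks <- function(metadata, stimulated, resting, counts,
                            families = default_families()) {
  stopifnot(inherits(counts, "feature_table"))
  ids <- Reduce(intersect, list(metadata$subject_id, stimulated$subject_id,
                                resting$subject_id, rownames(counts$counts)))
  if (length(ids) == 0) stop("no subjects shared across all input tables")
  n_all <- length(unique(c(metadata$subject_id, stimulated$subject_id,
                           resting$subject_id, rownames(counts$counts))))
  if (n_all > length(ids)) {
    message(sprintf("assemble_blocks: dropped %d subject(s) missing from at least one table",
                    n_all - length(ids)))
  }
  det_cols <- c("BMI", "Waist", "Blood_LPS", "Age")
  missing_det <- setdiff(det_cols, names(metadata))
  if (length(missing_det) > 0) {
    stop(sprintf("metadata lacks column(s): %s",
                 paste(missing_det, collapse = ", ")))
  }
  det <- as.matrix(metadata[match(ids, metadata$subject_id), det_cols])
  rownames(det) <- ids
  as_block <- function(df) {
    m <- as.matrix(df[match(ids, df$subject_id),
                      setdiff(names(df), "subject_id"), drop = FALSE])
    rownames(m) <- ids
    m
  }
  ra <- relative_abundance(counts$counts[ids, , drop = FALSE])
  attr(ra, "zero_rows") <- NULL
  absent <- setdiff(families, colnames(ra))
  if (length(absent) > 0) {
    warning(sprintf("families absent from count table, filled with zeros: %s",
                    paste(absent, collapse = ", ")))
    ra <- cbind(ra, matrix(0, nrow(ra), length(absent),
                           dimnames = list(ids, absent)))
  }
  block_set(list(biological_determinants = det,
                 stimulated_saliva = as_block(stimulated),
                 resting_saliva = as_block(resting),
                 microbiota = ra[, families, drop = FALSE]))
}

# Subset + class labels for one of the named comparisons.
comparison_design <- function(metadata, comparison, cutoff = 0.5) {
  taste <- classify_taster(metadata$la_threshold, metadata$censored, cutoff)
  switch(comparison,
    NW_vs_O = list(keep = rep(TRUE, nrow(metadata)),
                   y = factor(metadata$group_bmi, levels = c("NW", "O"))),
    T_vs_NT = list(keep = rep(TRUE, nrow(metadata)),
                   y = factor(taste, levels = c("T", "NT"))),
    OT_vs_ONT = {
      keep <- metadata$group_bmi == "O"
      list(keep = keep, y = factor(taste[keep], levels = c("T", "NT")))
    },
    NWNT_vs_ONT = {
      keep <- taste == "NT"
      list(keep = keep,
           y = factor(metadata$group_bmi[keep], levels = c("NW", "O")))
    },
    stop(sprintf("unknown comparison '%s'", comparison))
  )
}

#' Run one discriminant comparison end to end
#'
#' Chains the full analysis for one comparison (`NW_vs_O`, `T_vs_NT`,
#' `OT_vs_ONT` or `NWNT_vs_ONT`): classify tasters from thresholds, compute
#' per-sample Shannon diversity, run the two-class LDA effect-size screen on
#' family abundances, assemble and preprocess the four predictor blocks, fit
#' the MB-PLS-DA model, select components and variables (VIP and correlation
#' loadings), and run Mann-Whitney post-hoc tests. Stage outputs are written
#' as TSV plus a machine-readable `summary.json` when `out_dir` is given.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `metadata`, `counts`, `saliva_stimulated`, `saliva_resting` (file paths),
#'   `comparison` (one of the four names above) and optionally `cutoff`
#'   (default 0.5), `alpha` (0.05), `lda_cutoff` (2.0), `n_boot` (30),
#'   `vip_threshold` (1), `loading_threshold` (0.3), `n_components` (2),
#'   `min_fraction` (0.1), `min_total` (3), `seed`, `out_dir`.
#' @return invisibly, a list with `design`, `diversity`, `lefse`, `model`,
#'   `n_components_interpreted`, `vip_report` and `summary`.
#' @export
run_comparison <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$comparison))
  for (f in c("metadata", "counts", "saliva_stimulated", "saliva_resting")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop(sprintf("config field '%s' must name an existing file", f))
    }
  }
  cutoff <- config$cutoff %||% 0.5
  alpha <- config$alpha %||% 0.05
  lda_cutoff <- config$lda_cutoff %||% 2.0
  n_boot <- config$n_boot %||% 30
  vip_threshold <- config$vip_threshold %||% 1
  loading_threshold <- config$loading_threshold %||% 0.3
  n_components <- config$n_components %||% 2
  min_fraction <- config$min_fraction %||% 0.1
  min_total <- config$min_total %||% 3
  seed <- config$seed %||% 1

  metadata <- stop_stage("read", read_subject_table(config$metadata))
  counts <- stop_stage("read", read_feature_table(config$counts))
  stim <- stop_stage("read", read_subject_table(config$saliva_stimulated))
  rest <- stop_stage("read", read_subject_table(config$saliva_resting))
  if (!"censored" %in% names(metadata)) metadata$censored <- FALSE
  metadata$censored <- metadata$censored %in% c(TRUE, "TRUE", 1L, "1")

  design <- stop_stage("classify",
                       comparison_design(metadata, config$comparison, cutoff))
  if (any(table(design$y) < 2)) {
    stop(sprintf("[stage classify] comparison %s needs >= 2 samples per class (got %s)",
                 config$comparison,
                 paste(table(design$y), collapse = " vs ")))
  }
  meta_sub <- metadata[design$keep, , drop = FALSE]

  counts_f <- stop_stage("filter", filter_low_count_otus(counts, min_total))
  div <- stop_stage("diversity", {
    keep_ids <- intersect(meta_sub$subject_id, rownames(counts_f$counts))
    data.frame(subject_id = keep_ids,
               shannon = alpha_diversity(counts_f$counts[keep_ids, ,
                                                         drop = FALSE]),
               stringsAsFactors = FALSE)
  })

  blocks <- stop_stage("assemble",
                       assemble_blocks(meta_sub, stim, rest, counts_f))
  y <- design$y[match(blocks$sample_ids, meta_sub$subject_id)]

  lefse <- stop_stage("lefse", {
    ra <- blocks$blocks$microbiota
    effect_size_lda(ra, y, alpha = alpha, lda_cutoff = lda_cutoff,
                    n_boot = n_boot, seed = seed)
  })

  model <- stop_stage("fit", fit_mbpls(blocks, y, n_components = n_components))
  a_used <- stop_stage("select", select_components(model, min_fraction))
  vip_rep <- stop_stage("select", {
    sel <- select_variables(model, vip_threshold, loading_threshold)
    ph <- mann_whitney_posthoc(blocks, y)
    merge(sel, ph, by = c("block", "variable"), sort = FALSE)
  })

  summary <- list(
    comparison = config$comparison,
    n_per_class = as.list(table(y)),
    n_components_fitted = model$n_components,
    n_components_interpreted = a_used,
    explained_y_variance = model$explained_y_variance,
    block_importance_comp1 = as.list(model$block_importance[1, ]),
    selected_variables = vip_rep$variable[vip_rep$selected],
    lefse_passed = lefse$taxon[lefse$passed])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(div, file.path(config$out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lefse, file.path(config$out_dir, "lefse_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(vip_rep, file.path(config$out_dir, "vip_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(design = design, diversity = div, lefse = lefse,
                 model = model, n_components_interpreted = a_used,
                 vip_report = vip_rep, summary = summary))
}
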