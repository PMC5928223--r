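#' Default microbiota family inventory
#'
#' The 18 bacterial families (including the `unclassified` bin and the
#' TM7 incertae-sedis family) that make up the microbiota predictor block.
#'
#' @return character vector of 18 family names.
#' @export
default_families <- function() {
  c("Anaeroplasmataceae", "Bacteroidaceae", "Bifidobacteriaceae",
    "Coriobacteriaceae", "Deferribacteraceae", "Desulfovibrionaceae",
    "Eubacteriaceae", "Helicobacteraceae", "Lachnospiraceae",
    "Lactobacillaceae", "Porphyromonadaceae", "Prevotellaceae",
    "Rikenellaceae", "Ruminococcaceae", "Sphingomonadaceae",
    "Sutterellaceae", "TM7_family_incertae_sedis", "unclassified")
}

#' Default Dirichlet base concentrations for the family composition
#'
#' Mean relative abundances typical of a tongue-dorsum community (dominant
#' Lachnospiraceae/Porphyromonadaceae/Prevotellaceae, rare TM7 at about 1%),
#' scaled to a total concentration of ~200 so that between-sample
#' compositional noise is moderate but clearly super-Poisson.
#'
#' @return named positive numeric vector, one concentration per family.
#' @export
default_family_concentrations <- function() {
  mean_pct <- c(
    Anaeroplasmataceae = 1.5, Bacteroidaceae = 8, Bifidobacteriaceae = 3,
    Coriobacteriaceae = 3, Deferribacteraceae = 1.5, Desulfovibrionaceae = 2,
    Eubacteriaceae = 3, Helicobacteraceae = 4, Lachnospiraceae = 16,
    Lactobacillaceae = 5, Porphyromonadaceae = 14, Prevotellaceae = 12,
    Rikenellaceae = 2.5, Ruminococcaceae = 10, Sphingomonadaceae = 2,
    Sutterellaceae = 3, TM7_family_incertae_sedis = 1, unclassified = 8)
  mean_pct / sum(mean_pct) * 200
}

#' Default saliva and clinical variable inventory
#'
#' Variable names of the three non-microbiota predictor blocks: 4 biological
#' determinants, 10 stimulated-saliva and 9 resting-saliva variables
#' (flow, protein, amylase, lipolysis, proteolysis, lysozyme, total
#' antioxidant capacity, carbonic anhydrase VI, cystatin SN, and LPS in
#' stimulated saliva only).
#'
#' @return named list of character vectors: `biological_determinants`,
#'   `stimulated_saliva`, `resting_saliva`.
#' @export
default_saliva_variables <- function() {
  list(
    biological_determinants = c("BMI", "Waist", "Blood_LPS", "Age"),
    stimulated_saliva = c("Flux_S", "Prot_S", "Amyl_S", "Lipo_S", "Proteo_S",
                          "Lyso_S", "TAC_S", "CAVI_S", "Cysta_S", "LPSTot_S"),
    resting_saliva = c("Flux_R", "Prot_R", "Amyl_R", "Lipo_R", "Proteo_R",
                       "Lyso_R", "TAC_R", "CAVI_R", "Cysta_R"))
}

#' Specify a planted taster/non-taster effect
#'
#' @param variable_name variable carrying the effect; must exist in the named
#'   block.
#' @param block_name one of `microbiota`, `stimulated_saliva`,
#'   `resting_saliva`, `biological_determinants`.
#' @param direction `"up_in_taster"` or `"up_in_nontaster"`.
#' @param magnitude positive effect size: log2 fold-change for microbiota
#'   families, standardized mean shift in SD units (log scale) for
#'   saliva/clinical variables.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(variable_name, block_name,
                        direction = c("up_in_taster", "up_in_nontaster"),
                        magnitude) {
  direction <- match.arg(direction)
  stopifnot(is.character(variable_name), length(variable_name) == 1,
            is.character(block_name), length(block_name) == 1,
            is.numeric(magnitude), length(magnitude) == 1, magnitude > 0)
  structure(list(variable_name = variable_name, block_name = block_name,
                 direction = direction, magnitude = magnitude),
            class = "effect_spec")
}

#' Default planted effects
#'
#' The four ground-truth effects used throughout recovery testing, encoding
#' the directions reported for taster discrimination: TM7 family enriched and
#' resting lysozyme higher in tasters; Bacteroidaceae enriched and resting
#' salivary flow higher in non-tasters.
#'
#' @return list of [effect_spec()] objects.
#' @export
default_effects <- function() {
  list(
    effect_spec("TM7_family_incertae_sedis", "microbiota", "up_in_taster", 3),
    effect_spec("Bacteroidaceae", "microbiota", "up_in_nontaster", 3),
    effect_spec("Flux_R", "resting_saliva", "up_in_nontaster", 1.5),
    effect_spec("Lyso_R", "resting_saliva", "up_in_taster", 1.5))
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design: 21 normal-weight and 17 obese subjects,
#' with non-taster fractions of 4/21 and 8/17 respectively.
#'
#' @param n_normal_weight number of normal-weight (NW) subjects (>= 0).
#' @param n_obese number of obese (O) subjects (>= 0).
#' @param frac_nontaster_nw fraction of NW subjects that are non-tasters.
#' @param frac_nontaster_ob fraction of O subjects that are non-tasters.
#' @param seed integer seed; the same spec always generates the same cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal_weight = 21, n_obese = 17,
                        frac_nontaster_nw = 4 / 21, frac_nontaster_ob = 8 / 17,
                        seed = 1) {
  stopifnot(n_normal_weight >= 0, n_obese >= 0,
            frac_nontaster_nw >= 0, frac_nontaster_nw <= 1,
            frac_nontaster_ob >= 0, frac_nontaster_ob <= 1,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_normal_weight = as.integer(n_normal_weight),
                 n_obese = as.integer(n_obese),
                 frac_nontaster_nw = frac_nontaster_nw,
                 frac_nontaster_ob = frac_nontaster_ob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Effects targeting a given block, with the class each effect is raised in.
effects_for_block <- function(effects, block_name) {
  Filter(function(e) e$block_name == block_name, effects)
}

effect_target_class <- function(e) {
  if (e$direction == "up_in_taster") "T" else "NT"
}

check_effects_resolvable <- function(effects, inventory) {
  for (e in effects) {
    if (!e$block_name %in% names(inventory)) {
      stop(sprintf("unknown block '%s' in planted effect for variable '%s'",
                   e$block_name, e$variable_name))
    }
    if (!e$variable_name %in% inventory[[e$block_name]]) {
      stop(sprintf("unknown effect variable '%s' in block '%s'",
                   e$variable_name, e$block_name))
    }
  }
  invisible(TRUE)
}

#' Simulate a microbiome family count table
#'
#' Per sample, the family composition is drawn from a Dirichlet distribution
#' whose base concentrations are multiplied by `2^magnitude` on planted
#' families for samples in the effect's target class; counts are then drawn
#' multinomially at the given sequencing depth, so every sample's counts sum
#' to `depth` exactly.
#'
#' @param n_samples number of samples.
#' @param family_names feature (family) names; column order of the result.
#' @param base_concentrations positive Dirichlet concentrations, one per
#'   family.
#' @param effects list of [effect_spec()] with `block_name = "microbiota"`.
#' @param group_taste `"T"`/`"NT"` label per sample.
#' @param depth sequencing depth per sample (> 0).
#' @param seed optional integer seed.
#' @return a `feature_table` (samples x families) with a family-rank lineage.
#' @export
generate_microbiome_counts <- function(n_samples,
                                       family_names = default_families(),
                                       base_concentrations =
                                         default_family_concentrations(),
                                       effects = list(),
                                       group_taste = rep("T", n_samples),
                                       depth = 50000, seed = NULL) {
  stopifnot(length(base_concentrations) == length(family_names),
            depth > 0, length(group_taste) == n_samples)
  if (any(base_concentrations <= 0)) {
    stop("base concentrations must be positive")
  }
  effects <- effects_for_block(effects, "microbiota")
  check_effects_resolvable(effects, list(microbiota = family_names))
  base <- stats::setNames(as.numeric(base_concentrations), family_names)
  with_seed(seed, {
    counts <- matrix(0L, nrow = n_samples, ncol = length(family_names),
                     dimnames = list(
                       if (n_samples > 0) sprintf("S%03d", seq_len(n_samples)),
                       family_names))
    for (i in seq_len(n_samples)) {
      alpha <- base
      for (e in effects) {
        if (group_taste[i] == effect_target_class(e)) {
          alpha[e$variable_name] <- alpha[e$variable_name] * 2^e$magnitude
        }
      }
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      counts[i, ] <- as.integer(stats::rmultinom(1, size = depth,
                                                 prob = g / sum(g)))
    }
    feature_table(counts,
                  lineage = data.frame(feature_id = family_names,
                                       family = family_names,
                                       stringsAsFactors = FALSE))
  })
}

#' Simulate saliva and clinical predictor blocks
#'
#' Each variable is lognormal with a unit-free baseline (log-scale mean 0,
#' SD 1); planted variables are shifted by `magnitude` SD units on the log
#' scale in the effect's target class. All quantities are flows,
#' concentrations or activities, so positivity is guaranteed by construction.
#'
#' @param n_samples number of samples.
#' @param variables named list of character vectors (one entry per block);
#'   defaults to [default_saliva_variables()].
#' @param effects list of [effect_spec()] targeting these blocks.
#' @param group_taste `"T"`/`"NT"` label per sample.
#' @param seed optional integer seed.
#' @return a `block_set` with one block per entry of `variables`.
#' @export
generate_saliva_blocks <- function(n_samples,
                                   variables = default_saliva_variables(),
                                   effects = list(),
                                   group_taste = rep("T", n_samples),
                                   seed = NULL) {
  stopifnot(is.list(variables), length(group_taste) == n_samples)
  for (nm in names(variables)) {
    if (anyDuplicated(variables[[nm]])) {
      stop(sprintf("duplicate variable name in block '%s'", nm))
    }
  }
  effects <- Filter(function(e) e$block_name %in% names(variables), effects)
  check_effects_resolvable(effects, variables)
  ids <- if (n_samples > 0) sprintf("S%03d", seq_len(n_samples)) else
    character(0)
  with_seed(seed, {
    blocks <- lapply(names(variables), function(nm) {
      vars <- variables[[nm]]
      logm <- matrix(stats::rnorm(n_samples * length(vars)),
                     nrow = n_samples, ncol = length(vars),
                     dimnames = list(ids, vars))
      for (e in effects_for_block(effects, nm)) {
        target <- group_taste == effect_target_class(e)
        logm[target, e$variable_name] <-
          logm[target, e$variable_name] + e$magnitude
      }
      exp(logm)
    })
    names(blocks) <- names(variables)
    block_set(blocks)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces a two-group (normal-weight/obese) cohort with taster/non-taster
#' labels, ascending-series detection thresholds, all four predictor blocks,
#' and the list of planted effects as recoverable ground truth. Taster
#' thresholds are drawn log-uniformly over the series values below the
#' cutoff; non-taster thresholds at or above it, with a fraction censored at
#' the series maximum. BMI is uniform on [19, 25) for NW and [30, 45) for O
#' subjects; waist circumference tracks BMI; blood LPS is lognormal with a
#' +0.5 SD log-scale shift in the obese group.
#'
#' @param spec a [cohort_spec()].
#' @param effects list of [effect_spec()]; defaults to [default_effects()].
#' @param series the detection-threshold ladder (default the 18-solution
#'   series).
#' @param cutoff taster/non-taster cutoff, % wt/wt (default 0.5).
#' @param depth microbiome sequencing depth per sample (default 50000).
#' @param censored_frac fraction of non-tasters censored at the series
#'   maximum (default 0.25).
#' @return An object of class `"synthetic_cohort"`: list with `metadata`
#'   (data frame: subject_id, group_bmi, group_taste, la_threshold, censored,
#'   BMI, Waist, Age, Blood_LPS), `blocks` (a `block_set` with the four
#'   predictor blocks; microbiota as family relative abundances),
#'   `microbiome_counts` (a `feature_table`), `truth` (the planted effects)
#'   and `series`.
#' @export
generate_cohort <- function(spec, effects = default_effects(),
                            series = build_concentration_series(),
                            cutoff = 0.5, depth = 50000,
                            censored_frac = 0.25) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(series, "concentration_series"),
            censored_frac >= 0, censored_frac <= 1)
  inventory <- c(default_saliva_variables(),
                 list(microbiota = default_families()))
  check_effects_resolvable(effects, inventory)

  n <- spec$n_normal_weight + spec$n_obese
  seeds <- child_seeds(spec$seed, 3)
  conc <- series$concentrations
  idx_t <- which(conc < cutoff)
  idx_nt <- which(conc >= cutoff)
  if (length(idx_t) == 0 || length(idx_nt) == 0) {
    stop("cutoff must fall inside the concentration series")
  }

  meta <- with_seed(seeds[1], {
    group_bmi <- rep(c("NW", "O"), c(spec$n_normal_weight, spec$n_obese))
    taste <- character(n)
    for (g in c("NW", "O")) {
      gi <- which(group_bmi == g)
      frac <- if (g == "NW") spec$frac_nontaster_nw else spec$frac_nontaster_ob
      n_nt <- min(length(gi), max(0, round(frac * length(gi))))
      nt_i <- if (n_nt > 0) gi[sample.int(length(gi), n_nt)] else integer(0)
      taste[gi] <- "T"
      taste[nt_i] <- "NT"
    }
    thr <- numeric(n); cens <- logical(n)
    for (i in seq_len(n)) {
      if (taste[i] == "T") {
        thr[i] <- conc[idx_t[sample.int(length(idx_t), 1)]]
      } else if (stats::runif(1) < censored_frac) {
        thr[i] <- max(conc); cens[i] <- TRUE
      } else {
        thr[i] <- conc[idx_nt[sample.int(length(idx_nt), 1)]]
      }
    }
    bmi <- ifelse(group_bmi == "NW", stats::runif(n, 19, 25),
                  stats::runif(n, 30, 45))
    data.frame(
      subject_id = if (n > 0) sprintf("S%03d", seq_len(n)) else character(0),
      group_bmi = group_bmi, group_taste = taste,
      la_threshold = thr, censored = cens,
      BMI = bmi,
      Waist = 22 + 2.3 * bmi + stats::rnorm(n, 0, 3),
      Age = if (n > 0) sample(30:65, n, replace = TRUE) else integer(0),
      stringsAsFactors = FALSE)
  })

  saliva <- generate_saliva_blocks(n, effects = effects,
                                   group_taste = meta$group_taste,
                                   seed = seeds[2])
  # clinical determinants come from the metadata (BMI by group, waist and
  # age derived), except blood LPS which keeps its lognormal draw plus a
  # fixed +0.5 SD log-scale elevation in the obese group
  det <- saliva$blocks$biological_determinants
  det[, "BMI"] <- meta$BMI
  det[, "Waist"] <- meta$Waist
  det[, "Age"] <- meta$Age
  det[, "Blood_LPS"] <- det[, "Blood_LPS"] *
    exp(0.5 * (meta$group_bmi == "O"))
  meta$Blood_LPS <- det[, "Blood_LPS"]

  counts <- generate_microbiome_counts(
    n, effects = effects, group_taste = meta$group_taste, depth = depth,
    seed = seeds[3])
  micro_ra <- relative_abundance(counts)
  attr(micro_ra, "zero_rows") <- NULL

  all_blocks <- list(biological_determinants = det,
                     stimulated_saliva = saliva$blocks$stimulated_saliva,
                     resting_saliva = saliva$blocks$resting_saliva,
                     microbiota = micro_ra)
  if (n > 0) {
    all_blocks <- lapply(all_blocks, function(b) {
      rownames(b) <- meta$subject_id; b
    })
    rownames(counts$counts) <- meta$subject_id
  }

  structure(
    list(metadata = meta, blocks = block_set(all_blocks),
         microbiome_counts = counts, truth = effects, series = series,
         spec = spec, cutoff = cutoff),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$metadata$group_bmi, x$metadata$group_taste)
  cat(sprintf("Synthetic cohort: %d subjects (seed %d)\n",
              nrow(x$metadata), x$spec$seed))
  print(tab)
  cat(sprintf("  planted effects: %d\n", length(x$truth)))
  invisible(x)
}
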