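# Logistic-normal-multinomial simulator for multi-specimen-per-patient
# microbiome studies. A shared per-patient latent profile induces the
# patient-dominant clustering structure that plain Dirichlet-multinomial
# sampling cannot produce; a DM mode (patient_effect_sd = 0) remains
# available for simpler calibration tests.

default_genus_panel <- function(n_genera = 40L) {
  named <- c("Fusobacterium", "Prevotella", "Porphyromonas", "Streptococcus",
             "Neisseria", "Alloprevotella", "Selenomonas", "Parvimonas",
             "Capnocytophaga", "Veillonella", "Gemella", "Haemophilus")
  if (n_genera <= length(named)) return(named[seq_len(n_genera)])
  c(named, sprintf("Genus_%02d", seq_len(n_genera - length(named))))
}

#' Specification of a simulated paired microbiome study
#'
#' Defines the generative model: per patient a log-scale latent profile
#' (base composition + a patient effect shared by all of that patient's
#' specimens + specimen-type effects + planted differential effects), per
#' sample multinomial counts at a log-normally drawn depth, plus sporadic
#' trace spikes for a designated fraction of rare genera (the "sampling
#' bias" the predominance filter is meant to remove).
#'
#' @param n_patients Number of patients (default 10).
#' @param specimen_types Specimen types collected per patient (default
#'   outer tumor, inner tumor, adjacent normal).
#' @param n_genera Panel size (default 40; the first entries carry oral
#'   genus names, the rest synthetic fillers).
#' @param base_log_mean Log-scale base profile, length `n_genera`; default
#'   a geometric ramp spanning roughly 15% down to 0.05% relative
#'   abundance before effects.
#' @param patient_effect_sd SD of the per-patient, per-genus log effect
#'   (default 1.0; 0 switches off patient structure).
#' @param specimen_effects Optional tibble `genus`, `specimen_type`,
#'   `log_fc` of additional specimen-type enrichments.
#' @param planted_differentials Tibble `genus`, `type_a`, `type_b`, `fold`
#'   of planted contrasts: half of `log(fold)` is added to the genus in
#'   `type_a` specimens and subtracted in `type_b` specimens, so the
#'   expected A-over-B fold change equals `fold`. Default plants
#'   Fusobacterium 3-fold toward outer tumor vs adjacent normal,
#'   Streptococcus 3-fold toward adjacent normal, and Prevotella 3-fold
#'   toward inner vs outer tumor.
#' @param depth_mean Mean per-sample total count (default 50000, min 1000).
#' @param depth_sdlog Log-normal SD of depth (default 0.5).
#' @param rare_genus_rate Fraction of the panel that appears only
#'   sporadically at trace abundance (default 0.05).
#' @param seed Integer seed (default 0).
#' @return List of class `microbiome_sim_spec`.
#' @export
microbiome_sim_spec <- function(
    n_patients = 10L,
    specimen_types = c("outer_tumor", "inner_tumor", "adjacent_normal"),
    n_genera = 40L,
    base_log_mean = NULL,
    patient_effect_sd = 1.0,
    specimen_effects = NULL,
    planted_differentials = tibble(
      genus = c("Fusobacterium", "Streptococcus", "Prevotella"),
      type_a = c("outer_tumor", "adjacent_normal", "inner_tumor"),
      type_b = c("adjacent_normal", "outer_tumor", "outer_tumor"),
      fold = c(3, 3, 3)),
    depth_mean = 50000, depth_sdlog = 0.5,
    rare_genus_rate = 0.05, seed = 0L) {
  if (length(specimen_types) == 0L) abort("specimen_types must be non-empty")
  bad <- setdiff(specimen_types, specimen_types())
  if (length(bad)) {
    abort(paste0("unknown specimen type(s): ", paste(bad, collapse = ", ")))
  }
  if (n_patients < 2L) abort("need at least 2 patients")
  if (depth_mean < 1000) abort("depth_mean must be at least 1000")
  if (patient_effect_sd < 0) abort("patient_effect_sd must be >= 0")
  if (rare_genus_rate < 0 || rare_genus_rate >= 1) {
    abort("rare_genus_rate must be in [0, 1)")
  }
  genera <- default_genus_panel(n_genera)
  n_rare <- round(rare_genus_rate * n_genera)
  n_core <- n_genera - n_rare
  if (is.null(base_log_mean)) {
    base_log_mean <- c(seq(log(0.15), log(0.0005), length.out = n_core),
                       rep(-Inf, n_rare))
  }
  if (length(base_log_mean) != n_genera) {
    abort("base_log_mean must have length n_genera")
  }
  if (!is.null(planted_differentials) && nrow(planted_differentials)) {
    planted_differentials <- planted_differentials[
      planted_differentials$type_a %in% specimen_types &
        planted_differentials$type_b %in% specimen_types, ]
    bad <- setdiff(planted_differentials$genus, genera)
    if (length(bad)) {
      abort(paste0("planted genus not in panel: ",
                   paste(bad, collapse = ", ")))
    }
    if (any(planted_differentials$fold <= 0)) {
      abort("planted fold changes must be positive")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), specimen_types = specimen_types,
    n_genera = as.integer(n_genera), genera = genera,
    base_log_mean = base_log_mean, patient_effect_sd = patient_effect_sd,
    specimen_effects = specimen_effects,
    planted_differentials = planted_differentials,
    depth_mean = depth_mean, depth_sdlog = depth_sdlog,
    rare_genus_rate = rare_genus_rate, n_rare = n_rare,
    seed = as.integer(seed)), class = "microbiome_sim_spec")
}

#' Simulate a paired multi-specimen microbiome study
#'
#' Draws the study defined by a [microbiome_sim_spec()]: one sample per
#' patient and specimen type, multinomial counts from the softmax of the
#' latent log profile, log-normal per-sample depths, and sporadic trace
#' spikes for the rare genera. Deterministic given the spec's seed.
#'
#' @param spec A `microbiome_sim_spec`.
#' @return List with `table` (counts `abund_tbl`), `metadata` (sample
#'   metadata tibble), and `truth` (list: genus panel, planted
#'   differentials, patient assignments, per-sample expected relative
#'   compositions, and the generator parameters).
#' @export
simulate_paired_study <- function(spec) {
  stopifnot(inherits(spec, "microbiome_sim_spec"))
  g <- spec$n_genera
  rare_idx <- if (spec$n_rare > 0) seq(g - spec$n_rare + 1L, g) else integer()
  core_idx <- setdiff(seq_len(g), rare_idx)
  eff <- matrix(0, g, length(spec$specimen_types),
                dimnames = list(spec$genera, spec$specimen_types))
  se <- spec$specimen_effects
  if (!is.null(se) && nrow(se)) {
    for (i in seq_len(nrow(se))) {
      eff[se$genus[i], se$specimen_type[i]] <-
        eff[se$genus[i], se$specimen_type[i]] + se$log_fc[i]
    }
  }
  pd <- spec$planted_differentials
  if (!is.null(pd) && nrow(pd)) {
    for (i in seq_len(nrow(pd))) {
      half <- log(pd$fold[i]) / 2
      eff[pd$genus[i], pd$type_a[i]] <- eff[pd$genus[i], pd$type_a[i]] + half
      eff[pd$genus[i], pd$type_b[i]] <- eff[pd$genus[i], pd$type_b[i]] - half
    }
  }
  withr::with_seed(spec$seed, {
    meta <- tidyr::expand_grid(
      patient_id = sprintf("P%02d", seq_len(spec$n_patients)),
      specimen_type = spec$specimen_types) |>
      dplyr::mutate(sample_id = paste0(.data$patient_id, "_",
                                       .data$specimen_type),
                    .before = 1L)
    n_samples <- nrow(meta)
    patient_eff <- matrix(
      stats::rnorm(g * spec$n_patients, 0, spec$patient_effect_sd),
      nrow = g)
    colnames(patient_eff) <- unique(meta$patient_id)
    expected <- matrix(0, g, n_samples,
                       dimnames = list(spec$genera, meta$sample_id))
    counts <- matrix(0L, g, n_samples,
                     dimnames = list(spec$genera, meta$sample_id))
    for (j in seq_len(n_samples)) {
      z <- spec$base_log_mean + patient_eff[, meta$patient_id[j]] +
        eff[, meta$specimen_type[j]]
      p <- numeric(g)
      p[core_idx] <- exp(z[core_idx] - max(z[core_idx]))
      p[core_idx] <- p[core_idx] / sum(p[core_idx])
      if (length(rare_idx)) {
        spikes <- stats::runif(length(rare_idx)) < 0.3
        trace <- ifelse(spikes, stats::runif(length(rare_idx), 5e-5, 5e-4), 0)
        p[rare_idx] <- trace
        p[core_idx] <- p[core_idx] * (1 - sum(trace))
      }
      expected[, j] <- p
      depth <- max(1L, round(stats::rlnorm(1, log(spec$depth_mean),
                                           spec$depth_sdlog)))
      counts[, j] <- stats::rmultinom(1, depth, p)[, 1]
    }
    table <- abundance_table(
      dplyr::bind_cols(tibble(taxon_id = spec$genera),
                       as_tibble(as.data.frame(counts))),
      unit_kind = "counts")
    truth <- list(
      genera = spec$genera,
      planted_differentials = if (is.null(pd)) tibble() else pd,
      patients = meta[, c("sample_id", "patient_id", "specimen_type")],
      expected_composition = as_tibble(as.data.frame(expected),
                                       rownames = NULL) |>
        dplyr::mutate(taxon_id = spec$genera, .before = 1L),
      params = list(n_patients = spec$n_patients,
                    patient_effect_sd = spec$patient_effect_sd,
                    depth_mean = spec$depth_mean,
                    depth_sdlog = spec$depth_sdlog,
                    rare_genus_rate = spec$rare_genus_rate,
                    seed = spec$seed))
    list(table = table, metadata = sample_metadata(meta), truth = truth)
  })
}

#' Specification of one simulated clinical variable
#'
#' @param name Variable name.
#' @param type `"categorical"` or `"continuous"`.
#' @param levels Level names (categorical).
#' @param baseline_probs Level probabilities in the culture-negative group
#'   (categorical; must sum to 1).
#' @param odds_ratios Per-level odds ratios for the culture-positive group
#'   relative to the first (reference) level; length `length(levels)`,
#'   first entry 1. All 1 means independence of the outcome.
#' @param mean_neg,sd_neg,mean_pos,sd_pos Group parameters (continuous).
#' @return A list describing the variable.
#' @export
clinical_variable <- function(name, type = c("categorical", "continuous"),
                              levels = NULL, baseline_probs = NULL,
                              odds_ratios = NULL, mean_neg = 0, sd_neg = 1,
                              mean_pos = 0, sd_pos = 1) {
  type <- match.arg(type)
  if (type == "categorical") {
    if (is.null(levels) || is.null(baseline_probs)) {
      abort("categorical variables need levels and baseline_probs")
    }
    if (abs(sum(baseline_probs) - 1) > 1e-9 || any(baseline_probs <= 0)) {
      abort("baseline_probs must be positive and sum to 1")
    }
    odds_ratios <- odds_ratios %||% rep(1, length(levels))
    if (length(odds_ratios) != length(levels) || any(odds_ratios <= 0)) {
      abort("odds_ratios must be positive, one per level")
    }
  }
  list(name = name, type = type, levels = levels,
       baseline_probs = baseline_probs, odds_ratios = odds_ratios,
       mean_neg = mean_neg, sd_neg = sd_neg,
       mean_pos = mean_pos, sd_pos = sd_pos)
}

default_cohort_variables <- function() {
  list(
    clinical_variable("diabetes", "categorical", c("No", "Yes"),
                      c(0.88, 0.12)),
    clinical_variable("smoking", "categorical", c("No", "Yes"),
                      c(0.52, 0.48)),
    clinical_variable("t_staging", "categorical", c("T1/T2", "T3", "T4"),
                      c(0.41, 0.26, 0.33)),
    clinical_variable("cervical_lymph_node_metastasis", "categorical",
                      c("No", "Yes"), c(0.49, 0.51)),
    clinical_variable("age", "continuous",
                      mean_neg = 52.4, sd_neg = 12.5,
                      mean_pos = 52.4, sd_pos = 12.5))
}

#' Simulate a clinical cohort with known associations
#'
#' Draws the culture outcome at a stated prevalence, then each categorical
#' variable conditionally on outcome: negatives follow the baseline level
#' probabilities, positives follow those probabilities with each level's
#' odds multiplied by its odds ratio (all ratios 1 gives exact
#' independence). Continuous variables are normal with per-group
#' parameters.
#'
#' @param n_patients Cohort size (min 20; default 218).
#' @param variables List of [clinical_variable()] specs (default: a
#'   Table-1-like null panel, every odds ratio 1).
#' @param prevalence Positive-culture probability (default 0.482).
#' @param seed Integer seed (default 0).
#' @return List with `cohort` (patient-level tibble) and `truth` (tibble of
#'   per-level odds ratios, plus the prevalence).
#' @export
simulate_clinical_cohort <- function(n_patients = 218L, variables = NULL,
                                     prevalence = 0.482, seed = 0L) {
  if (n_patients < 20L) abort("need at least 20 patients")
  if (prevalence <= 0 || prevalence >= 1) {
    abort("prevalence must be in (0, 1)")
  }
  variables <- variables %||% default_cohort_variables()
  withr::with_seed(seed, {
    outcome <- ifelse(stats::runif(n_patients) < prevalence,
                      "positive", "negative")
    cohort <- tibble(
      patient_id = sprintf("SIM%04d", seq_len(n_patients)),
      culture_result = factor(outcome, levels = c("negative", "positive")))
    truth_rows <- list()
    for (v in variables) {
      if (v$type == "categorical") {
        p_neg <- v$baseline_probs
        odds <- p_neg / p_neg[1] * v$odds_ratios
        p_pos <- odds / sum(odds)
        draw <- function(n, p) sample(v$levels, n, replace = TRUE, prob = p)
        vals <- character(n_patients)
        vals[outcome == "negative"] <- draw(sum(outcome == "negative"), p_neg)
        vals[outcome == "positive"] <- draw(sum(outcome == "positive"), p_pos)
        cohort[[v$name]] <- factor(vals, levels = v$levels)
        truth_rows[[v$name]] <- tibble(variable = v$name, level = v$levels,
                                       odds_ratio = v$odds_ratios)
      } else {
        vals <- numeric(n_patients)
        vals[outcome == "negative"] <-
          stats::rnorm(sum(outcome == "negative"), v$mean_neg, v$sd_neg)
        vals[outcome == "positive"] <-
          stats::rnorm(sum(outcome == "positive"), v$mean_pos, v$sd_pos)
        cohort[[v$name]] <- vals
        truth_rows[[v$name]] <- tibble(
          variable = v$name, level = NA_character_,
          odds_ratio = NA_real_)
      }
    }
    list(cohort = cohort,
         truth = list(prevalence = prevalence,
                      variables = dplyr::bind_rows(truth_rows)))
  })
}

#' Write simulation truth to JSON
#'
#' Round-trips losslessly through [read_truth()]. Writing fails if a
#' planted differential references a genus missing from the truth's panel.
#'
#' @param truth Truth list from [simulate_paired_study()] (or any list of
#'   tibbles/scalars).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  pd <- truth$planted_differentials
  if (!is.null(pd) && nrow(pd) && !is.null(truth$genera)) {
    bad <- setdiff(pd$genus, truth$genera)
    if (length(bad)) {
      abort(paste0("truth references absent genus: ",
                   paste(bad, collapse = ", ")))
    }
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the truth list with data frames restored
#'   to tibbles.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(x) {
    if (is.data.frame(x)) return(as_tibble(x))
    if (is.list(x)) {
      df_like <- length(x) > 0 && all(vapply(x, is.atomic, logical(1))) &&
        length(unique(lengths(x))) == 1L && all(lengths(x) > 1L) &&
        !is.null(names(x))
      if (df_like) return(as_tibble(x))
      return(lapply(x, restore))
    }
    x
  }
  restore(raw)
}
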