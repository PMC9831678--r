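#' Subset an abundance table to selected samples
#'
#' @param table An `abund_tbl`.
#' @param ids Sample ids to keep, in the requested order.
#' @return An `abund_tbl` over the selected samples.
#' @export
select_samples <- function(table, ids) {
  stopifnot(inherits(table, "abund_tbl"))
  missing_ids <- setdiff(ids, sample_ids(table))
  if (length(missing_ids)) {
    abort(paste0("sample(s) not in table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  abundance_table(as_tibble(table)[, c("taxon_id", ids)],
                  unit_kind = unit_kind(table))
}

#' Run a full two-group contrast
#'
#' Wires one specimen-type contrast through the whole pipeline: per-sample
#' Shannon diversity with the rank-based group test, the Bray-Curtis
#' distance matrix with PCoA and PERMANOVA, the composition summary, and —
#' when at least 3 complete patient pairs exist — the paired differential
#' report. All artifacts plus a run manifest (package version, seed, config
#' hash, per-stage sample counts) are written to `out_dir` as TSV/JSON.
#'
#' @param table An `abund_tbl` (counts or relative).
#' @param metadata Metadata tibble covering the table's samples.
#' @param group_a,group_b Specimen types to contrast (A vs B).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param group_var Metadata column defining the groups (default
#'   `"specimen_type"`).
#' @param n_permutations,seed Permutation settings for PERMANOVA.
#' @param n_axes PCoA axes to retain.
#' @param fold_threshold,majority_fraction,min_mean_abundance,
#'   min_detection_fraction,pseudocount Paired-caller settings, as in
#'   [call_differential()].
#' @return (Invisibly) a list with `alpha`, `alpha_test`, `dist`, `pcoa`,
#'   `permanova`, `composition`, `paired` (or `NULL`), and `manifest`.
#' @export
run_contrast <- function(table, metadata, group_a, group_b, out_dir = NULL,
                         group_var = "specimen_type",
                         n_permutations = 999L, seed = 0L, n_axes = 2L,
                         fold_threshold = 2, majority_fraction = 0.5,
                         min_mean_abundance = 0.001,
                         min_detection_fraction = 0.5, pseudocount = 1e-5) {
  metadata <- resolve_metadata(metadata, table)
  if (!group_var %in% names(metadata)) {
    abort(paste0("metadata lacks the grouping column: ", group_var))
  }
  grp <- metadata[[group_var]]
  in_a <- metadata$sample_id[grp == group_a]
  in_b <- metadata$sample_id[grp == group_b]
  if (length(in_a) < 3L || length(in_b) < 3L) {
    abort(sprintf(
      "contrast '%s' (%d samples) vs '%s' (%d samples) needs >= 3 per group",
      group_a, length(in_a), group_b, length(in_b)))
  }
  ids <- c(in_a, in_b)
  sub <- select_samples(table, ids)
  sub_meta <- metadata[match(ids, metadata$sample_id), ]
  labels <- c(rep(group_a, length(in_a)), rep(group_b, length(in_b)))

  alpha <- alpha_diversity(sub) |>
    dplyr::mutate(group = labels)
  alpha_test <- alpha_group_test(alpha$shannon[alpha$group == group_a],
                                 alpha$shannon[alpha$group == group_b])
  dm <- distance_matrix(sub)
  ord <- pcoa(dm, n_axes = n_axes)
  pmv <- permanova(dm, labels, n_permutations = n_permutations, seed = seed)
  comp <- composition_summary(sub, sub_meta, group_by = group_var)

  paired <- tryCatch({
    pset <- paired_specimen_set(sub, sub_meta, group_a, group_b)
    if (nrow(pset$pairs) < 3L) {
      inform(sprintf(
        "paired analysis skipped: only %d complete pair(s) for %s vs %s",
        nrow(pset$pairs), group_a, group_b))
      NULL
    } else {
      call_differential(pset, fold_threshold = fold_threshold,
                        majority_fraction = majority_fraction,
                        min_mean_abundance = min_mean_abundance,
                        min_detection_fraction = min_detection_fraction,
                        pseudocount = pseudocount)
    }
  }, error = function(e) {
    inform(paste0("paired analysis skipped: ", conditionMessage(e)))
    NULL
  })

  config <- list(group_var = group_var, group_a = group_a, group_b = group_b,
                 n_permutations = n_permutations, seed = seed,
                 n_axes = n_axes, fold_threshold = fold_threshold,
                 majority_fraction = majority_fraction,
                 min_mean_abundance = min_mean_abundance,
                 min_detection_fraction = min_detection_fraction,
                 pseudocount = pseudocount)
  manifest <- list(
    package = "oromicro",
    version = as.character(utils::packageVersion("oromicro")),
    config = config, config_hash = rlang::hash(config),
    n_samples = list(total = length(ids), group_a = length(in_a),
                     group_b = length(in_b)),
    n_taxa = nrow(sub),
    n_pairs = if (is.null(paired)) 0L else paired$n_pairs[1])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"),
                     progress = FALSE)
    write_test_result(alpha_test, file.path(out_dir, "alpha_test.json"))
    write_distance_matrix(dm, file.path(out_dir, "bray_curtis.tsv"))
    write_ordination(ord, file.path(out_dir, "pcoa.tsv"))
    write_test_result(pmv, file.path(out_dir, "permanova.json"))
    readr::write_tsv(comp, file.path(out_dir, "composition.tsv"),
                     progress = FALSE)
    if (!is.null(paired)) {
      write_paired_diff(paired,
                        file.path(out_dir, "paired_differential.tsv"))
      readr::write_tsv(summarize_calls(paired),
                       file.path(out_dir, "paired_summary.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(alpha = alpha, alpha_test = alpha_test, dist = dm,
                 pcoa = ord, permanova = pmv, composition = comp,
                 paired = paired, manifest = manifest))
}

#' Run the clinicopathology association screen
#'
#' Produces a published-table-style report: the categorical association
#' screen, the continuous rows (patient-level t-tests when numeric columns
#' exist, summary-statistic t-tests when a summary tibble is supplied), and
#' the cohort summary lines.
#'
#' @param cohort Patient-level tibble with `culture_result`; or `NULL` with
#'   `fixture = "table1"` to use the packaged 218-patient cohort.
#' @param fixture Name of a packaged fixture (`"table1"`) or `NULL`.
#' @param continuous Optional continuous-summary tibble
#'   ([table1_continuous()] layout); defaults to the fixture's when
#'   `fixture = "table1"`.
#' @param out_dir Output directory or `NULL`.
#' @param variables Passed to [association_screen()].
#' @return (Invisibly) list with `screen` (categorical + continuous rows),
#'   `summary` (from [cohort_summary()]), and `significant` (character
#'   vector of flagged variables).
#' @export
run_clinical <- function(cohort = NULL, fixture = NULL, continuous = NULL,
                         out_dir = NULL, variables = NULL) {
  if (is.null(cohort)) {
    if (!identical(fixture, "table1")) {
      abort("provide a cohort or fixture = \"table1\"")
    }
    cohort <- table1_cohort()
    continuous <- continuous %||% table1_continuous()
  }
  screen <- association_screen(cohort, variables = variables)
  if (!is.null(continuous)) {
    nn <- sum(cohort$culture_result == "negative")
    np <- sum(cohort$culture_result == "positive")
    screen <- dplyr::bind_rows(
      screen, screen_continuous_summary(continuous, n_neg = nn, n_pos = np))
  }
  summary <- cohort_summary(cohort, continuous = continuous)
  significant <- screen$variable[screen$significant]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(screen, file.path(out_dir, "association_screen.tsv"),
                     progress = FALSE)
    readr::write_tsv(summary$categorical,
                     file.path(out_dir, "cohort_counts.tsv"),
                     progress = FALSE)
    lines <- c(
      sprintf("Cohort: %d patients (%s)", summary$n_total,
              paste(sprintf("%s n = %d", summary$n_by_outcome$culture_result,
                            summary$n_by_outcome$n), collapse = ", ")),
      sprintf("Significant at two-tailed 0.05: %s",
              if (length(significant)) paste(significant, collapse = ", ")
              else "none"))
    writeLines(lines, file.path(out_dir, "summary.txt"))
  }
  invisible(list(screen = screen, summary = summary,
                 significant = significant))
}
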