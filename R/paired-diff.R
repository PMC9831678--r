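#' Build a matched-pair specimen set for two groups
#'
#' Pairs specimens of two types (e.g. outer tumor vs adjacent normal) within
#' each patient. Each patient contributes at most one pair; when a patient
#' has several specimens of one type the lexicographically earliest
#' `sample_id` is used and a warning is emitted, keeping the pairing
#' deterministic. Patients lacking either specimen type are dropped.
#'
#' @param table An `abund_tbl` (counts are total-sum scaled to relative
#'   abundance, the scale on which fold changes are defined).
#' @param metadata Metadata tibble covering the table's samples.
#' @param group_a,group_b Specimen types to contrast; fold changes are
#'   reported as A over B.
#' @return Object of class `paired_set`: list with `pairs` (tibble:
#'   `patient_id`, `sample_a`, `sample_b`), `group_labels`, and `abundance`
#'   (relative `abund_tbl` restricted to the paired samples).
#' @export
paired_specimen_set <- function(table, metadata, group_a, group_b) {
  if (group_a == group_b) abort("group_a and group_b must differ")
  metadata <- resolve_metadata(metadata, table)
  pick <- function(type) {
    sub <- metadata[metadata$specimen_type == type, ]
    if (nrow(sub) == 0L) {
      return(tibble(patient_id = character(), sample_id = character()))
    }
    dup <- unique(sub$patient_id[duplicated(sub$patient_id)])
    if (length(dup)) {
      warn(sprintf(
        "patient(s) with multiple '%s' specimens, keeping earliest sample_id: %s",
        type, paste(dup, collapse = ", ")))
    }
    sub |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(sample_id = min(.data$sample_id), .groups = "drop")
  }
  a <- pick(group_a); b <- pick(group_b)
  pairs <- dplyr::inner_join(a, b, by = "patient_id",
                             suffix = c("_a", "_b")) |>
    dplyr::rename(sample_a = "sample_id_a", sample_b = "sample_id_b") |>
    dplyr::arrange(.data$patient_id)
  if (nrow(pairs) == 0L) {
    abort(sprintf("no patient has both '%s' and '%s' specimens",
                  group_a, group_b))
  }
  rel <- to_relative(table)
  keep <- c("taxon_id", pairs$sample_a, pairs$sample_b)
  structure(list(pairs = pairs,
                 group_labels = c(a = group_a, b = group_b),
                 abundance = abundance_table(as_tibble(rel)[, keep],
                                             unit_kind = "relative")),
            class = "paired_set")
}

#' @export
print.paired_set <- function(x, ...) {
  cat(sprintf("# Paired specimen set: %d pairs, %s (A) vs %s (B), %d genera\n",
              nrow(x$pairs), x$group_labels[["a"]], x$group_labels[["b"]],
              nrow(x$abundance)))
  print(x$pairs, ...)
  invisible(x)
}

#' Filter to predominant genera shared by both groups
#'
#' The alignment-based analysis considers only predominant genera found in
#' both specimen groups; rare genera and genera specific to one group only
#' are treated as sampling bias and removed. A genus is kept iff its mean
#' relative abundance reaches `min_mean_abundance` in group A samples AND in
#' group B samples, and it is detected (abundance > 0) in at least
#' `min_detection_fraction` of the samples of EACH group.
#'
#' @param pset A `paired_set`.
#' @param min_mean_abundance Mean relative-abundance floor per group,
#'   in (0, 1); default 0.001 (0.1%).
#' @param min_detection_fraction Detection-prevalence floor per group,
#'   in (0, 1); default 0.5.
#' @return Character vector of genus ids passing the filter, in table order.
#' @export
filter_predominant_shared <- function(pset, min_mean_abundance = 0.001,
                                      min_detection_fraction = 0.5) {
  stopifnot(inherits(pset, "paired_set"))
  if (min_mean_abundance <= 0 || min_mean_abundance >= 1) {
    abort("min_mean_abundance must be in (0, 1)")
  }
  if (min_detection_fraction <= 0 || min_detection_fraction >= 1) {
    abort("min_detection_fraction must be in (0, 1)")
  }
  m <- abund_matrix(pset$abundance)
  ma <- m[, pset$pairs$sample_a, drop = FALSE]
  mb <- m[, pset$pairs$sample_b, drop = FALSE]
  keep <- rowMeans(ma) >= min_mean_abundance &
    rowMeans(mb) >= min_mean_abundance &
    rowMeans(ma > 0) >= min_detection_fraction &
    rowMeans(mb > 0) >= min_detection_fraction
  rownames(m)[keep]
}

#' Matched-pair fold changes for one genus
#'
#' Per pair, the ratio (a + pseudocount) / (b + pseudocount) of the genus's
#' relative abundances in the pair's group-A and group-B samples. The
#' additive pseudocount keeps the ratio finite when the genus is absent from
#' one specimen, and swapping the groups maps every ratio to its exact
#' reciprocal.
#'
#' @param pset A `paired_set`.
#' @param genus Genus id present in the table.
#' @param pseudocount Additive relative-abundance constant > 0
#'   (default 1e-5).
#' @return Numeric vector of fold changes, one per pair, in pair order.
#' @export
paired_fold_changes <- function(pset, genus, pseudocount = 1e-5) {
  stopifnot(inherits(pset, "paired_set"))
  if (pseudocount <= 0) abort("pseudocount must be positive")
  m <- abund_matrix(pset$abundance)
  if (!genus %in% rownames(m)) {
    abort(paste0("genus not in abundance table: ", genus))
  }
  a <- m[genus, pset$pairs$sample_a]
  b <- m[genus, pset$pairs$sample_b]
  unname((a + pseudocount) / (b + pseudocount))
}

#' Call differential genera from matched pairs
#'
#' The two-fold matched-pair rule: after restricting to predominant shared
#' genera, a genus is called enriched in a group when at least a
#' `fold_threshold`-fold relative-abundance change in that direction occurs
#' in most matched pairs. "Most" is a supporting-pair fraction strictly
#' greater than `majority_fraction`, with the opposing direction capped at
#' `1 - majority_fraction` so a genus can never be enriched both ways.
#' Exchanging the two groups flips every call and inverts every fold change.
#'
#' @param pset A `paired_set` with at least 3 pairs.
#' @param fold_threshold Fold-change threshold > 1 (default 2).
#' @param majority_fraction Required supporting-pair fraction, in
#'   \[0.5, 1); the comparison is strict, so the default 0.5 means
#'   "strictly more than half of pairs".
#' @param min_mean_abundance,min_detection_fraction Passed to
#'   [filter_predominant_shared()].
#' @param pseudocount Passed to [paired_fold_changes()].
#' @return Tibble of class `paired_diff`, one row per genus: `genus`,
#'   `kept_after_filter`, `call` (one of `enriched_in_A`, `enriched_in_B`,
#'   `not_different`, `filtered_out`), `n_pairs`, `n_support_a`,
#'   `n_support_b`, `median_fold_change`, and the per-pair `fold_changes`
#'   list-column. The parameters are echoed in the `params` attribute.
#' @export
call_differential <- function(pset, fold_threshold = 2,
                              majority_fraction = 0.5,
                              min_mean_abundance = 0.001,
                              min_detection_fraction = 0.5,
                              pseudocount = 1e-5) {
  stopifnot(inherits(pset, "paired_set"))
  n_pairs <- nrow(pset$pairs)
  if (n_pairs < 3L) abort("need at least 3 matched pairs")
  if (fold_threshold <= 1) abort("fold_threshold must be > 1")
  if (majority_fraction < 0.5 || majority_fraction >= 1) {
    abort("majority_fraction must be in [0.5, 1)")
  }
  kept <- filter_predominant_shared(pset, min_mean_abundance,
                                    min_detection_fraction)
  genera <- taxon_ids(pset$abundance)
  rows <- purrr::map(genera, function(g) {
    if (!g %in% kept) {
      return(tibble(genus = g, kept_after_filter = FALSE,
                    call = "filtered_out", n_pairs = n_pairs,
                    n_support_a = NA_integer_, n_support_b = NA_integer_,
                    median_fold_change = NA_real_,
                    fold_changes = list(NULL)))
    }
    fc <- paired_fold_changes(pset, g, pseudocount)
    n_a <- sum(fc >= fold_threshold)
    n_b <- sum(fc <= 1 / fold_threshold)
    frac_a <- n_a / n_pairs
    frac_b <- n_b / n_pairs
    call <- if (frac_a > majority_fraction &&
                frac_b <= 1 - majority_fraction) {
      "enriched_in_A"
    } else if (frac_b > majority_fraction &&
               frac_a <= 1 - majority_fraction) {
      "enriched_in_B"
    } else {
      "not_different"
    }
    tibble(genus = g, kept_after_filter = TRUE, call = call,
           n_pairs = n_pairs, n_support_a = n_a, n_support_b = n_b,
           median_fold_change = median(fc), fold_changes = list(fc))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- list(
    group_a = pset$group_labels[["a"]], group_b = pset$group_labels[["b"]],
    fold_threshold = fold_threshold, majority_fraction = majority_fraction,
    min_mean_abundance = min_mean_abundance,
    min_detection_fraction = min_detection_fraction,
    pseudocount = pseudocount)
  class(out) <- c("paired_diff", class(out))
  out
}

#' Ranked report of enriched genera per group
#'
#' Orders enriched calls deterministically: by supporting-pair count, then
#' by fold-change magnitude in the call's direction (reciprocal for group
#' B), then lexicographically by genus name.
#'
#' @param results A `paired_diff` tibble from [call_differential()].
#' @return Tibble with columns `group`, `genus`, `n_support`,
#'   `median_fold_change`, `rank`.
#' @export
summarize_calls <- function(results) {
  stopifnot(inherits(results, "paired_diff"))
  params <- attr(results, "params")
  enr <- results[results$call %in% c("enriched_in_A", "enriched_in_B"), ]
  if (nrow(enr) == 0L) {
    return(tibble(group = character(), genus = character(),
                  n_support = integer(), median_fold_change = numeric(),
                  rank = integer()))
  }
  enr |>
    dplyr::mutate(
      group = ifelse(.data$call == "enriched_in_A",
                     params$group_a, params$group_b),
      n_support = ifelse(.data$call == "enriched_in_A",
                         .data$n_support_a, .data$n_support_b),
      effect = ifelse(.data$call == "enriched_in_A",
                      .data$median_fold_change,
                      1 / .data$median_fold_change)) |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(dplyr::desc(.data$n_support), dplyr::desc(.data$effect),
                   .data$genus, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("group", "genus", "n_support", "median_fold_change",
                  "rank")
}

#' Write a paired differential result to TSV
#'
#' Columns: genus, call, n_pairs, n_support_a, n_support_b,
#' median_fold_change, and the per-pair fold changes as a semicolon list.
#'
#' @param results A `paired_diff` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_diff <- function(results, path) {
  stopifnot(inherits(results, "paired_diff"))
  flat <- as_tibble(results) |>
    dplyr::mutate(fold_changes = purrr::map_chr(
      .data$fold_changes,
      function(fc) if (is.null(fc)) "" else
        paste(format(fc, digits = 8, trim = TRUE), collapse = ";")))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
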