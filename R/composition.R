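#' Mean composition per sample group
#'
#' Taxonomy bar-plot style summary: for each group, the mean over its
#' samples of the per-sample relative abundances (so every sample carries
#' equal weight regardless of sequencing depth, and each group's summary
#' sums to 1). Taxa can be collapsed to a higher rank via `level_map`, and
#' minor taxa beyond the overall top `top_k` can be pooled into `"Other"`.
#'
#' @param table An `abund_tbl`; counts are total-sum scaled first.
#' @param metadata Metadata tibble covering every sample in the table.
#' @param group_by Name of the metadata column to group by (default
#'   `"specimen_type"`).
#' @param level_map Optional named character vector mapping `taxon_id` to a
#'   higher rank (e.g. genus to phylum); taxa missing from the map are
#'   assigned `"Unclassified"` with a warning. `NULL` keeps taxa as-is.
#' @param top_k Optional integer: keep the `top_k` taxa with the highest
#'   overall mean abundance and pool the rest into `"Other"`.
#' @return Tibble with columns `group`, `taxon`, `mean_abundance`; each
#'   group's abundances sum to 1.
#' @export
composition_summary <- function(table, metadata, group_by = "specimen_type",
                                level_map = NULL, top_k = NULL) {
  metadata <- resolve_metadata(metadata, table)
  if (!group_by %in% names(metadata)) {
    abort(paste0("unknown metadata column: ", group_by))
  }
  rel <- to_relative(table)
  long <- abundance_long(rel)
  if (!is.null(level_map)) {
    unmapped <- setdiff(unique(long$taxon_id), names(level_map))
    if (length(unmapped)) {
      warn(paste0("taxa missing from level_map, assigned 'Unclassified': ",
                  paste(unmapped, collapse = ", ")))
    }
    long$taxon_id <- unname(level_map[long$taxon_id])
    long$taxon_id[is.na(long$taxon_id)] <- "Unclassified"
  }
  groups <- metadata[, c("sample_id", group_by)]
  names(groups)[2] <- "group"
  out <- long |>
    dplyr::inner_join(groups, by = "sample_id") |>
    dplyr::group_by(.data$group, .data$sample_id, taxon = .data$taxon_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$group, .data$taxon) |>
    dplyr::summarise(mean_abundance = mean(.data$abundance),
                     .groups = "drop")
  if (!is.null(top_k)) {
    keep <- out |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(overall = mean(.data$mean_abundance)) |>
      dplyr::slice_max(.data$overall, n = top_k, with_ties = FALSE) |>
      dplyr::pull(.data$taxon)
    out <- out |>
      dplyr::mutate(taxon = ifelse(.data$taxon %in% keep,
                                   .data$taxon, "Other")) |>
      dplyr::group_by(.data$group, .data$taxon) |>
      dplyr::summarise(mean_abundance = sum(.data$mean_abundance),
                       .groups = "drop")
  }
  dplyr::arrange(out, .data$group, dplyr::desc(.data$mean_abundance))
}
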