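#' Allowed specimen types
#'
#' The six specimen types collected per patient in a multi-site oral-cancer
#' sampling design.
#' @return Character vector of allowed `specimen_type` values.
#' @export
specimen_types <- function() {
  c("saliva", "swab", "outer_tumor", "inner_tumor",
    "adjacent_normal", "lymph_node")
}

.meta_levels <- list(
  t_stage = c("T1", "T2", "T3", "T4", "unknown"),
  n_stage = c("N0", "N1", "N2", "N3", "unknown"),
  ene = c("negative", "positive", "unknown"),
  lymphatic_metastasis = c("yes", "no", "unknown"),
  culture_result = c("negative", "positive", "unknown")
)

#' Validate per-sample metadata
#'
#' Checks sample-id uniqueness, specimen-type values, and the clinical
#' enums; blank or missing clinical values are mapped to `"unknown"` (missing
#' values are excluded per analysis, never imputed).
#'
#' @param x Data frame with at least `sample_id`, `patient_id`,
#'   `specimen_type`; optional clinical columns `t_stage`, `n_stage`, `ene`,
#'   `lymphatic_metastasis`, `culture_result`.
#' @return A validated metadata tibble with all clinical columns present.
#' @export
sample_metadata <- function(x) {
  x <- as_tibble(x)
  req <- c("sample_id", "patient_id", "specimen_type")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    abort(paste0("metadata missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  x$patient_id <- as.character(x$patient_id)
  x$specimen_type <- as.character(x$specimen_type)
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(paste0("duplicated sample id(s) in metadata: ",
                 paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(x$specimen_type), specimen_types())
  if (length(bad)) {
    abort(sprintf("unrecognized specimen_type value(s): %s; allowed: %s",
                  paste(bad, collapse = ", "),
                  paste(specimen_types(), collapse = ", ")))
  }
  for (col in names(.meta_levels)) {
    if (!col %in% names(x)) {
      x[[col]] <- "unknown"
    } else {
      v <- as.character(x[[col]])
      v[is.na(v) | v == ""] <- "unknown"
      bad <- setdiff(unique(v), .meta_levels[[col]])
      if (length(bad)) {
        abort(sprintf("invalid %s value(s): %s; allowed: %s", col,
                      paste(bad, collapse = ", "),
                      paste(.meta_levels[[col]], collapse = ", ")))
      }
      x[[col]] <- v
    }
  }
  x[, c(req, names(.meta_levels))]
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `patient_id`, `specimen_type` and optional clinical columns.
#' @return A validated metadata tibble (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  sample_metadata(raw)
}

#' Write sample metadata to TSV
#' @param x Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# Resolve metadata rows against an abundance table. Samples present in the
# metadata but absent from the table are dropped with a warning; table
# samples missing from the metadata are an error at analysis time.
resolve_metadata <- function(metadata, table) {
  metadata <- sample_metadata(metadata)
  ids <- sample_ids(table)
  missing_meta <- setdiff(ids, metadata$sample_id)
  if (length(missing_meta)) {
    abort(paste0("abundance-table sample(s) absent from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  extra <- setdiff(metadata$sample_id, ids)
  if (length(extra)) {
    warn(paste0("metadata sample(s) absent from abundance table, dropped: ",
                paste(extra, collapse = ", ")))
    metadata <- metadata[metadata$sample_id %in% ids, ]
  }
  metadata[match(ids, metadata$sample_id), ]
}
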