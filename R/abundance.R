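#' Construct a genus abundance table
#'
#' An abundance table is a tibble with one row per taxon and one numeric
#' column per sample, plus a leading `taxon_id` character column. The
#' `unit_kind` attribute records whether the body holds raw counts or
#' relative abundances (per-sample fractions summing to 1). Orientation is
#' fixed as taxa-by-samples; transposed input is never auto-detected because
#' silent transposition is a classic pipeline bug.
#'
#' @param x A data frame whose first column is `taxon_id` and whose remaining
#'   columns are numeric per-sample abundances.
#' @param unit_kind Either `"counts"` or `"relative"`.
#' @return A tibble of class `abund_tbl` with attribute `unit_kind`.
#' @examples
#' tbl <- abundance_table(
#'   data.frame(taxon_id = c("Fusobacterium", "Streptococcus"),
#'              s1 = c(10, 30), s2 = c(5, 5)),
#'   unit_kind = "counts")
#' to_relative(tbl)
#' @export
abundance_table <- function(x, unit_kind = c("counts", "relative")) {
  unit_kind <- match.arg(unit_kind)
  x <- as_tibble(x)
  if (ncol(x) < 2L || names(x)[1L] != "taxon_id") {
    abort("first column must be `taxon_id`, followed by one column per sample")
  }
  x$taxon_id <- as.character(x$taxon_id)
  if (anyDuplicated(x$taxon_id)) {
    dup <- unique(x$taxon_id[duplicated(x$taxon_id)])
    abort(paste0("duplicated taxon id(s): ", paste(dup, collapse = ", ")))
  }
  sample_ids <- names(x)[-1L]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(paste0("duplicated sample id(s): ", paste(dup, collapse = ", ")))
  }
  for (s in sample_ids) {
    if (!is.numeric(x[[s]])) {
      abort(paste0("non-numeric abundance column: ", s))
    }
    if (anyNA(x[[s]])) abort(paste0("missing value in sample ", s))
    if (any(x[[s]] < 0)) abort(paste0("negative abundance in sample ", s))
  }
  if (unit_kind == "relative") {
    sums <- vapply(sample_ids, function(s) sum(x[[s]]), numeric(1))
    bad <- sample_ids[abs(sums - 1) > 1e-9]
    if (length(bad)) {
      abort(paste0("relative-abundance column(s) not summing to 1: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(x, unit_kind = unit_kind,
            class = c("abund_tbl", class(as_tibble(x))))
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x) - 1L, unit_kind(x)))
  NextMethod()
}

#' Unit kind of an abundance table
#'
#' @param x An `abund_tbl`.
#' @return `"counts"` or `"relative"`.
#' @export
unit_kind <- function(x) attr(x, "unit_kind", exact = TRUE) %||% "counts"

#' Sample identifiers of an abundance table
#' @param x An `abund_tbl`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(x) names(x)[-1L]

#' Taxon identifiers of an abundance table
#' @param x An `abund_tbl`.
#' @return Character vector of taxon ids in row order.
#' @export
taxon_ids <- function(x) x$taxon_id

#' Abundance table as a taxa-by-samples matrix
#' @param x An `abund_tbl`.
#' @return Numeric matrix with taxon ids as rownames and sample ids as colnames.
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$taxon_id
  m
}

#' Read a genus abundance table from TSV
#'
#' Expects a tab-separated file whose first header cell is `taxon_id` and
#' whose remaining header cells are sample ids; the body is numeric.
#'
#' @param path Path to the TSV file.
#' @param unit_kind `"counts"` (integer body) or `"relative"` (columns sum
#'   to 1).
#' @return A validated [abundance_table()].
#' @export
read_abundance_table <- function(path, unit_kind = c("counts", "relative")) {
  unit_kind <- match.arg(unit_kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L || names(raw)[1L] != "taxon_id") {
    abort(paste0(path, ": first header cell must be 'taxon_id'"))
  }
  for (j in seq(2L, ncol(raw))) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      abort(sprintf("%s: non-numeric cell at taxon '%s', sample '%s': '%s'",
                    path, raw[[1L]][i], names(raw)[j], col[i]))
    }
    if (unit_kind == "counts" && any(abs(num - round(num)) > 0)) {
      i <- which(abs(num - round(num)) > 0)[1L]
      abort(sprintf("%s: non-integer count at taxon '%s', sample '%s'",
                    path, raw[[1L]][i], names(raw)[j]))
    }
    raw[[j]] <- if (unit_kind == "counts") as.numeric(round(num)) else num
  }
  abundance_table(raw, unit_kind = unit_kind)
}

#' Write an abundance table to TSV
#'
#' @param x An `abund_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abund_tbl"))
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Convert counts to relative abundance
#'
#' Each sample column is divided by its sum (total-sum scaling; no
#' rarefaction is performed anywhere in the package). Applying it to an
#' already-relative table is a no-op.
#'
#' @param x An `abund_tbl`.
#' @return An `abund_tbl` with `unit_kind = "relative"`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  if (unit_kind(x) == "relative") return(x)
  out <- as_tibble(x)
  for (s in sample_ids(x)) {
    tot <- sum(out[[s]])
    if (tot <= 0) {
      abort(paste0("sample has zero total abundance: ", s))
    }
    out[[s]] <- out[[s]] / tot
  }
  abundance_table(out, unit_kind = "relative")
}

#' Pivot an abundance table to long form
#'
#' @param x An `abund_tbl`.
#' @return Tibble with columns `taxon_id`, `sample_id`, `abundance`.
#' @export
abundance_long <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  tidyr::pivot_longer(as_tibble(x), -"taxon_id",
                      names_to = "sample_id", values_to = "abundance")
}
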