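# ggplot2 views of the main result types. Aesthetics stay deliberately
# plain; these are working plots, not figure-final graphics.

#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_boxplot
#'   geom_jitter geom_hline labs theme_minimal facet_wrap
NULL

#' Plot PCoA coordinates
#'
#' @param object A `pcoa_res`.
#' @param metadata Optional metadata tibble; when given, points are colored
#'   by `colour_by`.
#' @param colour_by Metadata column for the point color (default
#'   `"specimen_type"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_res
#' @export
autoplot.pcoa_res <- function(object, metadata = NULL,
                              colour_by = "specimen_type", ...) {
  df <- object$coordinates
  pct <- 100 * object$proportion_explained
  p <- if (!is.null(metadata)) {
    df <- dplyr::left_join(df, as_tibble(metadata), by = "sample_id")
    ggplot(df, aes(x = .data$axis1, y = .data$axis2,
                   colour = .data[[colour_by]]))
  } else {
    ggplot(df, aes(x = .data$axis1, y = .data$axis2))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PCoA 1 (%.1f%%)", pct[1]),
         y = sprintf("PCoA 2 (%.1f%%)", pct[2])) +
    theme_minimal()
}

#' Stacked-bar composition plot
#'
#' @param comp Output of [composition_summary()].
#' @return A ggplot with one stacked bar per group.
#' @export
plot_composition <- function(comp) {
  ggplot(comp, aes(x = .data$group, y = .data$mean_abundance,
                   fill = .data$taxon)) +
    geom_col() +
    labs(x = NULL, y = "Mean relative abundance", fill = "Taxon") +
    theme_minimal()
}

#' Per-sample alpha diversity boxplot
#'
#' @param alpha Tibble with columns `shannon` and `group` (as produced by
#'   [run_contrast()]).
#' @return A ggplot.
#' @export
plot_alpha <- function(alpha) {
  ggplot(alpha, aes(x = .data$group, y = .data$shannon)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(x = NULL, y = "Shannon index (nats)") +
    theme_minimal()
}

#' Paired fold-change dot plot
#'
#' One point per matched pair and kept genus, on the log2 fold-change
#' scale; the dashed lines mark the calling threshold in each direction.
#'
#' @param object A `paired_diff` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot paired_diff
#' @export
autoplot.paired_diff <- function(object, ...) {
  params <- attr(object, "params")
  kept <- object[object$kept_after_filter, ]
  df <- tidyr::unnest(
    dplyr::select(as_tibble(kept), "genus", "call", "fold_changes"),
    "fold_changes")
  thr <- log2(params$fold_threshold)
  ggplot(df, aes(x = log2(.data$fold_changes),
                 y = stats::reorder(.data$genus, .data$fold_changes,
                                    FUN = stats::median),
                 colour = .data$call)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = 0, colour = NA) +
    ggplot2::geom_vline(xintercept = c(-thr, 0, thr),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey40") +
    labs(x = sprintf("log2 fold change (%s / %s)", params$group_a,
                     params$group_b),
         y = NULL, colour = "Call") +
    theme_minimal()
}
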