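# Clinicopathology association screen: contingency construction, chi-square
# tests against the bacterial-culture outcome, summary-statistic t-tests for
# continuous rows, and cohort summary lines. The packaged fixture transcribes
# the published 218-patient cohort table so every reproduction runs with no
# external data.

table1_path <- function(which) {
  system.file("extdata", paste0("table1_", which, ".tsv"),
              package = "oromicro", mustWork = TRUE)
}

#' Published cohort cross-tabulation counts
#'
#' Categorical rows of the packaged 218-patient cohort fixture: per variable
#' and level, the patient counts in the culture-negative (n = 113) and
#' culture-positive (n = 105) groups.
#'
#' @return Tibble with columns `variable`, `level`, `negative`, `positive`;
#'   level order as printed.
#' @export
table1_counts <- function() {
  readr::read_tsv(table1_path("categorical"),
                  col_types = "ccii", progress = FALSE)
}

#' Published cohort continuous-variable summaries
#'
#' Continuous rows of the cohort fixture as group means and standard
#' deviations (the printed table reports only summaries, not patient-level
#' values).
#'
#' @return Tibble with columns `variable`, `unit`, `mean_negative`,
#'   `sd_negative`, `mean_positive`, `sd_positive`.
#' @export
table1_continuous <- function() {
  readr::read_tsv(table1_path("continuous"),
                  col_types = "ccdddd", progress = FALSE)
}

#' Patient-level expansion of the cohort fixture
#'
#' Expands the categorical cross-tabulation counts into a 218-row
#' patient-level tibble (one row per patient, factor columns with the
#' printed level order). Within each culture group every variable's counts
#' are honored exactly, but the joint distribution across variables is not
#' recoverable from printed marginals, so columns are assigned independently
#' within group: only per-variable cross-tabulations against
#' `culture_result` — the analyses the table supports — are meaningful on
#' this cohort.
#'
#' @return Tibble with `patient_id`, `culture_result`, and one factor
#'   column per categorical variable.
#' @export
table1_cohort <- function() {
  counts <- table1_counts()
  n_neg <- sum(counts$negative[counts$variable == counts$variable[1]])
  n_pos <- sum(counts$positive[counts$variable == counts$variable[1]])
  cohort <- tibble(
    patient_id = sprintf("PT%03d", seq_len(n_neg + n_pos)),
    culture_result = factor(rep(c("negative", "positive"), c(n_neg, n_pos)),
                            levels = c("negative", "positive")))
  for (v in unique(counts$variable)) {
    sub <- counts[counts$variable == v, ]
    vals <- c(rep(sub$level, sub$negative), rep(sub$level, sub$positive))
    cohort[[v]] <- factor(vals, levels = sub$level)
  }
  cohort
}

#' Cross-tabulate a cohort variable against culture result
#'
#' Rows are the outcome (culture result) in declared order; columns are the
#' variable's levels in declared (factor) order. Patients with a missing
#' value in either column are excluded pairwise.
#'
#' @param cohort Patient-level tibble with a `culture_result` column.
#' @param variable Name of a categorical cohort column.
#' @param outcome Name of the outcome column (default `"culture_result"`).
#' @return Integer matrix of class `contingency_tbl` (rows = outcome
#'   levels, columns = variable levels).
#' @export
crosstab <- function(cohort, variable, outcome = "culture_result") {
  if (nrow(cohort) == 0L) abort("empty cohort")
  for (col in c(outcome, variable)) {
    if (!col %in% names(cohort)) abort(paste0("unknown variable: ", col))
  }
  y <- cohort[[outcome]]
  x <- cohort[[variable]]
  keep <- !is.na(y) & !is.na(x) & x != "unknown" & y != "unknown"
  y <- droplevels(factor(y[keep]))
  x <- droplevels(factor(x[keep]))
  if (nlevels(x) < 2L) {
    abort(paste0("variable '", variable, "' has a single observed level"))
  }
  if (nlevels(y) < 2L) {
    abort(paste0("outcome '", outcome, "' has a single observed level"))
  }
  m <- unclass(table(y, x))
  names(dimnames(m)) <- c(outcome, variable)
  structure(m, class = c("contingency_tbl", "matrix", "array"))
}

#' Construct a labeled contingency table
#' @param counts Non-negative integer matrix.
#' @param row_labels,col_labels Optional dimnames.
#' @return A `contingency_tbl`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    abort("contingency counts must be non-negative integers")
  }
  if (sum(m) == 0) abort("contingency table grand total must be positive")
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  structure(m, class = c("contingency_tbl", "matrix", "array"))
}

#' Write a labeled contingency table to TSV
#' @param x A `contingency_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(x, path) {
  out <- as_tibble(as.data.frame(unclass(x)), rownames = "row_label")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

assoc_result <- function(variable, test, statistic, dof, p_value,
                         detail = NULL, small_expected = FALSE) {
  structure(list(variable = variable, test = test,
                 statistic = unname(statistic), dof = unname(dof),
                 p_value = unname(p_value),
                 significant = unname(p_value) < 0.05,
                 small_expected = small_expected, detail = detail),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("# %s: %s\n", x$variable, x$test))
  cat(sprintf("statistic = %.4f, df = %s, p = %.4g%s%s\n", x$statistic,
              format(x$dof), x$p_value,
              if (x$significant) " *" else "",
              if (x$small_expected) " (expected count < 1 somewhere)" else ""))
  invisible(x)
}

#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) {
  tibble(variable = x$variable, test = x$test, statistic = x$statistic,
         dof = x$dof, p_value = x$p_value, significant = x$significant,
         small_expected = x$small_expected)
}

#' Chi-square test of independence on a contingency table
#'
#' SPSS-convention chi-square: Yates continuity correction for 2x2 tables,
#' Pearson chi-square for larger tables, degrees of freedom
#' \eqn{(r-1)(c-1)}, upper-tail p. An expected cell below 1 sets the
#' `small_expected` caveat flag rather than erroring.
#'
#' @param table A `contingency_tbl` with at least 2 rows and 2 columns.
#' @param variable Label used in the result (defaults to the column
#'   dimension name).
#' @return An `assoc_result`.
#' @export
chi_square_test <- function(table, variable = NULL) {
  m <- unclass(table)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need at least a 2x2 table")
  if (sum(m) == 0) abort("grand total must be positive")
  variable <- variable %||% names(dimnames(m))[2] %||% "variable"
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  ht <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  test <- if (nrow(m) == 2L && ncol(m) == 2L) {
    "chi-square (Yates)"
  } else {
    "chi-square (Pearson)"
  }
  assoc_result(variable, test, ht$statistic, ht$parameter, ht$p.value,
               detail = contingency_table(m),
               small_expected = any(expected < 1))
}

#' Pooled-variance two-sample t-test of a continuous variable
#'
#' Equal-variances-assumed two-sided t-test between the culture-negative
#' and culture-positive groups, reporting group mean and SD. With zero
#' variance in both groups and equal means, p = 1 by convention.
#'
#' @param values_neg,values_pos Numeric vectors, each of length >= 2.
#' @param variable Label for the result.
#' @return An `assoc_result` with a `detail` tibble of group summaries.
#' @export
two_sample_location_test <- function(values_neg, values_pos,
                                     variable = "value") {
  values_neg <- values_neg[!is.na(values_neg)]
  values_pos <- values_pos[!is.na(values_pos)]
  if (length(values_neg) < 2L || length(values_pos) < 2L) {
    abort("each group needs at least 2 values")
  }
  if (sd(values_neg) == 0 && sd(values_pos) == 0) {
    if (mean(values_neg) == mean(values_pos)) {
      return(assoc_result(variable, "pooled t-test", 0,
                          length(values_neg) + length(values_pos) - 2, 1))
    }
    abort("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(values_neg, values_pos, var.equal = TRUE)
  detail <- tibble(group = c("negative", "positive"),
                   n = c(length(values_neg), length(values_pos)),
                   mean = c(mean(values_neg), mean(values_pos)),
                   sd = c(sd(values_neg), sd(values_pos)))
  assoc_result(variable, "pooled t-test", ht$statistic, ht$parameter,
               ht$p.value, detail = detail)
}

#' Pooled t-test from printed group summaries
#'
#' Same pooled-variance two-sided t-test, computed directly from group
#' sizes, means, and standard deviations — the form a published
#' mean-plus-SD table supports.
#'
#' @param n_neg,mean_neg,sd_neg Negative-group size, mean, SD.
#' @param n_pos,mean_pos,sd_pos Positive-group size, mean, SD.
#' @param variable Label for the result.
#' @return An `assoc_result`.
#' @export
t_test_from_summary <- function(n_neg, mean_neg, sd_neg,
                                n_pos, mean_pos, sd_pos,
                                variable = "value") {
  if (n_neg < 2L || n_pos < 2L) abort("each group needs n >= 2")
  dof <- n_neg + n_pos - 2
  sp2 <- ((n_neg - 1) * sd_neg^2 + (n_pos - 1) * sd_pos^2) / dof
  if (sp2 == 0) {
    if (mean_neg == mean_pos) {
      return(assoc_result(variable, "pooled t-test (from summaries)",
                          0, dof, 1))
    }
    abort("zero pooled variance with unequal means")
  }
  tstat <- (mean_neg - mean_pos) / sqrt(sp2 * (1 / n_neg + 1 / n_pos))
  p <- 2 * stats::pt(-abs(tstat), dof)
  assoc_result(variable, "pooled t-test (from summaries)", tstat, dof, p)
}

#' Cohort summary lines
#'
#' Pooled totals, per-level counts and percentages (1 decimal) for the
#' categorical variables, and — when a continuous-summary tibble is given —
#' size-weighted pooled means of the group means.
#'
#' @param cohort Patient-level tibble with `culture_result`.
#' @param continuous Optional tibble in the [table1_continuous()] layout.
#' @return List with `n_total`, `n_by_outcome`, `categorical` (tibble:
#'   variable, level, count, pct), and `continuous_pooled` (tibble:
#'   variable, pooled_mean) or `NULL`.
#' @export
cohort_summary <- function(cohort, continuous = NULL) {
  if (nrow(cohort) == 0L) abort("empty cohort")
  n_total <- nrow(cohort)
  n_by <- cohort |>
    dplyr::count(.data$culture_result, name = "n")
  cat_vars <- setdiff(names(cohort), c("patient_id", "culture_result"))
  cat_vars <- cat_vars[!vapply(cohort[cat_vars], is.numeric, logical(1))]
  categorical <- purrr::map_dfr(cat_vars, function(v) {
    cohort |>
      dplyr::count(level = .data[[v]], name = "count") |>
      dplyr::mutate(variable = v,
                    pct = round(100 * .data$count / n_total, 1)) |>
      dplyr::select("variable", "level", "count", "pct")
  })
  continuous_pooled <- NULL
  if (!is.null(continuous)) {
    nn <- sum(n_by$n[n_by$culture_result == "negative"])
    np <- sum(n_by$n[n_by$culture_result == "positive"])
    continuous_pooled <- continuous |>
      dplyr::mutate(pooled_mean = (nn * .data$mean_negative +
                                     np * .data$mean_positive) / (nn + np)) |>
      dplyr::select("variable", "pooled_mean")
  }
  list(n_total = n_total, n_by_outcome = n_by, categorical = categorical,
       continuous_pooled = continuous_pooled)
}

#' Screen cohort variables for association with culture result
#'
#' One test per requested variable against the bacterial-culture outcome:
#' categorical columns get the chi-square test of [chi_square_test()],
#' numeric columns the pooled t-test. Results keep the input order; flags
#' use the two-tailed 0.05 level with no multiplicity correction by
#' default (Benjamini-Hochberg adjusted p-values are added on request).
#'
#' @param cohort Patient-level tibble with `culture_result`.
#' @param variables Character vector of cohort column names (default: all
#'   columns except `patient_id` and the outcome).
#' @param p_adjust If `TRUE`, append a `p_adjusted` (BH) column; the
#'   `significant` flag stays on the raw p-values.
#' @return Tibble: `variable`, `test`, `statistic`, `dof`, `p_value`,
#'   `significant`, `small_expected` (and optionally `p_adjusted`).
#' @export
association_screen <- function(cohort, variables = NULL, p_adjust = FALSE) {
  variables <- variables %||%
    setdiff(names(cohort), c("patient_id", "culture_result"))
  if (length(variables) == 0L) {
    return(tibble(variable = character(), test = character(),
                  statistic = numeric(), dof = numeric(),
                  p_value = numeric(), significant = logical(),
                  small_expected = logical()))
  }
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown)) {
    abort(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  out <- purrr::map_dfr(variables, function(v) {
    res <- if (is.numeric(cohort[[v]])) {
      two_sample_location_test(
        cohort[[v]][cohort$culture_result == "negative"],
        cohort[[v]][cohort$culture_result == "positive"], variable = v)
    } else {
      chi_square_test(crosstab(cohort, v), variable = v)
    }
    tidy(res)
  })
  if (p_adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Screen the printed continuous rows from their summaries
#'
#' Runs [t_test_from_summary()] on every row of a continuous-summary tibble
#' in the [table1_continuous()] layout.
#'
#' @param continuous Summary tibble.
#' @param n_neg,n_pos Group sizes (defaults: the fixture cohort's 113/105).
#' @return Tibble in the [association_screen()] layout.
#' @export
screen_continuous_summary <- function(continuous, n_neg = 113, n_pos = 105) {
  purrr::pmap_dfr(continuous, function(variable, mean_negative, sd_negative,
                                       mean_positive, sd_positive, ...) {
    tidy(t_test_from_summary(n_neg, mean_negative, sd_negative,
                             n_pos, mean_positive, sd_positive,
                             variable = variable))
  })
}
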