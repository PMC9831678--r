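# Shared container for the package's group-comparison tests. Permutation
# tests use the add-one p estimator p = (1 + #{perm >= obs}) / (1 + P), so p
# is never exactly 0 and never below 1/(P+1).

perm_test <- function(statistic, p_value, method, n_permutations = NA_integer_,
                      seed = NA_integer_, ...) {
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           method = method, n_permutations = n_permutations, seed = seed),
      list(...)),
    class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("# %s\n", x$method))
  cat(sprintf("statistic = %.6g, p = %.4g", x$statistic, x$p_value))
  if (!is.na(x$n_permutations)) {
    cat(sprintf(" (%d permutations, seed %d)", x$n_permutations, x$seed))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Write a test result as a JSON record
#' @param x A `perm_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(x, path) {
  jsonlite::write_json(
    list(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

add_one_p <- function(perm_stats, observed) {
  (1 + sum(perm_stats >= observed - 1e-12)) / (1 + length(perm_stats))
}

# Sums of squares decomposition of a distance matrix given group labels,
# via the standard identity SS = sum_{i<j in set} d_ij^2 / |set|. Full-matrix
# sums (both triangles + zero diagonal) avoid upper.tri masks in the
# permutation loop.
ss_decompose <- function(d2, labels) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

permanova_f <- function(d2, labels) {
  n <- nrow(d2)
  g <- length(unique(labels))
  ss <- ss_decompose(d2, labels)
  (ss[["between"]] / (g - 1)) / (ss[["within"]] / (n - g))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix: the observed pseudo-F
#' \eqn{F = (SS_B/(g-1)) / (SS_W/(n-g))} is computed from squared distances
#' via the within-group sums-of-squares identity, and significance is
#' assessed by permuting group labels over samples.
#'
#' @param dm A `dist_mat`.
#' @param labels Group label per sample, in the distance-matrix sample
#'   order; at least 2 groups with at least 2 samples each.
#' @param n_permutations Number of label permutations (default 999, min 99).
#' @param seed Integer seed for the permutation stream (default 0).
#' @return A `perm_test` with the pseudo-F statistic and add-one p-value.
#' @export
permanova <- function(dm, labels, n_permutations = 999L, seed = 0L) {
  stopifnot(inherits(dm, "dist_mat"))
  labels <- as.character(labels)
  n <- nrow(dm)
  if (length(labels) != n) abort("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2L) abort("need at least 2 groups")
  if (any(tab < 2L)) {
    abort(paste0("group(s) with fewer than 2 samples: ",
                 paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  if (n_permutations < 99L) abort("n_permutations must be at least 99")
  d2 <- unclass(dm)^2
  if (max(d2) - min(d2[upper.tri(d2)]) < 1e-15 || sum(d2) == 0) {
    abort("constant distance matrix: pseudo-F undefined")
  }
  obs <- permanova_f(d2, labels)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) permanova_f(d2, sample(labels)), numeric(1))
  })
  perm_test(obs, add_one_p(perm, obs), "PERMANOVA (pseudo-F)",
            n_permutations = as.integer(n_permutations),
            seed = as.integer(seed))
}

#' Two-group comparison of alpha-diversity values
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact enumeration for
#' up to 8 untied values per group, midrank/normal approximation with tie
#' correction otherwise. Rank-based so the result is invariant under any
#' strictly monotone transform of the diversity values.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return A `perm_test` with the rank-sum W statistic and two-sided p.
#' @export
alpha_group_test <- function(values_a, values_b) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    abort("each group needs at least 3 values")
  }
  exact <- length(values_a) <= 8L && length(values_b) <= 8L &&
    !anyDuplicated(c(values_a, values_b))
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  perm_test(ht$statistic, min(1, ht$p.value), "Mann-Whitney U (two-sided)")
}

#' Within- versus between-patient specimen clustering test
#'
#' Formalizes the observation that specimens from the same patient cluster
#' together: the statistic is mean(between-patient distances) minus
#' mean(within-patient distances), and the null is built by permuting
#' patient labels over samples. A large positive statistic with a small p
#' indicates patient-dominant community structure.
#'
#' @param dm A `dist_mat`.
#' @param patient_of Patient id per sample, in distance-matrix order; at
#'   least 2 patients must contribute >= 2 specimens each.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed (default 0).
#' @return A `perm_test`; extra fields `mean_within` and `mean_between`.
#' @export
patient_clustering_test <- function(dm, patient_of, n_permutations = 999L,
                                    seed = 0L) {
  stopifnot(inherits(dm, "dist_mat"))
  patient_of <- as.character(patient_of)
  n <- nrow(dm)
  if (length(patient_of) != n) abort("one patient id per sample required")
  if (sum(table(patient_of) >= 2L) < 2L) {
    abort("need at least 2 patients with at least 2 specimens each")
  }
  d <- unclass(dm)
  ut <- upper.tri(d)
  stat_fun <- function(lab) {
    same <- outer(lab, lab, "==")[ut]
    mean(d[ut][!same]) - mean(d[ut][same])
  }
  obs <- stat_fun(patient_of)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat_fun(sample(patient_of)), numeric(1))
  })
  same <- outer(patient_of, patient_of, "==")[ut]
  perm_test(obs, add_one_p(perm, obs),
            "patient clustering (between - within distance)",
            n_permutations = as.integer(n_permutations),
            seed = as.integer(seed),
            mean_within = mean(d[ut][same]),
            mean_between = mean(d[ut][!same]))
}
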