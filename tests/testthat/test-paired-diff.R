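test_that("pairing is per-patient, deterministic, and warns on duplicates", {
  tbl <- random_counts(5, 5, seed = 31)
  md <- tibble::tibble(
    sample_id = sample_ids(tbl),
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    specimen_type = c("outer_tumor", "outer_tumor", "adjacent_normal",
                      "outer_tumor", "adjacent_normal"))
  expect_warning(
    pset <- paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal"),
    "p1")
  expect_equal(nrow(pset$pairs), 2L)
  expect_equal(pset$pairs$sample_a[1], "S01")  # earliest sample_id wins
  expect_equal(unit_kind(pset$abundance), "relative")
  expect_error(paired_specimen_set(tbl, md, "saliva", "swab"), "no patient")
})

test_that("predominance filter drops group-specific and rare genera", {
  n <- 6
  ids_a <- sprintf("P%02d_outer_tumor", 1:n)
  ids_b <- sprintf("P%02d_adjacent_normal", 1:n)
  m <- matrix(0, 4, 2 * n,
              dimnames = list(c("shared_common", "tumor_only",
                                "too_rare", "filler"),
                              c(ids_a, ids_b)))
  m["shared_common", ] <- 0.05
  m["tumor_only", seq_len(n)] <- 0.02          # absent from all of group B
  m["too_rare", ] <- 0.0005                    # below the 0.1% mean floor
  m["filler", ] <- 1 - colSums(m)
  tbl <- abundance_table(
    dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m))), "relative")
  md <- tibble::tibble(sample_id = c(ids_a, ids_b),
                       patient_id = rep(sprintf("P%02d", 1:n), 2),
                       specimen_type = rep(c("outer_tumor",
                                             "adjacent_normal"), each = n))
  pset <- paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal")
  kept <- filter_predominant_shared(pset)
  expect_true("shared_common" %in% kept)
  expect_false("tumor_only" %in% kept)
  expect_false("too_rare" %in% kept)
  expect_error(filter_predominant_shared(pset, min_mean_abundance = 0),
               "min_mean_abundance")
  expect_error(filter_predominant_shared(pset, min_detection_fraction = 1),
               "min_detection_fraction")
})

test_that("fold changes follow the pseudocount-protected ratio", {
  pset <- pairs_from_abundances(a = c(0.04, 0.02, 0.01),
                                b = c(0.02, 0.02, 0.00))
  fc <- paired_fold_changes(pset, "Fusobacterium", pseudocount = 1e-5)
  expect_equal(fc[1], (0.04 + 1e-5) / (0.02 + 1e-5), tolerance = 1e-12)
  expect_equal(fc[2], 1.0)
  expect_equal(fc[3], (0.01 + 1e-5) / 1e-5, tolerance = 1e-12)
  expect_true(all(is.finite(fc)))
  expect_error(paired_fold_changes(pset, "Absentia"), "Absentia")
  expect_error(paired_fold_changes(pset, "Fusobacterium", pseudocount = 0),
               "pseudocount")
})

test_that("two-fold majority rule calls the stated examples", {
  # fold changes approx (2.5, 4.0, 2.2, 0.9): 3/4 pairs >= 2-fold toward A
  pset <- pairs_from_abundances(a = c(0.0500, 0.0800, 0.0440, 0.0180),
                                b = rep(0.02, 4))
  res <- call_differential(pset)
  row <- res[res$genus == "Fusobacterium", ]
  expect_equal(row$call, "enriched_in_A")
  expect_equal(row$n_support_a, 3L)
  expect_equal(row$n_support_b, 0L)

  # (2.5, 0.4, 1.0, 1.1): one pair each way
  pset2 <- pairs_from_abundances(a = c(0.0500, 0.0080, 0.0200, 0.0220),
                                 b = rep(0.02, 4))
  res2 <- call_differential(pset2)
  row2 <- res2[res2$genus == "Fusobacterium", ]
  expect_equal(row2$call, "not_different")
  expect_equal(row2$n_support_a, 1L)
  expect_equal(row2$n_support_b, 1L)

  expect_error(call_differential(pairs_from_abundances(c(.1, .2), c(.1, .1))),
               "3 matched pairs")
  expect_error(call_differential(pset, majority_fraction = 0.4), "majority")
  expect_error(call_differential(pset, fold_threshold = 1), "fold_threshold")
})

test_that("calls are antisymmetric under group exchange", {
  tbl <- random_counts(15, 16, seed = 33)
  md <- tibble::tibble(
    sample_id = sample_ids(tbl),
    patient_id = rep(sprintf("P%02d", 1:8), 2),
    specimen_type = rep(c("outer_tumor", "adjacent_normal"), each = 8))
  ab <- paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal")
  ba <- paired_specimen_set(tbl, md, "adjacent_normal", "outer_tumor")
  res_ab <- call_differential(ab)
  res_ba <- call_differential(ba)
  flip <- c(enriched_in_A = "enriched_in_B", enriched_in_B = "enriched_in_A",
            not_different = "not_different", filtered_out = "filtered_out")
  expect_equal(unname(flip[res_ab$call]), res_ba$call)
  for (g in res_ab$genus[res_ab$kept_after_filter]) {
    fc_ab <- res_ab$fold_changes[res_ab$genus == g][[1]]
    fc_ba <- res_ba$fold_changes[res_ba$genus == g][[1]]
    expect_equal(fc_ab, 1 / fc_ba, tolerance = 1e-9)
  }
})

test_that("calls are invariant to per-sample count scaling", {
  tbl <- random_counts(12, 12, seed = 34)
  md <- tibble::tibble(
    sample_id = sample_ids(tbl),
    patient_id = rep(sprintf("P%02d", 1:6), 2),
    specimen_type = rep(c("outer_tumor", "adjacent_normal"), each = 6))
  scaled <- tibble::as_tibble(tbl)
  for (j in seq_along(sample_ids(tbl))) {
    scaled[[j + 1]] <- scaled[[j + 1]] * (j * 7)
  }
  scaled <- abundance_table(scaled, "counts")
  r1 <- call_differential(
    paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal"))
  r2 <- call_differential(
    paired_specimen_set(scaled, md, "outer_tumor", "adjacent_normal"))
  expect_equal(r1$call, r2$call)
  expect_equal(r1$median_fold_change, r2$median_fold_change,
               tolerance = 1e-12)
})

test_that("raising the fold threshold never creates new enrichment calls", {
  tbl <- random_counts(20, 14, seed = 35)
  md <- tibble::tibble(
    sample_id = sample_ids(tbl),
    patient_id = rep(sprintf("P%02d", 1:7), 2),
    specimen_type = rep(c("outer_tumor", "adjacent_normal"), each = 7))
  pset <- paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal")
  thresholds <- c(1.5, 2, 3, 5)
  calls <- lapply(thresholds, function(thr) {
    call_differential(pset, fold_threshold = thr)$call
  })
  for (k in seq_len(length(thresholds) - 1)) {
    was_nd <- calls[[k]] == "not_different"
    expect_true(all(calls[[k + 1]][was_nd] %in%
                      c("not_different", "filtered_out")))
  }
  # filter containment: every called genus passed the predominance filter
  res <- call_differential(pset)
  kept <- filter_predominant_shared(pset)
  expect_true(all(res$genus[res$call != "filtered_out"] %in% kept))
  expect_true(all(res$kept_after_filter == (res$call != "filtered_out")))
})

test_that("call summary orders by support, effect size, then name", {
  empty <- call_differential(
    pairs_from_abundances(rep(0.02, 3), rep(0.02, 3)))
  expect_equal(nrow(summarize_calls(empty)), 0L)

  n <- 4
  ids_a <- sprintf("P%02d_outer_tumor", 1:n)
  ids_b <- sprintf("P%02d_adjacent_normal", 1:n)
  m <- matrix(0, 4, 2 * n, dimnames = list(
    c("Zeta", "Alpha", "Beta", "filler"), c(ids_a, ids_b)))
  m["Zeta", ] <- c(rep(0.08, n), rep(0.02, n))    # 4/4 support, fold 4
  m["Alpha", ] <- c(rep(0.06, n), rep(0.02, n))   # 4/4 support, fold 3
  m["Beta", ] <- c(rep(0.06, n), rep(0.02, n))    # ties Alpha -> name order
  m["filler", ] <- 1 - colSums(m)
  tbl <- abundance_table(
    dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m))), "relative")
  md <- tibble::tibble(sample_id = c(ids_a, ids_b),
                       patient_id = rep(sprintf("P%02d", 1:n), 2),
                       specimen_type = rep(c("outer_tumor",
                                             "adjacent_normal"), each = n))
  res <- call_differential(
    paired_specimen_set(tbl, md, "outer_tumor", "adjacent_normal"))
  rep_tbl <- summarize_calls(res)
  enr <- rep_tbl[rep_tbl$group == "outer_tumor", ]
  expect_equal(enr$genus[1:3], c("Zeta", "Alpha", "Beta"))
  expect_equal(enr$rank, seq_len(nrow(enr)))

  # one enriched genus -> one-row report (filler direction varies)
  single <- call_differential(
    pairs_from_abundances(a = rep(0.08, 4), b = rep(0.02, 4),
                          background = 0.85))
  srep <- summarize_calls(single)
  expect_gte(nrow(srep), 1L)
  expect_true("Fusobacterium" %in% srep$genus)
})

test_that("paired result TSV writer flattens fold changes", {
  pset <- pairs_from_abundances(a = c(0.05, 0.06, 0.07),
                                b = rep(0.02, 3))
  res <- call_differential(pset)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_paired_diff(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$genus, res$genus)
  expect_true(grepl(";", back$fold_changes[back$genus == "Fusobacterium"]))
})
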