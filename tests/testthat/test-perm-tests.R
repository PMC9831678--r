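test_that("PERMANOVA pseudo-F agrees with an independent implementation", {
  tbl <- random_counts(25, 14, seed = 2)
  dm <- distance_matrix(tbl)
  labels <- rep(c("g1", "g2"), c(6, 8))
  ours <- permanova(dm, labels, n_permutations = 199, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ g,
                        data = data.frame(g = labels), permutations = 99)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)

  # three groups
  labels3 <- rep(c("a", "b", "c"), c(5, 4, 5))
  ours3 <- permanova(dm, labels3, n_permutations = 199, seed = 1)
  ref3 <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ g,
                         data = data.frame(g = labels3), permutations = 99)
  expect_equal(ours3$statistic, ref3$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to sample order and reproducible by seed", {
  tbl <- random_counts(20, 12, seed = 4)
  labels <- rep(c("a", "b"), each = 6)
  dm <- distance_matrix(tbl)
  r1 <- permanova(dm, labels, n_permutations = 199, seed = 5)
  r2 <- permanova(dm, labels, n_permutations = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)

  perm <- withr::with_seed(8, sample(12))
  dm_p <- dist_mat(unclass(dm)[perm, perm])
  r3 <- permanova(dm_p, labels[perm], n_permutations = 199, seed = 5)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-12)

  expect_gte(r1$p_value, 1 / 200)
  expect_error(permanova(dm, rep("a", 12)), "2 groups")
  expect_error(permanova(dm, c("c", labels[-1])), "fewer than 2")
  expect_error(permanova(dm, labels, n_permutations = 10), "99")
})

test_that("PERMANOVA saturates at the +1 lower bound for separated clusters", {
  comp_a <- c(0.7, 0.2, 0.05, 0.05)
  comp_b <- c(0.05, 0.05, 0.2, 0.7)
  cols <- lapply(1:20, function(i) {
    base <- if (i <= 10) comp_a else comp_b
    base + (i %% 5) * 1e-4  # break exact ties, then renormalize
  })
  m <- vapply(cols, function(x) x / sum(x), numeric(4))
  colnames(m) <- sprintf("S%02d", 1:20)
  tbl <- abundance_table(
    dplyr::bind_cols(tibble::tibble(taxon_id = paste0("T", 1:4)),
                     tibble::as_tibble(as.data.frame(m))), "relative")
  res <- permanova(distance_matrix(tbl), rep(c("a", "b"), each = 10),
                   n_permutations = 999, seed = 0)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("rank-sum group test matches exact enumeration and is
           monotone-invariant", {
  r <- alpha_group_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)  # minimal two-sided p, n=3,3

  same <- alpha_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  withr::with_seed(6, {
    a <- stats::rnorm(10); b <- stats::rnorm(12, 0.5)
    p1 <- alpha_group_test(a, b)$p_value
    p2 <- alpha_group_test(exp(a), exp(b))$p_value  # strictly monotone map
    expect_equal(p1, p2, tolerance = 1e-12)
  })
  expect_error(alpha_group_test(c(1, 2), c(1, 2, 3)), "3 values")
})

test_that("patient clustering statistic is 1 with p at the bound in the
           block-extreme case", {
  n_pat <- 8
  ids <- as.vector(t(outer(sprintf("P%d", 1:n_pat), c("_x", "_y"), paste0)))
  d <- matrix(1, 2 * n_pat, 2 * n_pat, dimnames = list(ids, ids))
  diag(d) <- 0
  pat <- rep(sprintf("P%d", 1:n_pat), each = 2)
  for (p in unique(pat)) {
    idx <- which(pat == p)
    d[idx, idx] <- 0
  }
  res <- patient_clustering_test(dist_mat(d), pat, n_permutations = 199,
                                 seed = 0)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 200)
  expect_equal(res$mean_within, 0)
  expect_equal(res$mean_between, 1)
})

test_that("patient clustering is null-calibrated when labels carry no
           structure", {
  tbl <- random_counts(30, 16, seed = 13)
  dm <- distance_matrix(tbl)
  pats <- rep(sprintf("P%d", 1:8), each = 2)
  stats <- p_values <- numeric(40)
  for (i in 1:40) {
    shuffled <- withr::with_seed(100 + i, sample(pats))
    res <- patient_clustering_test(dm, shuffled, n_permutations = 99,
                                   seed = i)
    stats[i] <- res$statistic
    p_values[i] <- res$p_value
  }
  expect_lt(abs(mean(stats)), 0.05)       # statistic centers on zero
  expect_lte(mean(p_values < 0.05), 0.2)  # no systematic rejection
  expect_error(
    patient_clustering_test(dm, sprintf("P%d", 1:16)), "2 specimens")
})
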