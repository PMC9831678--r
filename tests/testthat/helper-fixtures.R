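# Fixture builders shared across the suite; everything is generated in code.

tiny_counts <- function() {
  abundance_table(
    tibble::tibble(taxon_id = c("Fusobacterium", "Prevotella", "Neisseria"),
                   s1 = c(10, 0, 30), s2 = c(5, 5, 0)),
    unit_kind = "counts")
}

random_counts <- function(n_taxa, n_samples, seed = 1, max_count = 200) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_taxa * n_samples, max_count / 4) +
                  1L * (stats::runif(n_taxa * n_samples) < 0.5),
                nrow = n_taxa)
    m[sample(length(m), length(m) %/% 5)] <- 0
    m[1, ] <- m[1, ] + 1L   # guard against all-zero columns
    tbl <- tibble::as_tibble(as.data.frame(m))
    names(tbl) <- sprintf("S%02d", seq_len(n_samples))
    abundance_table(
      dplyr::bind_cols(
        tibble::tibble(taxon_id = sprintf("T%02d", seq_len(n_taxa))), tbl),
      unit_kind = "counts")
  })
}

# Paired set with explicit per-pair relative abundances for one genus of
# interest; a filler taxon absorbs the remainder of each composition.
pairs_from_abundances <- function(a, b, genus = "Fusobacterium",
                                  background = 0.05) {
  n <- length(a)
  stopifnot(length(b) == n)
  ids_a <- sprintf("P%02d_outer_tumor", seq_len(n))
  ids_b <- sprintf("P%02d_adjacent_normal", seq_len(n))
  vals <- cbind(rbind(a, rep(background, n), 1 - a - background),
                rbind(b, rep(background, n), 1 - b - background))
  colnames(vals) <- c(ids_a, ids_b)
  tbl <- abundance_table(
    dplyr::bind_cols(
      tibble::tibble(taxon_id = c(genus, "Veillonella", "Other")),
      tibble::as_tibble(as.data.frame(vals))),
    unit_kind = "relative")
  meta <- tibble::tibble(
    sample_id = c(ids_a, ids_b),
    patient_id = rep(sprintf("P%02d", seq_len(n)), 2),
    specimen_type = rep(c("outer_tumor", "adjacent_normal"), each = n))
  paired_specimen_set(tbl, meta, "outer_tumor", "adjacent_normal")
}

# Euclidean distance matrix of 2-d points
euclid_dm <- function(xy, ids = NULL) {
  d <- as.matrix(stats::dist(xy))
  rownames(d) <- colnames(d) <- ids %||% paste0("S", seq_len(nrow(xy)))
  dist_mat(d)
}

null_sim_spec <- function(seed, n_patients = 8,
                          types = c("outer_tumor", "adjacent_normal")) {
  microbiome_sim_spec(n_patients = n_patients, specimen_types = types,
                      patient_effect_sd = 0, planted_differentials = NULL,
                      rare_genus_rate = 0, seed = seed)
}
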