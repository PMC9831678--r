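#' Shannon diversity index
#'
#' Alpha diversity of a single sample, \eqn{H = -\sum_{p_i > 0} p_i \ln p_i}
#' in nats. Zero-abundance taxa contribute nothing, so appending absent taxa
#' never changes the value; the maximum \eqn{\ln S} is reached only for a
#' uniform composition over the S observed taxa.
#'
#' @param p Relative-abundance vector: non-negative entries summing to 1
#'   (tolerance 1e-9).
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(0.1, 10))            # ln 10
#' shannon_index(c(0.5, 0.25, 0.25))
#' @export
shannon_index <- function(p) {
  if (!is.numeric(p) || any(is.na(p))) abort("p must be numeric, no NA")
  if (any(p < 0)) abort("negative relative abundance")
  s <- sum(p)
  if (s == 0) abort("zero-sum abundance vector")
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("relative abundances must sum to 1 (got %.6g)", s))
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of an abundance table
#'
#' @param table An `abund_tbl`; counts are total-sum scaled first.
#' @return Tibble with columns `sample_id`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  rel <- to_relative(table)
  m <- abund_matrix(rel)
  tibble(sample_id = colnames(m),
         shannon = apply(m, 2, shannon_index))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{BC = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}.
#' Symmetric, zero iff the vectors are identical, and bounded in \[0, 1\]
#' with 1 for disjoint supports. Bray-Curtis is a semimetric: the triangle
#' inequality can fail.
#'
#' @param x,y Non-negative vectors aligned to the same taxon order.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 6, 2), c(4, 2, 4))  # 0.4
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("negative abundance")
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) abort("Bray-Curtis undefined for two all-zero samples")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' Bray-Curtis distance matrix over all samples
#'
#' Computes pairwise Bray-Curtis dissimilarities on relative abundances
#' (counts are total-sum scaled first; Bray-Curtis on raw counts would
#' confound library size with composition).
#'
#' @param table An `abund_tbl` with at least two samples.
#' @return Object of class `dist_mat`: a symmetric numeric matrix with zero
#'   diagonal and sample ids as dimnames.
#' @export
distance_matrix <- function(table) {
  stopifnot(inherits(table, "abund_tbl"))
  if (ncol(table) - 1L < 2L) abort("need at least 2 samples")
  rel <- to_relative(table)
  m <- t(abund_matrix(rel))           # samples x taxa for vegdist
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dist_mat(d)
}

#' Construct a distance-matrix object
#'
#' @param d Symmetric numeric matrix, zero diagonal, entries in \[0, 1\] for
#'   Bray-Curtis; dimnames are sample ids.
#' @return Object of class `dist_mat`.
#' @export
dist_mat <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  colnames(d) <- rownames(d)
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal not zero")
  if (any(d < 0)) abort("negative distance")
  structure(d, class = c("dist_mat", "matrix", "array"))
}

#' @export
print.dist_mat <- function(x, ...) {
  cat(sprintf("# Distance matrix over %d samples\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Long-form view of a distance matrix
#' @param x A `dist_mat`.
#' @param ... Unused.
#' @return Tibble of unordered sample pairs with their distances.
#' @method tidy dist_mat
#' @export
tidy.dist_mat <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
         distance = x[idx])
}

#' Write / read a labeled square distance matrix TSV
#' @param x A `dist_mat`.
#' @param path File path.
#' @return `path` invisibly, or the `dist_mat` read back.
#' @export
write_distance_matrix <- function(x, path) {
  out <- as_tibble(as.data.frame(unclass(x)), rownames = "sample_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"), progress = FALSE)
  m <- as.matrix(raw[, -1L])
  rownames(m) <- raw$sample_id
  dist_mat(m)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' scales eigenvectors by the square root of their (positive) eigenvalues.
#' Negative eigenvalues — which arise because Bray-Curtis is not Euclidean —
#' are dropped without Cailliez/Lingoes correction; their summed magnitude is
#' reported so the user can judge the distortion.
#'
#' @param dm A `dist_mat`.
#' @param n_axes Number of axes to retain (default 2); must be below the
#'   number of samples.
#' @return Object of class `pcoa_res`: list with `coordinates` (tibble:
#'   `sample_id`, `axis1`, ...), `eigenvalues` (all, descending),
#'   `proportion_explained` (per retained axis, relative to the positive
#'   eigenvalue total), and `negative_eigenvalue_magnitude`.
#' @export
pcoa <- function(dm, n_axes = 2L) {
  stopifnot(inherits(dm, "dist_mat"))
  n <- nrow(dm)
  if (n < 2L) abort("need at least 2 samples for ordination")
  if (n_axes >= n) abort("n_axes must be smaller than the number of samples")
  d2 <- unclass(dm)^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% d2 %*% j
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  if (!any(pos)) abort("degenerate geometry: no positive eigenvalues")
  k <- min(n_axes, sum(pos))
  lambda <- e$values[seq_len(k)]
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lambda), k)
  colnames(coords) <- paste0("axis", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(sample_id = rownames(dm)),
                                   as_tibble(coords)),
    eigenvalues = e$values,
    proportion_explained = lambda / sum(e$values[pos]),
    negative_eigenvalue_magnitude = sum(abs(e$values[e$values < 0]))
  ), class = "pcoa_res")
}

#' @export
print.pcoa_res <- function(x, ...) {
  k <- ncol(x$coordinates) - 1L
  cat(sprintf("# PCoA: %d samples, %d retained axes\n",
              nrow(x$coordinates), k))
  cat(sprintf("# proportion explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$proportion_explained),
                    collapse = ", ")))
  if (x$negative_eigenvalue_magnitude > 0) {
    cat(sprintf("# dropped negative eigenvalue magnitude: %.4g\n",
                x$negative_eigenvalue_magnitude))
  }
  print(x$coordinates, ...)
  invisible(x)
}

#' @method tidy pcoa_res
#' @export
tidy.pcoa_res <- function(x, ...) x$coordinates

#' @method glance pcoa_res
#' @export
glance.pcoa_res <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_axes = ncol(x$coordinates) - 1L,
         prop_explained_total = sum(x$proportion_explained),
         negative_eigenvalue_magnitude = x$negative_eigenvalue_magnitude)
}

#' Write PCoA coordinates (with an eigenvalue header block) to TSV
#' @param x A `pcoa_res`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(x, path) {
  hdr <- c(
    paste0("# eigenvalues\t",
           paste(format(x$eigenvalues, digits = 12), collapse = "\t")),
    paste0("# proportion_explained\t",
           paste(format(x$proportion_explained, digits = 12),
                 collapse = "\t")))
  writeLines(hdr, path)
  readr::write_tsv(x$coordinates, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
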