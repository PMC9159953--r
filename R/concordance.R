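#' Aitchison distance between samples
#'
#' Euclidean distance on CLR coordinates. Strictly positive input is taken as
#' compositions and CLR-transformed first; input containing non-positive
#' values (an already-transformed or standardized matrix) is used as-is.
#'
#' @param m samples x features matrix.
#' @return a `dist` object over samples.
#' @export
aitchison_distance <- function(m) {
  if (anyNA(m)) abort_stage("aitchison_distance", "NaN/NA input")
  if (all(m > 0)) m <- clr_rows(m)
  stats::dist(m)
}

#' Bray-Curtis dissimilarity between samples
#'
#' @param m samples x features non-negative abundance matrix.
#' @return a `dist` object with entries in `[0, 1]`.
#' @export
bray_curtis_distance <- function(m) {
  if (anyNA(m)) abort_stage("bray_curtis_distance", "NaN/NA input")
  stopifnot(all(m >= 0))
  vegan::vegdist(m, method = "bray")
}

#' Procrustes correspondence test between two distance matrices
#'
#' Embeds both matrices by classical MDS (all positive-eigenvalue axes),
#' centres and scales each configuration to unit sum of squares, and measures
#' agreement by the symmetric-Procrustes statistic `m2 = 1 - (sum sv)^2`
#' where `sv` are the singular values of the cross-configuration product
#' (equivalently, the minimum residual sum of squares after translation,
#' scaling and rotation). Significance comes from row permutations of one
#' configuration: `p = (1 + #{perm correlation >= observed}) / (n_perm + 1)`.
#'
#' @param d_expr,d_taxa `dist` objects over the same ordered samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return list with `procrustes_m2`, `procrustes_p`, `procrustes_cor`,
#'   `n_perm`.
#' @export
procrustes_test <- function(d_expr, d_taxa, n_perm = 9999, seed = 1L) {
  emb <- function(d) {
    cm <- suppressWarnings(
      stats::cmdscale(d, k = attr(d, "Size") - 1, eig = TRUE))
    keep <- cm$eig > sqrt(.Machine$double.eps) * max(abs(cm$eig))
    if (sum(keep) < 2)
      abort_stage("procrustes_test", "degenerate embedding (<2 positive axes)")
    pts <- cm$points[, seq_len(sum(keep)), drop = FALSE]
    pts <- sweep(pts, 2, colMeans(pts))
    pts / sqrt(sum(pts^2))
  }
  x <- emb(d_expr); y <- emb(d_taxa)
  n <- nrow(x)
  t0 <- sum(svd(crossprod(x, y))$d)
  perms <- with_seed(seed,
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))))
  stats <- as.vector(procrustes_perm_stats(x, y, perms))
  list(procrustes_m2 = 1 - t0^2,
       procrustes_p = (1 + sum(stats >= t0)) / (n_perm + 1),
       procrustes_cor = t0, n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles with a permutation test;
#' p-values are bounded below by `1/(n_perm + 1)`.
#'
#' @param d1,d2 `dist` objects over the same ordered samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `mantel_r`, `mantel_p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  if (stats::sd(as.vector(d1)) < 1e-12 || stats::sd(as.vector(d2)) < 1e-12)
    abort_stage("mantel_test", "constant distance matrix")
  res <- with_seed(seed,
    vegan::mantel(d1, d2, method = "pearson", permutations = n_perm))
  list(mantel_r = unname(res$statistic), mantel_p = unname(res$signif),
       n_perm = n_perm)
}

#' Overall expression/microbiome concordance for one cohort
#'
#' Aitchison distance on the (transformed) expression matrix, Bray-Curtis on
#' the taxa counts, then Procrustes (protest) and Mantel permutation tests.
#'
#' @param expr samples x genes transformed expression matrix.
#' @param taxa_counts samples x taxa non-negative abundance matrix.
#' @param n_perm permutations for both tests.
#' @param seed integer seed.
#' @return list combining the fields of [procrustes_test()] and
#'   [mantel_test()].
#' @export
concordance_test <- function(expr, taxa_counts, n_perm = 9999, seed = 1L) {
  de <- aitchison_distance(expr)
  dt <- bray_curtis_distance(taxa_counts)
  c(procrustes_test(de, dt, n_perm, seed = derive_seed(seed, 11L)),
    mantel_test(de, dt, n_perm, seed = derive_seed(seed, 12L)))
}
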