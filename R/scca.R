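#' @name scca
#' @title Sparse CCA via penalized matrix decomposition
#' @description
#' Group-level integration of a taxa matrix X (samples x taxa, CLR,
#' standardized) and an expression matrix Y (samples x genes, transformed,
#' standardized). The objective
#' `max_{u,v} u' X'Y v  s.t. ||u||2 <= 1, ||v||2 <= 1, ||u||1 <= c1,
#' ||v||1 <= c2` is solved by alternating soft-thresholding on the
#' cross-product matrix (diagonal-covariance penalized matrix decomposition);
#' later components come from deflated cross-products. Penalties are
#' expressed as fractions `lambda` of the maximal l1 bound,
#' `c = lambda * sqrt(dim)`, floored at 1 (an l1 bound below 1 is infeasible
#' for a unit-l2 vector).
NULL

# project x onto {u : ||u||2 = 1 (or 0), ||u||1 <= c} by scaled
# soft-thresholding; the threshold is found by bisection
l1_unit <- function(x, c) {
  if (all(x == 0)) return(x)
  u <- x / sqrt(sum(x^2))
  if (sum(abs(u)) <= c) return(u)
  lo <- 0; hi <- max(abs(x))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(x, mid)
    nrm <- sqrt(sum(su^2))
    if (nrm == 0 || sum(abs(su)) / nrm > c) lo <- mid else hi <- mid
  }
  su <- soft_threshold(x, hi)
  nrm <- sqrt(sum(su^2))
  if (nrm == 0) {
    # k exactly tied maxima make every feasible point have ||.||1 >= sqrt(k);
    # when that exceeds c the bisection collapses, so fall back to the
    # sparsest vertex: all weight on the first max coordinate
    su <- numeric(length(x))
    j <- which.max(abs(x))
    su[j] <- sign(x[j])
    return(su)
  }
  su / nrm
}

penalty_bound <- function(lambda, dim) {
  stopifnot(lambda > 0, lambda <= 1)
  max(1, lambda * sqrt(dim))
}

#' Penalized rank-1 decomposition of a cross-product matrix
#'
#' Alternating updates `u <- S(Cv, d1)/||.||2`, `v <- S(C'u, d2)/||.||2`,
#' with each threshold chosen by bisection as the smallest value meeting the
#' l1 bound (zero when the unpenalized unit vector already satisfies it),
#' iterated to a fixed point. Initialization is the leading right singular
#' vector of C.
#'
#' @param C cross-product matrix `X'Y` (taxa x genes).
#' @param c1,c2 l1 bounds on u and v.
#' @param tol convergence tolerance on the max loading change.
#' @param max_iter iteration cap; non-convergence returns with
#'   `converged = FALSE` and a warning.
#' @return list with `u`, `v`, `d = u'Cv`, `iters`, `converged`.
#' @export
pmd_rank1 <- function(C, c1, c2, tol = 1e-6, max_iter = 100) {
  stopifnot(all(is.finite(C)))
  if (all(C == 0))
    return(list(u = numeric(nrow(C)), v = numeric(ncol(C)), d = 0,
                iters = 0L, converged = TRUE))
  v0 <- svd(C, nu = 0, nv = 1)$v[, 1]
  fit <- pmd_rank1_cpp(C, c1, c2, v0, tol = tol, max_iter = max_iter)
  fit$u <- drop(fit$u); fit$v <- drop(fit$v)
  if (!fit$converged) warning("pmd_rank1: no convergence in ", max_iter,
                              " iterations")
  fit
}

# orient a component: the entry of v with largest |v| is positive
orient_component <- function(u, v) {
  if (all(v == 0)) return(list(u = u, v = v))
  if (v[which.max(abs(v))] < 0) { u <- -u; v <- -v }
  list(u = u, v = v)
}

#' Fit K sparse CCA components with deflation
#'
#' Component k is the penalized rank-1 decomposition of
#' `C_k = C_{k-1} - d u v'`, so successive components capture residual
#' covariation (approximately uncorrelated components).
#'
#' @param X samples x taxa standardized matrix.
#' @param Y samples x genes standardized matrix.
#' @param lambda_taxa,lambda_genes penalty fractions in (0, 1].
#' @param K number of components (truncated to `min(dim)` with a warning).
#' @param tol,max_iter passed to [pmd_rank1()].
#' @return list of components, each with `index`, `u`, `v`, `d`.
#' @export
fit_components <- function(X, Y, lambda_taxa, lambda_genes, K = 10,
                           tol = 1e-6, max_iter = 100) {
  C <- crossprod(X, Y)
  c1 <- penalty_bound(lambda_taxa, ncol(X))
  c2 <- penalty_bound(lambda_genes, ncol(Y))
  kmax <- min(nrow(C), ncol(C))
  if (K > kmax) {
    warning("fit_components: K truncated to ", kmax)
    K <- kmax
  }
  comps <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- pmd_rank1(C, c1, c2, tol = tol, max_iter = max_iter)
    o <- orient_component(fit$u, fit$v)
    comps[[k]] <- list(index = k, u = stats::setNames(o$u, colnames(X)),
                       v = stats::setNames(o$v, colnames(Y)), d = fit$d)
    C <- C - fit$d * tcrossprod(fit$u, fit$v)
  }
  comps
}

#' Tune sparse CCA penalties by leave-one-out grid search
#'
#' For every penalty pair on the grid and every held-out sample i, the first
#' component is fitted on the remaining samples and held-out scores
#' `X_i u_{-i}`, `Y_i v_{-i}` recorded; the objective is the Pearson
#' correlation of the two held-out score vectors. Returns the argmax cell;
#' ties go to the sparser pair (smaller `lambda_taxa` first).
#'
#' @param X,Y standardized matrices (same samples).
#' @param grid_taxa,grid_genes candidate lambda values.
#' @param tol,max_iter passed to [pmd_rank1()].
#' @return list with `lambda_taxa`, `lambda_genes`, `cv_cor` and the full
#'   `grid` data.frame of objectives.
#' @export
tune_penalties <- function(X, Y, grid_taxa = seq(0.05, 0.5, by = 0.05),
                           grid_genes = seq(0.05, 0.5, by = 0.05),
                           tol = 1e-6, max_iter = 100) {
  n <- nrow(X)
  if (n < 5) abort_stage("tune_penalties", "need at least 5 samples")
  cells <- expand.grid(lambda_genes = sort(grid_genes),
                       lambda_taxa = sort(grid_taxa))[, 2:1]
  cells <- cells[order(cells$lambda_taxa, cells$lambda_genes), ]
  obj <- rep(NA_real_, nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sx <- sy <- numeric(n)
    degenerate <- FALSE
    for (i in seq_len(n)) {
      f <- fit_components(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                          cells$lambda_taxa[ci], cells$lambda_genes[ci],
                          K = 1, tol = tol, max_iter = max_iter)[[1]]
      if (all(f$u == 0) || all(f$v == 0)) { degenerate <- TRUE; break }
      sx[i] <- drop(X[i, ] %*% f$u)
      sy[i] <- drop(Y[i, ] %*% f$v)
    }
    if (!degenerate && stats::sd(sx) > 1e-12 && stats::sd(sy) > 1e-12)
      obj[ci] <- stats::cor(sx, sy)
  }
  if (all(is.na(obj)))
    abort_stage("tune_penalties",
                "all grid cells degenerate; widen the penalty grid")
  best <- which.max(obj)   # first argmax = sparsest by the cell ordering
  list(lambda_taxa = cells$lambda_taxa[best],
       lambda_genes = cells$lambda_genes[best],
       cv_cor = obj[best], grid = cbind(cells, cv_cor = obj))
}

#' Held-out significance of sparse CCA components
#'
#' For each held-out sample, the K components are refitted without it
#' (`mode = "full"`; `mode = "fast"` refits only component k on the
#' cross-product deflated by the k-1 full-data components, an approximation).
#' Component k's held-out scores across samples are tested with a two-sided
#' Pearson correlation test; p-values are BH-adjusted across the K
#' components.
#'
#' @param X,Y standardized matrices.
#' @param lambda_taxa,lambda_genes penalty fractions.
#' @param K number of components.
#' @param fdr significance threshold on q (default 0.1).
#' @param mode `"full"` (faithful, costly) or `"fast"` (approximate).
#' @param tol,max_iter passed to [pmd_rank1()].
#' @return list with `components` (full-data loadings) and `summary`
#'   data.frame (`component`, `d`, `heldout_cor`, `p`, `q`, `significant`).
#' @export
component_significance <- function(X, Y, lambda_taxa, lambda_genes, K = 10,
                                   fdr = 0.1, mode = c("full", "fast"),
                                   tol = 1e-6, max_iter = 100) {
  mode <- match.arg(mode)
  n <- nrow(X)
  full <- fit_components(X, Y, lambda_taxa, lambda_genes, K,
                         tol = tol, max_iter = max_iter)
  K <- length(full)
  sx <- sy <- matrix(NA_real_, n, K)
  c1 <- penalty_bound(lambda_taxa, ncol(X))
  c2 <- penalty_bound(lambda_genes, ncol(Y))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    if (mode == "full") {
      fc <- fit_components(Xi, Yi, lambda_taxa, lambda_genes, K,
                           tol = tol, max_iter = max_iter)
      for (k in seq_len(K)) {
        sx[i, k] <- drop(X[i, ] %*% fc[[k]]$u)
        sy[i, k] <- drop(Y[i, ] %*% fc[[k]]$v)
      }
    } else {
      C <- crossprod(Xi, Yi)
      for (k in seq_len(K)) {
        f <- pmd_rank1(C, c1, c2, tol = tol, max_iter = max_iter)
        sx[i, k] <- drop(X[i, ] %*% f$u)
        sy[i, k] <- drop(Y[i, ] %*% f$v)
        # deflate by the full-data component so folds share the subspace
        C <- C - full[[k]]$d * tcrossprod(full[[k]]$u, full[[k]]$v)
      }
    }
  }
  p <- r <- numeric(K)
  for (k in seq_len(K)) {
    if (stats::sd(sx[, k]) < 1e-12 || stats::sd(sy[, k]) < 1e-12) {
      warning("component ", k, ": constant held-out score vector; p = 1")
      p[k] <- 1; r[k] <- NA_real_
    } else {
      ct <- stats::cor.test(sx[, k], sy[, k])
      p[k] <- ct$p.value; r[k] <- unname(ct$estimate)
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  summary <- data.frame(component = seq_len(K),
                        d = vapply(full, `[[`, numeric(1), "d"),
                        heldout_cor = r, p = p, q = q,
                        significant = q < fdr)
  list(components = full, summary = summary)
}

#' Run the sparse CCA stage end to end
#'
#' Optionally tunes the penalties on a grid, fits K components on the full
#' data, and attaches held-out significance.
#'
#' @param X,Y standardized taxa and expression matrices.
#' @param lambda_taxa,lambda_genes fixed penalties; when NULL they are tuned
#'   with [tune_penalties()].
#' @param grid_taxa,grid_genes tuning grids.
#' @param K number of components.
#' @param fdr component significance threshold.
#' @param mode significance mode, see [component_significance()].
#' @return list with `penalties`, `components`, `summary`.
#' @export
scca_run <- function(X, Y, lambda_taxa = NULL, lambda_genes = NULL,
                     grid_taxa = seq(0.05, 0.5, by = 0.05),
                     grid_genes = seq(0.05, 0.5, by = 0.05),
                     K = 10, fdr = 0.1, mode = "full") {
  if (is.null(lambda_taxa) || is.null(lambda_genes)) {
    tuned <- tune_penalties(X, Y, grid_taxa, grid_genes)
    lambda_taxa <- tuned$lambda_taxa; lambda_genes <- tuned$lambda_genes
  }
  sig <- component_significance(X, Y, lambda_taxa, lambda_genes, K = K,
                                fdr = fdr, mode = mode)
  list(penalties = list(lambda_taxa = lambda_taxa,
                        lambda_genes = lambda_genes),
       components = sig$components, summary = sig$summary)
}
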