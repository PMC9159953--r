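rand_rank1 <- function(p1, p2, sigma = 3, seed = 1) {
  set.seed(seed)
  a <- rnorm(p1); a <- a / sqrt(sum(a^2))
  b <- rnorm(p2); b <- b / sqrt(sum(b^2))
  list(C = sigma * tcrossprod(a, b), a = a, b = b, sigma = sigma)
}

test_that("unpenalized rank-1 decomposition matches the leading SVD", {
  for (s in 1:10) {
    r <- rand_rank1(12, 9, sigma = 2 + s / 5, seed = s)
    f <- pmd_rank1(r$C, c1 = sqrt(12), c2 = sqrt(9))
    expect_equal(abs(drop(crossprod(f$u, r$a))), 1, tolerance = 1e-6)
    expect_equal(abs(drop(crossprod(f$v, r$b))), 1, tolerance = 1e-6)
    expect_equal(f$d, r$sigma, tolerance = 1e-6)
  }
  # and on full-rank random matrices, against the top singular triplet
  for (s in 1:10) {
    set.seed(100 + s)
    C <- matrix(rnorm(20 * 15), 20)
    f <- pmd_rank1(C, c1 = sqrt(20), c2 = sqrt(15))
    sv <- svd(C)
    expect_equal(f$d, sv$d[1], tolerance = 1e-5)
    expect_equal(abs(drop(crossprod(f$u, sv$u[, 1]))), 1, tolerance = 1e-5)
  }
})

test_that("heavy sparsity on a diagonal matrix selects the dominant axis", {
  C <- diag(c(3, 1))
  f <- pmd_rank1(C, c1 = 1, c2 = 1)
  expect_equal(abs(f$u), c(1, 0), tolerance = 1e-8)
  expect_equal(abs(f$v), c(1, 0), tolerance = 1e-8)
  expect_equal(f$d, 3, tolerance = 1e-8)
})

test_that("degenerate inputs give zero components", {
  expect_equal(soft_threshold(c(1, -2), 5), c(0, 0))
  f <- pmd_rank1(matrix(0, 3, 4), 1, 1)
  expect_equal(f$u, rep(0, 3))
  expect_equal(f$d, 0)
})

test_that("components satisfy their norm constraints on random instances", {
  for (s in 1:25) {
    set.seed(s)
    X <- scale(matrix(rnorm(20 * 8), 20))
    Y <- scale(matrix(rnorm(20 * 12), 20))
    lam <- runif(2, 0.2, 0.9)
    comps <- fit_components(X, Y, lam[1], lam[2], K = 3)
    c1 <- max(1, lam[1] * sqrt(8)); c2 <- max(1, lam[2] * sqrt(12))
    for (cm in comps) {
      expect_lte(sqrt(sum(cm$u^2)), 1 + 1e-8)
      expect_lte(sqrt(sum(cm$v^2)), 1 + 1e-8)
      expect_lte(sum(abs(cm$u)), c1 + 1e-6)
      expect_lte(sum(abs(cm$v)), c2 + 1e-6)
      if (any(cm$v != 0)) expect_gt(cm$v[which.max(abs(cm$v))], 0)
    }
  }
})

test_that("deflation removes each component from the cross-product", {
  set.seed(4)
  X <- scale(matrix(rnorm(30 * 10), 30))
  Y <- scale(matrix(rnorm(30 * 14), 30))
  comps <- fit_components(X, Y, 0.9, 0.9, K = 2)
  C <- crossprod(X, Y)
  C2 <- C - comps[[1]]$d * tcrossprod(comps[[1]]$u, comps[[1]]$v)
  expect_lt(abs(drop(t(comps[[1]]$u) %*% C2 %*% comps[[1]]$v)), 1e-4)
  # K = 1 equals the undeflated rank-1 fit
  f <- pmd_rank1(C, max(1, 0.9 * sqrt(10)), max(1, 0.9 * sqrt(14)))
  expect_equal(abs(comps[[1]]$u), abs(f$u), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_warning(fit_components(X, Y, 0.5, 0.5, K = 99), "truncated")
})

test_that("planted-factor supports are recovered by the leading components", {
  xy <- fx_xy()
  truth <- fx_cohort()$truth
  sc <- scca_run(xy$X, xy$Y, lambda_taxa = 0.3, lambda_genes = 0.3, K = 2,
                 mode = "full")
  u <- sc$components[[1]]$u; v <- sc$components[[1]]$v
  tsup <- paste0("otu:", truth$latent_taxon_support[[1]])
  gsup <- truth$latent_gene_support[[1]]
  sel_t <- names(u)[u != 0]; sel_g <- names(v)[v != 0]
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac(sel_t, intersect(tsup, colnames(xy$X))), 0.6)
  expect_gte(jac(sel_g, intersect(gsup, colnames(xy$Y))), 0.6)
  expect_lt(sc$summary$q[1], 0.1)
})

test_that("penalty tuning returns grid cells with sparse tie-breaking", {
  xy <- fx_xy()
  one <- tune_penalties(xy$X, xy$Y, grid_taxa = 0.25, grid_genes = 0.25)
  expect_equal(one$lambda_taxa, 0.25)
  expect_equal(one$lambda_genes, 0.25)
  tuned <- tune_penalties(xy$X, xy$Y, grid_taxa = c(0.15, 0.45),
                          grid_genes = c(0.15, 0.45))
  expect_true(tuned$lambda_taxa %in% c(0.15, 0.45))
  expect_gt(tuned$cv_cor, 0.3)   # a planted factor is detectable under CV
  expect_equal(nrow(tuned$grid), 4)
})

test_that("pure-noise tuning objectives are centred near zero", {
  set.seed(99)
  n <- 40
  X <- scale(matrix(rnorm(n * 10), n)); Y <- scale(matrix(rnorm(n * 15), n))
  tuned <- tune_penalties(X, Y, grid_taxa = c(0.3, 0.6),
                          grid_genes = c(0.3, 0.6))
  expect_lt(mean(abs(tuned$grid$cv_cor), na.rm = TRUE), 2 / sqrt(n))
})

test_that("perfectly matched one-dimensional data attains the analytic p", {
  set.seed(6)
  z <- scale(matrix(rnorm(20), 20))
  colnames(z) <- "f1"
  sig <- suppressWarnings(
    component_significance(z, z, 1, 1, K = 1, mode = "full"))
  r <- sig$summary$heldout_cor[1]
  tstat <- r * sqrt(18) / sqrt(1 - r^2)
  expect_equal(sig$summary$p[1], 2 * pt(-abs(tstat), 18), tolerance = 1e-8)
  expect_gt(r, 0.99)
})
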