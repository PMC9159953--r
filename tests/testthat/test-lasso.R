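orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * p), n)))[, seq_len(p)]
  q * sqrt(n)     # X'X = n I, the scaling under which lasso = S(OLS, lambda)
}

test_that("orthonormal design reduces the lasso to soft-thresholded OLS", {
  n <- 50; p <- 10
  X <- orthonormal_design(n, p, seed = 2)
  set.seed(3)
  beta <- c(2, -1.5, 1, rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  y <- y - mean(y)
  ols <- drop(crossprod(X, y)) / n
  grid <- homico:::lasso_lambda_grid(X, y, 50)
  B <- homico:::lasso_path_cd(X, y, grid, tol = 1e-16)
  for (l in c(1, 10, 25, 40))
    expect_equal(unname(B[, l]), unname(soft_threshold(ols, grid[l])),
                 tolerance = 1e-8)
  # KKT boundary: at lambda >= max|X'y|/n everything is zero
  expect_true(all(B[, 1] == 0))
})

test_that("the coordinate-descent path matches glmnet on a well-posed design", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 90; p <- 20
  X <- scale(matrix(rnorm(n * p), n))
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n, 0, 0.5)
  y <- y - mean(y)
  grid <- homico:::lasso_lambda_grid(X, y, 60)
  B <- homico:::lasso_path_cd(X, y, grid)
  ref <- glmnet::glmnet(X, y, lambda = grid, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(B - as.matrix(ref$beta))), 1e-4)
})

test_that("LOO-selected models recover planted supports", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 100; p <- 50
    X <- scale(matrix(rnorm(n * p), n))
    beta <- c(rep(1, 3), rep(0, p - 3))
    y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
    f <- fit_lasso_path(y - mean(y), X)
    hits <- hits + all(f$beta[1:3] != 0)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("debiased estimates agree with OLS when n >> p", {
  inside <- 0; total <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 200; p <- 8
    X <- scale(matrix(rnorm(n * p), n))
    beta <- c(1, -1, rep(0, p - 2))
    y <- drop(X %*% beta) + rnorm(n)
    y <- y - mean(y)
    f <- fit_lasso_path(y, X)
    inf <- desparsified_inference(y, X, f$beta, seed = s)
    ols <- drop(solve(crossprod(X), crossprod(X, y)))
    inside <- inside + sum(abs(inf$estimate - ols) <= 2 * inf$se)
    total <- total + p
  }
  expect_gte(inside / total, 0.95)
})

test_that("confidence intervals contain the debiased estimate and cover the null", {
  cover <- c()
  for (s in 1:4) {
    set.seed(400 + s)
    n <- 100; p <- 50
    X <- scale(matrix(rnorm(n * p), n))
    y <- rnorm(n); y <- y - mean(y)
    f <- fit_lasso_path(y, X)
    inf <- desparsified_inference(y, X, f$beta, seed = s)
    expect_true(all(inf$ci_low <= inf$estimate & inf$estimate <= inf$ci_high))
    cover <- c(cover, inf$ci_low <= 0 & 0 <= inf$ci_high)
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("duplicated predictors are flagged rather than breaking inference", {
  set.seed(5)
  n <- 60
  X <- scale(matrix(rnorm(n * 6), n))
  X <- cbind(X, X[, 6])
  colnames(X) <- paste0("V", 1:7)
  y <- rnorm(n); y <- y - mean(y)
  expect_warning(nw <- desparsify_design(X, seed = 1), "collinear")
  inf <- desparsified_inference(y, X, setNames(numeric(7), colnames(X)),
                                nodewise = nw)
  expect_true(all(is.infinite(inf$se[nw$degenerate])))
  expect_true(all(inf$p[nw$degenerate] == 1))
  expect_error(desparsify_design(X, seed = 1, on_collinear = "error"),
               "collinear")
})

test_that("stability frequencies behave at the extremes", {
  set.seed(8)
  n <- 100; p <- 20
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("V", 1:p)
  y <- drop(X[, 1] * 2) + rnorm(n, 0, 0.5)
  y <- y - mean(y)
  f <- fit_lasso_path(y, X)
  st <- stability_select(y, X, f$lambda_best, K = 60, seed = 3)
  expect_gte(st$freq["V1"], 0.9)
  expect_true("V1" %in% st$stable)
  # K = 1 gives frequencies in {0, 1}
  st1 <- stability_select(y, X, f$lambda_best, K = 1, seed = 3)
  expect_true(all(st1$freq %in% c(0, 1)))
  # determinism under the seed
  st2 <- stability_select(y, X, f$lambda_best, K = 60, seed = 3)
  expect_identical(st$freq, st2$freq)
  expect_error(stability_select(y[1:10], X[1:10, ], 0.1), "smaller than 10")
})

test_that("pure-noise predictors rarely reach the stability threshold", {
  false_sel <- 0
  for (s in 1:5) {
    set.seed(500 + s)
    n <- 100; p <- 50
    X <- scale(matrix(rnorm(n * p), n))
    colnames(X) <- paste0("V", 1:p)
    y <- rnorm(n); y <- y - mean(y)
    f <- fit_lasso_path(y, X)
    st <- stability_select(y, X, f$lambda_best, K = 60, seed = s)
    false_sel <- false_sel + sum(st$freq >= 0.6)
  }
  # false stable selections stay a small fraction of the 50 predictors
  expect_lte(false_sel / 5, 2)
})

test_that("gene-wise association tables are order-independent and filtered", {
  res <- fixture("assoc40", function()
    run_assoc_sim(3, n_case = 40, n_genes = 60, n_otus = 20,
                  n_direct_pairs = 4, direct_effect = 2))
  a <- res$assoc$associations
  expect_true(all(a$q < 0.1))
  expect_true(all(a$stability_freq >= 0.6))
  expect_true(all(a$kind == "taxon"))
  expect_true(all(is.finite(a$spearman_rho)))
  # execution-order contract: shuffling the gene columns changes nothing
  prep2 <- res$prep
  ord <- rev(seq_len(ncol(prep2$expr)))
  prep2$expr <- prep2$expr[, ord]
  res2 <- suppressWarnings(genewise_associations(prep2, "case", seed = 3))
  k1 <- res$assoc$records[order(res$assoc$records$gene,
                                res$assoc$records$predictor), ]
  k2 <- res2$records[order(res2$records$gene, res2$records$predictor), ]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("case-specific filtering drops pairs stable in controls", {
  case_res <- list(associations = data.frame(
    gene = c("g1", "g2"), predictor = c("t1", "t2"), q = c(0.01, 0.02),
    stringsAsFactors = FALSE),
    stable_pairs = data.frame(gene = c("g1", "g2", "g3"),
                              predictor = c("t1", "t2", "t9"),
                              stability_freq = c(1, 1, 0.7),
                              stringsAsFactors = FALSE))
  ctrl_res <- list(stable_pairs = data.frame(gene = "g2", predictor = "t2",
                                             stability_freq = 0.65,
                                             stringsAsFactors = FALSE))
  out <- case_specific_associations(case_res, ctrl_res)
  expect_identical(out$associations$gene, "g1")
  expect_equal(out$n_overlap, 1)
  # empty control set leaves the case table unchanged
  out2 <- case_specific_associations(case_res,
                                     list(stable_pairs = ctrl_res$stable_pairs[0, ]))
  expect_equal(nrow(out2$associations), 2)
})
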