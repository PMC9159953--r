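#' @name lasso_assoc
#' @title Gene-wise lasso associations with debiased inference and stability
#'   selection
#' @description
#' Each host gene's (transformed, centred) expression is regressed on the
#' standardized predictor matrix of CLR taxa plus encoded covariates with a
#' lasso whose penalty is chosen by leave-one-out CV; per-predictor p-values
#' and confidence intervals come from the desparsified (debiased) lasso via
#' nodewise regressions; robustness comes from stability selection with a
#' perturbed penalty. Records surviving the final filter satisfy
#' `q < 0.1 & f >= f_thr & kind == "taxon"`.
NULL

lasso_lambda_grid <- function(X, y, nlambda = 100, ratio = 1e-3) {
  n <- length(y)
  lmax <- max(abs(crossprod(X, y))) / n
  if (lmax == 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

#' Lasso path with leave-one-out CV penalty selection
#'
#' Coordinate-descent path (warm starts, glmnet objective
#' `(1/2n)||y - Xb||^2 + lambda ||b||_1`) over 100 log-spaced penalties from
#' `lambda_max = max|X'y|/n` down to `1e-3 lambda_max`; `lambda_best`
#' minimizes the leave-one-out mean squared error; the returned coefficients
#' are the full-data fit at `lambda_best`.
#'
#' @param y centred response vector.
#' @param X standardized samples x predictors matrix.
#' @param nlambda grid size.
#' @return list with `beta` (named coefficients), `lambda_best`, `lambda_grid`,
#'   `cv_mse`.
#' @export
fit_lasso_path <- function(y, X, nlambda = 100) {
  if (is.null(dim(X)) || ncol(X) == 0)
    abort_stage("fit_lasso_path", "no predictors")
  y <- y - mean(y)
  grid <- lasso_lambda_grid(X, y, nlambda)
  cv_mse <- as.vector(lasso_loo_mse(X, y, grid))
  best <- which.min(cv_mse)
  B <- lasso_path_cd(X, y, grid)
  beta <- stats::setNames(B[, best], colnames(X))
  list(beta = beta, lambda_best = grid[best], lambda_grid = grid,
       cv_mse = cv_mse)
}

#' Nodewise projections for the desparsified lasso
#'
#' Regresses each design column on all others with a 10-fold-CV lasso and
#' stores the residual (projection) vectors; these depend only on the design,
#' so they are computed once per cohort-group and reused by every gene model.
#'
#' @param X standardized samples x predictors matrix.
#' @param seed integer seed for the CV folds.
#' @param nfolds folds for the nodewise CV.
#' @param resid_floor minimum fraction of a column's variance the nodewise
#'   projection must leave unexplained (default 0.05); the penalty is raised
#'   above its CV minimum until the floor holds, keeping the debiasing
#'   remainder controlled on (near-)exactly collinear designs such as CLR
#'   compositions.
#' @param on_collinear what to do with columns whose projection is degenerate
#'   (e.g. exact duplicates, as arise when a lineage is a singleton chain
#'   across taxonomic ranks): `"flag"` marks them so inference reports an
#'   infinite SE and p = 1; `"error"` aborts.
#' @return list with `Z` (projection matrix), `zx` (`diag(Z'X)`) and
#'   `degenerate` (logical per column), used by [desparsified_inference()].
#' @export
desparsify_design <- function(X, seed = 1L, nfolds = 10, resid_floor = 0.05,
                              on_collinear = c("flag", "error")) {
  on_collinear <- match.arg(on_collinear)
  n <- nrow(X); p <- ncol(X)
  Z <- matrix(0, n, p, dimnames = dimnames(X))
  if (p == 1) {
    Z[, 1] <- X[, 1]
  } else {
    with_seed(seed, {
      for (j in seq_len(p)) {
        Xj <- X[, -j, drop = FALSE]
        xj <- X[, j] - mean(X[, j])
        grid <- lasso_lambda_grid(Xj, xj, 100)
        foldid <- sample(rep_len(seq_len(min(nfolds, n)), n))
        mse <- as.vector(lasso_kfold_mse(Xj, xj, grid, foldid))
        B <- lasso_path_cd(Xj, xj, grid)
        R <- xj - Xj %*% B
        resid_frac <- colSums(R^2) / (n * stats::var(xj) *
                                        (n - 1) / n)
        # residual floor: when a column is (near-)exactly predictable from
        # the others -- the CLR closure makes every taxon a linear
        # combination of the rest -- the CV-min projection vanishes and the
        # debiasing remainder term blows up; back off to the smallest
        # penalty that keeps at least `resid_floor` of the variance
        # unexplained (Zhang-Zhang-style restricted projection)
        best <- which.min(mse)
        while (best > 1 && resid_frac[best] < resid_floor) best <- best - 1
        Z[, j] <- R[, best]
      }
    })
  }
  zx <- colSums(Z * X)
  # identifiability guard: exact duplicates (|cor| ~ 1 with another column)
  # or a numerically vanished projection. Diffuse near-collinearity (e.g.
  # the CLR closure, where each taxon is a linear combination of all the
  # others) is left to the regularized projections themselves.
  cm <- abs(stats::cor(X)); diag(cm) <- 0
  degenerate <- apply(cm, 2, max) > 1 - 1e-8 |
    colSums(Z^2) / n < 1e-10 | abs(zx) / n < 1e-10
  if (any(degenerate)) {
    msg <- paste0("collinear design; degenerate projection for: ",
                  paste(colnames(X)[degenerate], collapse = ", "))
    if (on_collinear == "error") abort_stage("desparsify_design", msg)
    warning("desparsify_design: ", msg, "; SE flagged infinite")
  }
  list(Z = Z, zx = zx, degenerate = degenerate)
}

#' Desparsified-lasso estimates, confidence intervals and p-values
#'
#' Bias-corrects the lasso fit with the nodewise projections,
#' `b_j = beta_j + Z_j'(y - X beta) / (Z_j'X_j)`, with
#' `SE_j = sigma ||Z_j||_2 / |Z_j'X_j|` and the residual noise estimate
#' `sigma^2 = RSS / (n - #nonzero)`; the estimator is asymptotically normal,
#' and because sigma is estimated, p-values and 95% confidence intervals use
#' a Student-t reference with `n - #nonzero` degrees of freedom (equivalent
#' to the normal reference as n grows, calibrated in the far tail at the
#' cohort sizes this pipeline targets).
#'
#' @param y centred response.
#' @param X standardized design.
#' @param beta lasso coefficients at the selected penalty.
#' @param nodewise result of [desparsify_design()] for this X (computed if
#'   NULL).
#' @param seed used only when `nodewise` must be computed.
#' @return data.frame with `predictor`, `beta`, `estimate`, `se`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
desparsified_inference <- function(y, X, beta, nodewise = NULL, seed = 1L) {
  if (is.null(nodewise)) nodewise <- desparsify_design(X, seed = seed)
  n <- length(y)
  y <- y - mean(y)
  resid <- drop(y - X %*% beta)
  s <- sum(beta != 0)
  df <- max(n - s, 1)
  sigma <- sqrt(sum(resid^2) / df)
  degen <- nodewise$degenerate %||% rep(FALSE, ncol(X))
  zx <- ifelse(degen, 1, nodewise$zx)
  b <- beta + drop(crossprod(nodewise$Z, resid)) / zx
  se_classic <- sigma * sqrt(colSums(nodewise$Z^2)) / abs(zx)
  # heteroscedasticity guard: sandwich variance of Z_j'resid with the same
  # df correction; counts (e.g. RNA-seq) leave the log-scale residuals
  # heteroscedastic, and the far tail of the classical SE is what the
  # pooled BH correction is most sensitive to
  se_sand <- sqrt(drop(crossprod(nodewise$Z^2, resid^2)) * n / df) / abs(zx)
  se <- pmax(se_classic, se_sand)
  b[degen] <- beta[degen]
  se[degen] <- Inf
  if (sigma == 0) {
    warning("perfect fit (sigma = 0); p set to 0 for nonzero estimates")
    p <- ifelse(b != 0, 0, 1)
    se <- rep(0, length(b))
  } else {
    p <- 2 * stats::pt(-abs(b / se), df = df)
  }
  half <- stats::qt(0.975, df = df) * se
  data.frame(predictor = colnames(X) %||% paste0("V", seq_len(ncol(X))),
             beta = unname(beta),
             estimate = unname(b), se = unname(se), p = unname(p),
             ci_low = unname(b - half), ci_high = unname(b + half),
             stringsAsFactors = FALSE)
}

#' Stability selection with a perturbed penalty
#'
#' K rounds, each fitting the lasso on a random half of the samples at a
#' penalty drawn uniformly in a neighbourhood of `lambda_best`; the selection
#' frequency per predictor is the fraction of rounds in which its coefficient
#' is nonzero, and predictors with frequency at least `f_thr` form the stable
#' set.
#'
#' @param y centred response.
#' @param X standardized design.
#' @param lambda_best penalty from [fit_lasso_path()].
#' @param K number of subsampling rounds (default 100).
#' @param frac subsample fraction (default 0.5, i.e. `floor(n/2)` samples).
#' @param f_thr stability threshold (default 0.6).
#' @param perturb multiplicative penalty perturbation range (default
#'   `c(0.8, 1.2)`).
#' @param seed integer seed.
#' @return list with `freq` (named frequencies) and `stable` (predictor IDs).
#' @export
stability_select <- function(y, X, lambda_best, K = 100, frac = 0.5,
                             f_thr = 0.6, perturb = c(0.8, 1.2), seed = 1L) {
  n <- length(y)
  m <- floor(n * frac)
  if (m < 10) abort_stage("stability_select", "subsample smaller than 10")
  y <- y - mean(y)
  draws <- with_seed(seed, list(
    idx = vapply(seq_len(K), function(k) sample.int(n, m), integer(m)),
    lam = lambda_best * stats::runif(K, perturb[1], perturb[2])))
  counts <- as.vector(stability_counts_cd(X, y, draws$idx, draws$lam))
  freq <- stats::setNames(counts / K, colnames(X))
  list(freq = freq, stable = names(freq)[freq >= f_thr], f_thr = f_thr, K = K)
}

# build the standardized predictor matrix (CLR taxa + 0/1 covariates) for one
# group; returns the matrix plus the kind of each retained column
build_predictors <- function(prep, samples, covariates = c("sex", "subtype")) {
  taxa <- prep$taxa[samples, , drop = FALSE]
  kinds <- rep("taxon", ncol(taxa))
  covs <- intersect(covariates, colnames(prep$metadata))
  X <- taxa
  for (cv in covs) {
    val <- prep$metadata[[cv]][match(samples, prep$metadata$sample_id)]
    X <- cbind(X, stats::setNames(data.frame(as.numeric(val)), cv))
    kinds <- c(kinds, "covariate")
  }
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 1e-12
  Xs <- scale(X[, keep, drop = FALSE])
  list(X = Xs, kinds = kinds[keep])
}

#' Gene-wise lasso association table for one cohort group
#'
#' For every gene: LOO-CV lasso, desparsified inference and stability
#' selection; all gene x predictor p-values in the group are pooled for one
#' BH correction; the filtered association table keeps records with
#' `q < fdr`, stability frequency `>= f_thr` and predictor kind `"taxon"`,
#' with the Spearman correlation of the raw expression and CLR abundance
#' attached as effect-direction/weight. Per-gene seeds are derived from
#' `seed`, so results are identical whatever the execution order
#' (serial/parallel contract).
#'
#' @param prep output of [preprocess_dataset()].
#' @param group `"case"` or `"ctrl"`.
#' @param fdr BH threshold (default 0.1).
#' @param f_thr stability threshold (default 0.6).
#' @param K_stab stability rounds (default 100).
#' @param covariates metadata columns encoded as 0/1 predictors.
#' @param nlambda lasso path size.
#' @param seed master seed.
#' @return list with `records` (all gene x predictor records),
#'   `associations` (final filtered table), `stable_pairs` (pre-threshold
#'   stability-selected gene/taxon pairs), `group`, `n`.
#' @export
genewise_associations <- function(prep, group = "case", fdr = 0.1,
                                  f_thr = 0.6, K_stab = 100,
                                  covariates = c("sex", "subtype"),
                                  nlambda = 100, seed = 1L) {
  samples <- prep$metadata$sample_id[prep$metadata$group == group]
  samples <- intersect(samples, rownames(prep$expr))
  if (length(samples) == 0)
    abort_stage("genewise_associations", "no samples in group ", group)
  pred <- build_predictors(prep, samples, covariates)
  X <- pred$X
  expr <- prep$expr[samples, , drop = FALSE]
  genes <- colnames(expr)
  nodewise <- desparsify_design(X, seed = derive_seed(seed, 7L))
  taxa_cols <- colnames(X)[pred$kinds == "taxon"]
  rho <- stats::cor(expr, prep$taxa[samples, taxa_cols, drop = FALSE],
                    method = "spearman")

  recs <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    y <- expr[, g] - mean(expr[, g])
    if (stats::sd(y) < 1e-12) next
    fit <- fit_lasso_path(y, X, nlambda = nlambda)
    inf <- desparsified_inference(y, X, fit$beta, nodewise = nodewise)
    st <- stability_select(y, X, fit$lambda_best, K = K_stab, f_thr = f_thr,
                           seed = derive_seed(seed, 1000L, id_hash(g)))
    inf$gene <- g
    inf$kind <- pred$kinds[match(inf$predictor, colnames(X))]
    inf$stability_freq <- unname(st$freq[inf$predictor])
    inf$lambda_best <- fit$lambda_best
    inf$spearman_rho <- ifelse(inf$kind == "taxon",
                               rho[g, match(inf$predictor, taxa_cols)],
                               NA_real_)
    recs[[gi]] <- inf
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    abort_stage("genewise_associations", "no testable genes")
  # one BH correction across the cohort-group, within the discovery family:
  # gene-taxon tests form the family of interest; covariate tests are
  # nuisance adjustments and are corrected separately so their (often real)
  # effects do not relax the threshold for taxon discoveries
  records$q <- NA_real_
  for (knd in unique(records$kind)) {
    sel <- records$kind == knd
    records$q[sel] <- stats::p.adjust(records$p[sel], method = "BH")
  }
  associations <- records[records$q < fdr &
                            records$stability_freq >= f_thr &
                            records$kind == "taxon", , drop = FALSE]
  stable_pairs <- records[records$stability_freq >= f_thr &
                            records$kind == "taxon",
                          c("gene", "predictor", "stability_freq"),
                          drop = FALSE]
  rownames(associations) <- rownames(stable_pairs) <- NULL
  list(records = records, associations = associations,
       stable_pairs = stable_pairs, group = group, n = length(samples))
}

#' Case-specific association filtering
#'
#' Removes from the case association table any (gene, taxon) pair present in
#' the control group's pre-threshold stability-selected set — overlap is
#' judged without any p/FDR cut-off, so case-specificity is robust to the
#' significance threshold.
#'
#' @param case_res,ctrl_res outputs of [genewise_associations()] for the two
#'   groups of one cohort.
#' @return list with `associations` (case-only table), `overlap` (excluded
#'   pairs), `n_overlap`.
#' @export
case_specific_associations <- function(case_res, ctrl_res) {
  key <- function(df) paste(df$gene, df$predictor, sep = "\r")
  ctrl_keys <- key(ctrl_res$stable_pairs)
  case_tab <- case_res$associations
  shared <- key(case_tab) %in% ctrl_keys
  pre_shared <- key(case_res$stable_pairs) %in% ctrl_keys
  list(associations = case_tab[!shared, , drop = FALSE],
       overlap = case_res$stable_pairs[pre_shared, , drop = FALSE],
       n_overlap = sum(pre_shared))
}
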