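#' @name validation
#' @title Simulation studies validating the pipeline's statistical engine
#' @description
#' Self-contained simulation studies used by the test suite and the
#' reproduction script: oracle comparisons (PMD vs SVD, Fisher vs
#' hypergeometric, lasso vs closed form), planted-truth recovery, null
#' calibration, and an end-to-end determinism check. Every study takes a
#' seed and returns plain numbers.
NULL

#' PMD against the SVD oracle at maximal penalties
#'
#' With both l1 bounds at `sqrt(dim)` the penalized decomposition must equal
#' the leading singular triplet. Runs random instances of the given shapes
#' and returns the worst absolute deviation of `d`, `|u'u1|` and `|v'v1|`.
#'
#' @param n_instances instances per shape (default 100).
#' @param shapes list of `c(nrow, ncol)` shapes.
#' @param seed integer seed.
#' @return max absolute deviation across instances (0 = exact agreement).
#' @export
pmd_svd_gap <- function(n_instances = 100,
                        shapes = list(c(20, 15), c(20, 10)), seed = 1L) {
  gap <- 0
  with_seed(seed, {
    for (shape in shapes) {
      for (i in seq_len(n_instances)) {
        C <- matrix(rnorm(shape[1] * shape[2]), shape[1])
        f <- pmd_rank1(C, sqrt(shape[1]), sqrt(shape[2]), tol = 1e-8,
                       max_iter = 500)
        sv <- svd(C)
        gap <- max(gap, abs(f$d - sv$d[1]),
                   abs(1 - abs(drop(crossprod(f$u, sv$u[, 1])))),
                   abs(1 - abs(drop(crossprod(f$v, sv$v[, 1])))))
      }
    }
  })
  gap
}

# simulate one cohort, preprocess at OTU level, return the standardized
# case-group matrices plus truth
sim_case_xy <- function(seed, n_case, n_genes, n_otus, n_latent = 0,
                        genes_per_factor = 0, taxa_per_factor = 0,
                        latent_effect = 1.5, n_direct_pairs = 0,
                        direct_effect = 1.5) {
  cfg <- sim_config(n_case = n_case, n_ctrl = 5, n_genes = n_genes,
                    n_otus = n_otus, n_latent = n_latent,
                    genes_per_factor = genes_per_factor,
                    taxa_per_factor = taxa_per_factor,
                    latent_effect = latent_effect,
                    n_direct_pairs = n_direct_pairs,
                    direct_effect = direct_effect, seed = seed)
  sim <- simulate_paired_dataset(cfg)
  prep <- preprocess_dataset(sim$dataset, combine_ranks = FALSE)
  smp <- prep$metadata$sample_id[prep$metadata$group == "case"]
  list(X = standardize_columns(prep$taxa[smp, , drop = FALSE]),
       Y = standardize_columns(prep$expr[smp, , drop = FALSE]),
       prep = prep, truth = sim$truth)
}

#' Sparse CCA support recovery and held-out power study
#'
#' Plants a single latent factor (10% of genes and taxa active, loading
#' `effect`) and measures, over seeds, the sensitivity and precision of
#' component 1's nonzero loadings against the planted supports, and how
#' often component 1 reaches held-out significance (q < 0.1).
#'
#' @param n_seeds number of simulated cohorts (default 50).
#' @param n samples per cohort (default 60).
#' @param n_genes,n_otus feature counts (defaults 200/50).
#' @param effect latent loading magnitude (default 1.5).
#' @param lambda penalty fraction for both views (default 0.3).
#' @param K components fitted per run (default 5).
#' @param seed master seed.
#' @return list with mean `sensitivity`, mean `precision`, `power`
#'   (fraction of seeds with component-1 q < 0.1).
#' @export
scca_recovery_study <- function(n_seeds = 50, n = 60, n_genes = 200,
                                n_otus = 50, effect = 1.5, lambda = 0.3,
                                K = 5, seed = 1L) {
  sens <- prec <- pow <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    xy <- sim_case_xy(derive_seed(seed, 61L, s), n, n_genes, n_otus,
                      n_latent = 1,
                      genes_per_factor = round(0.1 * n_genes),
                      taxa_per_factor = round(0.1 * n_otus),
                      latent_effect = effect)
    sc <- suppressWarnings(
      scca_run(xy$X, xy$Y, lambda_taxa = lambda, lambda_genes = lambda,
               K = K, mode = "full"))
    u <- sc$components[[1]]$u; v <- sc$components[[1]]$v
    tsup <- intersect(paste0("otu:", xy$truth$latent_taxon_support[[1]]),
                      colnames(xy$X))
    gsup <- intersect(xy$truth$latent_gene_support[[1]], colnames(xy$Y))
    sel <- c(names(u)[u != 0], names(v)[v != 0])
    truth <- c(tsup, gsup)
    sens[s] <- length(intersect(sel, truth)) / length(truth)
    prec[s] <- length(intersect(sel, truth)) / max(1, length(sel))
    pow[s] <- sc$summary$q[1] < 0.1
  }
  list(sensitivity = mean(sens), precision = mean(prec), power = mean(pow))
}

#' Type-I error of held-out component significance under the null
#'
#' Independent Gaussian X and Y; reports how often any of the K components
#' reaches q < 0.1 (BH within run).
#'
#' @param n_seeds number of null datasets (default 100).
#' @param n,p_taxa,p_genes dimensions (defaults 60, 50, 200).
#' @param lambda penalty fraction (default 0.3).
#' @param K components per run (default 5).
#' @param seed master seed.
#' @return fraction of seeds with any significant component.
#' @export
scca_type1_study <- function(n_seeds = 100, n = 60, p_taxa = 50,
                             p_genes = 200, lambda = 0.3, K = 5, seed = 1L) {
  hits <- 0
  for (s in seq_len(n_seeds)) {
    xy <- with_seed(derive_seed(seed, 62L, s), {
      list(X = scale(matrix(rnorm(n * p_taxa), n)),
           Y = scale(matrix(rnorm(n * p_genes), n)))
    })
    colnames(xy$X) <- paste0("t", seq_len(p_taxa))
    colnames(xy$Y) <- paste0("g", seq_len(p_genes))
    sc <- suppressWarnings(
      scca_run(xy$X, xy$Y, lambda_taxa = lambda, lambda_genes = lambda,
               K = K, mode = "full"))
    hits <- hits + any(sc$summary$q < 0.1)
  }
  hits / n_seeds
}

#' Lasso closed form on an orthonormal design
#'
#' Under `X'X = n I` the lasso equals elementwise soft-thresholded OLS;
#' returns the worst deviation over a penalty grid.
#'
#' @param n,p design size (defaults 60, 12).
#' @param seed integer seed.
#' @return max absolute coefficient gap.
#' @export
lasso_orthonormal_gap <- function(n = 60, p = 12, seed = 1L) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(n * p), n)))[, seq_len(p)] * sqrt(n)
    beta <- c(2, -1.5, 1, rep(0, p - 3))
    y <- drop(q %*% beta) + rnorm(n, 0, 0.3)
    y <- y - mean(y)
    ols <- drop(crossprod(q, y)) / n
    grid <- lasso_lambda_grid(q, y, 50)
    B <- lasso_path_cd(q, y, grid, tol = 1e-16)
    max(abs(B - vapply(grid, function(l) soft_threshold(ols, l),
                       numeric(p))))
  })
}

#' Desparsified-lasso confidence-interval coverage under the null
#'
#' Gaussian designs with a zero coefficient vector; reports the empirical
#' coverage of the 95% intervals over `n_designs * p` coefficients.
#'
#' @param n_designs independent designs (default 4).
#' @param n,p design size (defaults 100, 50).
#' @param seed master seed.
#' @return empirical coverage in `[0, 1]`.
#' @export
despars_coverage_study <- function(n_designs = 4, n = 100, p = 50,
                                   seed = 1L) {
  cover <- c()
  for (s in seq_len(n_designs)) {
    dat <- with_seed(derive_seed(seed, 63L, s), {
      X <- scale(matrix(rnorm(n * p), n))
      colnames(X) <- paste0("V", seq_len(p))
      list(X = X, y = rnorm(n))
    })
    y <- dat$y - mean(dat$y)
    f <- fit_lasso_path(y, dat$X)
    inf <- desparsified_inference(y, dat$X, f$beta,
                                  seed = derive_seed(seed, 64L, s))
    cover <- c(cover, inf$ci_low <= 0 & 0 <= inf$ci_high)
  }
  mean(cover)
}

#' Gene-wise association recovery and null survival study
#'
#' Recovery arm: plants `n_pairs` direct gene~taxon effects and measures the
#' fraction of truth recovered and the fraction of reported pairs that are
#' false, per seed (medians returned). Null arm: no planted effects;
#' reports the fraction of seeds with zero surviving records.
#'
#' @param n_seeds seeds per arm (default 10).
#' @param n samples in the analyzed group (default 80).
#' @param n_genes,n_otus feature counts (defaults 200/50).
#' @param n_pairs planted pairs (default 10).
#' @param effect planted coefficient (default 1.5).
#' @param seed master seed.
#' @return list with `recovery_median`, `false_rate_median`,
#'   `null_zero_rate`.
#' @export
assoc_recovery_study <- function(n_seeds = 10, n = 80, n_genes = 200,
                                 n_otus = 50, n_pairs = 10, effect = 1.5,
                                 seed = 1L) {
  rec <- fal <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    xs <- derive_seed(seed, 65L, s)
    cfg <- sim_config(n_case = n, n_ctrl = 5, n_genes = n_genes,
                      n_otus = n_otus, n_latent = 0, genes_per_factor = 0,
                      taxa_per_factor = 0, n_direct_pairs = n_pairs,
                      direct_effect = effect, seed = xs)
    sim <- simulate_paired_dataset(cfg)
    prep <- preprocess_dataset(sim$dataset, combine_ranks = FALSE)
    la <- suppressWarnings(genewise_associations(prep, "case", seed = xs))
    truth <- paste(sim$truth$direct_pairs$gene,
                   paste0("otu:", sim$truth$direct_pairs$taxon))
    found <- paste(la$associations$gene, la$associations$predictor)
    rec[s] <- sum(truth %in% found) / length(truth)
    fal[s] <- if (length(found)) sum(!found %in% truth) / length(found) else 0
  }
  zero <- 0
  for (s in seq_len(n_seeds)) {
    xs <- derive_seed(seed, 66L, s)
    cfg <- sim_config(n_case = n, n_ctrl = 5, n_genes = n_genes,
                      n_otus = n_otus, n_latent = 0, genes_per_factor = 0,
                      taxa_per_factor = 0, n_direct_pairs = 0, seed = xs)
    sim <- simulate_paired_dataset(cfg)
    prep <- preprocess_dataset(sim$dataset, combine_ranks = FALSE)
    la <- suppressWarnings(genewise_associations(prep, "case", seed = xs))
    zero <- zero + (nrow(la$associations) == 0)
  }
  list(recovery_median = stats::median(rec),
       false_rate_median = stats::median(fal),
       null_zero_rate = zero / n_seeds)
}

#' Fisher p against the exhaustive hypergeometric tail
#'
#' Random 2x2 tables with total at most `max_total`; the one-sided Fisher p
#' must equal the hypergeometric upper tail summed by enumeration.
#'
#' @param n_tables number of random tables (default 500).
#' @param max_total largest table total (default 200).
#' @param seed integer seed.
#' @return max absolute difference across tables.
#' @export
fisher_oracle_gap <- function(n_tables = 500, max_total = 200, seed = 1L) {
  with_seed(seed, {
    gap <- 0
    for (i in seq_len(n_tables)) {
      N <- sample(20:max_total, 1)
      K <- sample(1:(N - 1), 1)             # pathway size
      nI <- sample(1:(N - 1), 1)            # interest size
      n1 <- sample(max(0, K + nI - N):min(K, nI), 1)
      tab <- matrix(c(n1, K - n1, nI - n1, N - K - nI + n1), 2,
                    byrow = TRUE)
      p_f <- stats::fisher.test(tab, alternative = "greater")$p.value
      # enumeration over all attainable overlap values
      hi <- min(K, nI)
      p_h <- sum(vapply(n1:hi, function(k)
        exp(lchoose(K, k) + lchoose(N - K, nI - k) - lchoose(N, nI)),
        numeric(1)))
      gap <- max(gap, abs(p_f - p_h))
    }
    gap
  })
}

#' Differential-enrichment formula properties
#'
#' Checks the comparative log-odds z statistic on fixed tables: zero on
#' identical tables, exact antisymmetry under arm swap, and agreement with
#' direct arithmetic.
#'
#' @return list with `identical_z`, `antisymmetry_gap`, `formula_gap`.
#' @export
differential_formula_props <- function() {
  mk <- function(n1, n2, n3, n4)
    data.frame(pathway = "pw", n1 = n1, n2 = n2, n3 = n3, n4 = n4,
               odds_ratio = 1, p = 0.5, q = 0.5, stringsAsFactors = FALSE)
  ident <- differential_enrichment(mk(10, 10, 10, 70), mk(10, 10, 10, 70))
  fwd <- differential_enrichment(mk(10, 10, 10, 70), mk(2, 18, 18, 62))
  rev <- differential_enrichment(mk(2, 18, 18, 62), mk(10, 10, 10, 70))
  lor <- function(x) log(x[1] * x[4] / (x[2] * x[3]))
  sef <- function(x) sqrt(sum(1 / x))
  oracle <- (lor(c(10, 10, 10, 70)) - lor(c(2, 18, 18, 62))) /
    sqrt(sef(c(10, 10, 10, 70))^2 + sef(c(2, 18, 18, 62))^2)
  list(identical_z = ident$z_diff,
       antisymmetry_gap = abs(fwd$z_diff + rev$z_diff),
       formula_gap = abs(fwd$z_diff - oracle))
}

#' Null calibration of the Procrustes and Mantel tests
#'
#' Independent Gaussian point clouds at `n` samples; reports the rejection
#' rates at alpha = 0.05 over replicates, plus the self-agreement p-value
#' (identical distance matrices), which must equal `1/(n_perm + 1)`.
#'
#' @param n_reps replicates (default 500).
#' @param n samples (default 20).
#' @param n_perm permutations per test (default 999).
#' @param seed master seed.
#' @return list with `procrustes_rejection`, `mantel_rejection`,
#'   `self_agreement_p`.
#' @export
concordance_calibration_study <- function(n_reps = 500, n = 20,
                                          n_perm = 999, seed = 1L) {
  rej_p <- rej_m <- 0
  for (r in seq_len(n_reps)) {
    d <- with_seed(derive_seed(seed, 67L, r), {
      list(a = stats::dist(matrix(rnorm(n * 8), n)),
           b = stats::dist(matrix(rnorm(n * 8), n)))
    })
    pp <- procrustes_test(d$a, d$b, n_perm = n_perm,
                          seed = derive_seed(seed, 68L, r))$procrustes_p
    pm <- mantel_test(d$a, d$b, n_perm = n_perm,
                      seed = derive_seed(seed, 69L, r))$mantel_p
    rej_p <- rej_p + (pp < 0.05)
    rej_m <- rej_m + (pm < 0.05)
  }
  d0 <- with_seed(seed, stats::dist(matrix(rnorm(n * 5), n)))
  self_p <- procrustes_test(d0, d0, n_perm = n_perm,
                            seed = seed)$procrustes_p
  list(procrustes_rejection = rej_p / n_reps,
       mantel_rejection = rej_m / n_reps, self_agreement_p = self_p)
}

#' End-to-end determinism of run + compare on three synthetic cohorts
#'
#' Runs three cohorts and the cross-cohort comparison twice under one master
#' seed and checks that every written table is byte-identical.
#'
#' @param seed master seed.
#' @param base_dir scratch directory (a tempdir by default).
#' @return list with `identical` (logical) and `n_files` compared.
#' @export
e2e_determinism_study <- function(seed = 1L, base_dir = tempfile("e2e")) {
  cfgs <- lapply(1:3, function(i)
    sim_config(n_case = 20, n_ctrl = 20, n_genes = 60, n_otus = 18,
               n_latent = 1, genes_per_factor = 6, taxa_per_factor = 3,
               n_direct_pairs = 3, direct_effect = 2, seq_depth_mean = 5000,
               seed = derive_seed(seed, 70L, i)))
  run_all <- function(tag) {
    out <- file.path(base_dir, tag)
    runs <- lapply(seq_along(cfgs), function(i) {
      sim <- simulate_paired_dataset(cfgs[[i]])
      suppressWarnings(run_cohort(
        sim$dataset,
        cohort_config(cohort = paste0("C", i), seed = derive_seed(seed, 71L),
                      n_perm = 49, scca_K = 2, lambda_taxa = 0.3,
                      lambda_genes = 0.3, K_stab = 30, nlambda = 50),
        file.path(out, paste0("C", i))))
    })
    names(runs) <- paste0("C", 1:3)
    compare_cohorts(runs, file.path(out, "compare"))
    out
  }
  d1 <- run_all("r1"); d2 <- run_all("r2")
  f1 <- list.files(d1, recursive = TRUE, full.names = FALSE)
  f1 <- f1[grepl("[.](tsv|json)$", f1)]
  same <- vapply(f1, function(f)
    identical(readLines(file.path(d1, f), warn = FALSE),
              readLines(file.path(d2, f), warn = FALSE)), logical(1))
  unlink(base_dir, recursive = TRUE)
  list(identical = all(same), n_files = length(f1))
}
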