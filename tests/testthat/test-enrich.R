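test_that("Fisher enrichment p equals the hypergeometric upper tail", {
  # fixed table (n1..n4) = (5, 5, 10, 80): set size 10, interest 15, bkg 100
  bkg <- sprintf("g%03d", 1:100)
  interest <- bkg[1:15]
  set <- c(bkg[1:5], bkg[16:20])      # 5 in interest, 5 outside
  coll <- list(pw = set)
  out <- fisher_enrichment(interest, bkg, coll, profile = "lasso")
  expect_equal(out$n1, 5); expect_equal(out$n2, 5)
  expect_equal(out$n3, 10); expect_equal(out$n4, 80)
  # oracle: exhaustive hypergeometric tail P[X >= 5], drawing 15 from 10/90
  oracle <- sum(dhyper(5:10, 10, 90, 15))
  expect_equal(out$p, oracle, tolerance = 1e-12)

  # random tables against the phyper oracle
  set.seed(2)
  for (i in 1:100) {
    N <- sample(30:200, 1)
    K <- sample(5:(N - 10), 1)          # pathway size
    nI <- sample(5:(N - 5), 1)          # interest size
    n1 <- max(5, min(K, nI, sample(5:15, 1)))
    if (n1 > min(K, nI)) next
    tab <- matrix(c(n1, K - n1, nI - n1, N - K - nI + n1), 2, byrow = TRUE)
    if (any(tab < 0)) next
    p_fisher <- fisher.test(tab, alternative = "greater")$p.value
    p_hyper <- sum(dhyper(n1:min(K, nI), K, N - K, nI))
    expect_equal(p_fisher, p_hyper, tolerance = 1e-10)
  }
})

test_that("profile size filters and the overlap floor are enforced", {
  bkg <- sprintf("g%03d", 1:200)
  interest <- bkg[1:30]
  coll <- list(small = bkg[1:9],              # < 10 for lasso profile
               low_overlap = c(bkg[1:4], bkg[100:110]),   # overlap 4
               ok = c(bkg[1:8], bkg[120:130]))
  out <- fisher_enrichment(interest, bkg, coll, profile = "lasso")
  expect_identical(out$pathway, "ok")
  # scca profile excludes sets under 25 genes
  out2 <- fisher_enrichment(interest, bkg, coll, profile = "scca")
  expect_equal(nrow(out2), 0)
  expect_error(fisher_enrichment(c(interest, "zzz"), bkg, coll, "lasso"),
               "background")
})

test_that("interest equal to background degenerates to p = 1", {
  bkg <- sprintf("g%03d", 1:80)
  coll <- list(pw = bkg[1:20])
  out <- fisher_enrichment(bkg, bkg, coll, profile = "lasso")
  expect_equal(out$p, 1)
  expect_true(is.finite(out$odds_ratio))   # Haldane-guarded
})

test_that("differential z follows the comparative log-odds formula", {
  mk_rec <- function(n1, n2, n3, n4)
    data.frame(pathway = "pw", n1 = n1, n2 = n2, n3 = n3, n4 = n4,
               odds_ratio = (n1 * n4) / (n2 * n3), p = 0.5, q = 0.5,
               stringsAsFactors = FALSE)
  # identical tables: z_diff = 0, p = 1
  d0 <- differential_enrichment(mk_rec(10, 10, 10, 70), mk_rec(10, 10, 10, 70))
  expect_equal(d0$z_diff, 0)
  expect_equal(d0$p_diff, 1)

  # independent arithmetic oracle on the fixed pair of tables
  ca <- c(10, 10, 10, 70); co <- c(2, 18, 18, 62)
  lor <- function(x) log(x[1] * x[4] / (x[2] * x[3]))
  se <- function(x) sqrt(sum(1 / x))
  z_oracle <- (lor(ca) - lor(co)) / sqrt(se(ca)^2 + se(co)^2)
  d1 <- differential_enrichment(mk_rec(10, 10, 10, 70), mk_rec(2, 18, 18, 62))
  expect_equal(d1$z_diff, z_oracle, tolerance = 1e-12)
  expect_equal(d1$z_case, lor(ca) / se(ca), tolerance = 1e-12)

  # doubling all cells preserves log OR and scales |z_diff| by sqrt(2)
  d2 <- differential_enrichment(mk_rec(20, 20, 20, 140), mk_rec(4, 36, 36, 124))
  expect_equal(d2$z_diff, sqrt(2) * d1$z_diff, tolerance = 1e-12)

  # antisymmetry under swapping case and control
  d3 <- differential_enrichment(mk_rec(2, 18, 18, 62), mk_rec(10, 10, 10, 70))
  expect_equal(d3$z_diff, -d1$z_diff, tolerance = 1e-12)

  # zero cells get the Haldane correction rather than infinities
  d4 <- differential_enrichment(mk_rec(0, 20, 10, 70), mk_rec(5, 15, 10, 70))
  expect_true(is.finite(d4$z_diff))
})

test_that("BH adjustment matches a hand-rolled step-up", {
  set.seed(9)
  p <- runif(20)^2
  bh <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(q, 1); out
  }
  expect_equal(p.adjust(p, "BH"), bh(p), tolerance = 1e-12)
  bkg <- sprintf("g%03d", 1:150)
  coll <- lapply(1:6, function(i) sample(bkg, 30))
  names(coll) <- paste0("pw", 1:6)
  out <- fisher_enrichment(bkg[1:40], bkg, coll, profile = "lasso")
  if (nrow(out)) expect_equal(out$q, bh(out$p), tolerance = 1e-12)
})

test_that("case-specific pathway calling applies the two-part rule", {
  case_recs <- data.frame(pathway = c("a", "b", "c", "d"),
                          p = c(0.001, 0.002, 0.003, 0.5),
                          q = c(0.02, 0.05, 0.05, 0.8),
                          component = c(1L, 2L, 1L, 3L),
                          stringsAsFactors = FALSE)
  ctrl_recs <- data.frame(pathway = c("a", "b", "c", "d"),
                          p = c(0.9, 0.01, 0.01, 0.4),
                          q = c(0.9, 0.05, 0.05, 0.7),
                          stringsAsFactors = FALSE)
  diff_recs <- data.frame(pathway = c("a", "b", "c", "d"),
                          z_diff = c(0, 3, 0.1, 0),
                          q_diff = c(1, 0.1, 0.3, 1),
                          stringsAsFactors = FALSE)
  out <- case_specific_pathways(case_recs, ctrl_recs, diff_recs)
  # a: case-only (part 1); b: both arms + differential (part 2); c: both
  # arms but not differential -> excluded; d: not significant
  expect_setequal(out$pathway, c("a", "b"))
  expect_equal(out$part[out$pathway == "a"], 1L)
  expect_equal(out$part[out$pathway == "b"], 2L)
  expect_equal(out$component[out$pathway == "b"], 2L)
})
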