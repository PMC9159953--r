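mk <- function(v, nr, nc, rn = sprintf("g%02d", seq_len(nr)))
  matrix(v, nr, nc, dimnames = list(rn, sprintf("s%02d", seq_len(nc))))

test_that("expression filter keeps genes expressed in at least half the samples", {
  counts <- mk(0L, 3, 10)
  counts[1, 1:5] <- 4L      # 5 of 10 -> kept
  counts[2, 1:4] <- 4L      # 4 of 10 -> dropped
  counts[3, ] <- 2L
  out <- filter_genes(counts)
  expect_identical(rownames(out), c("g01", "g03"))
  # coding restriction applies regardless of expression
  out2 <- filter_genes(counts, coding_ids = c("g01"))
  expect_identical(rownames(out2), "g01")
  expect_error(filter_genes(counts, coding_ids = "nope"), "no genes pass")
})

test_that("log size-factor transform is depth-invariant and monotone", {
  counts <- mk(rpois(40 * 6, 50) + 1L, 40, 6)
  tr <- variance_stabilize(counts)
  expect_true(all(diff(tr[, 1][order(counts[, 1])]) >= 0))
  # identical samples transform identically
  c2 <- cbind(counts, counts[, 1, drop = FALSE])
  colnames(c2) <- c(colnames(counts), "dup")
  t2 <- variance_stabilize(c2)
  expect_equal(unname(t2[, "dup"]), unname(t2[, 1]))
  # doubling every count in one sample is absorbed by its size factor
  c3 <- counts; c3[, 2] <- 2L * c3[, 2]
  t3 <- variance_stabilize(c3)
  expect_lt(max(abs(t3[, 2] - tr[, 2])), log2(2))
  expect_error(variance_stabilize(rbind(counts, g99 = 0L)), "all-zero")
})

test_that("size factors match the DESeq reference on a fixed matrix", {
  skip_if_not_installed("DESeq2")
  counts <- mk(rpois(60 * 8, 80) + 1L, 60, 8)
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-10)
})

test_that("variance filter keeps the top three quarters with boundary ties", {
  # variances 0,1,2,3 over samples -> 25% quantile 0.75, gene 1 dropped
  m <- rbind(g1 = rep(1, 4), g2 = c(0, 1, 1, 2) * sqrt(3 / 2) + 5,
             g3 = c(0, 1, 1, 2) * sqrt(3), g4 = c(0, 1, 1, 2) * sqrt(9 / 2))
  colnames(m) <- paste0("s", 1:4)
  v <- apply(m, 1, var)
  expect_equal(unname(v), c(0, 1, 2, 3), tolerance = 1e-12)
  expect_identical(rownames(variance_filter(m)), c("g2", "g3", "g4"))
  # all equal variances are all kept; quantile 0 is the identity
  m2 <- rbind(a = c(1, 2), b = c(3, 4))
  colnames(m2) <- c("s1", "s2")
  expect_identical(variance_filter(m2), m2)
  expect_identical(variance_filter(m, quantile = 0), m)
  expect_error(variance_filter(m[, 1, drop = FALSE]), "2 samples")
})

test_that("rank summarization sums members, skips unlabelled, blocks contaminants", {
  tx <- data.frame(otu_id = c("o1", "o2", "o3"),
                   phylum = c("pA", "pA", "pB"),
                   genus = c("gX", "gX", "gY"),
                   species = c("s1", NA, "s3"),
                   stringsAsFactors = FALSE)
  counts <- mk(c(3L, 4L, 5L), 3, 2, rn = tx$otu_id)
  counts[] <- c(3, 4, 5, 3, 4, 5)
  out <- summarize_ranks(counts, tx)
  expect_equal(unname(out$genus["genus:gX", ]), c(7, 7))
  expect_false("species:NA" %in% rownames(out$species))
  expect_true("genus:gX" %in% rownames(out$genus))
  expect_equal(nrow(out$species), 2)   # o2 missing from species only
  out2 <- summarize_ranks(counts, tx, blocklist = "pA")
  expect_false(any(grepl("gX", rownames(out2$genus))))
  expect_error(summarize_ranks(rbind(counts, o9 = 1), tx), "o9")
})

test_that("prevalence filter applies inclusive thresholds with a ceiling", {
  m <- mk(1L, 2, 10, rn = c("t1", "t2"))
  m[1, ] <- c(4, 4, rep(0, 8))       # rel 0.002 in 2 of 10 samples
  m[2, ] <- 1                        # rel ~5e-4 under depth 2000
  depth_fill <- 2000 - colSums(m)
  m <- rbind(m, filler = depth_fill)
  out <- prevalence_filter(m)
  expect_true("t1" %in% rownames(out))   # 2 >= ceiling(1)
  expect_false("t2" %in% rownames(out))
  # boundary: exactly 0.001 abundance in exactly ceiling(0.1 n) samples
  m2 <- rbind(t = c(2, rep(0, 9)), f = c(1998, rep(1000, 9)))
  colnames(m2) <- paste0("s", 1:10)
  expect_true("t" %in% rownames(prevalence_filter(m2)))
  m3 <- m2; m3[, 1] <- 0
  expect_error(prevalence_filter(m3), "zero-depth")
})

test_that("combined CLR has closed-form values and scale invariance", {
  tabs <- list(r1 = mk(c(1L, 1L), 2, 1, rn = c("r1:a", "r1:b")))
  tabs$r1[] <- c(1, 1)
  # flat composition maps to zero
  flat <- combine_and_clr(list(x = matrix(c(1, 1, 1, 1), 4, 1,
    dimnames = list(paste0("x:t", 1:4), "s1"))), pseudocount = 0)
  expect_equal(unname(flat["s1", ]), rep(0, 4))
  two <- combine_and_clr(list(x = matrix(c(2, 8), 2, 1,
    dimnames = list(c("x:a", "x:b"), "s1"))), pseudocount = 0)
  expect_equal(unname(two["s1", ]), c(log(2) - log(4), log(8) - log(4)),
               tolerance = 1e-9)
  # per-sample scaling leaves CLR unchanged
  a <- matrix(c(2, 8, 20, 80), 2, 2, dimnames = list(c("x:a", "x:b"),
                                                     c("s1", "s2")))
  clr <- combine_and_clr(list(x = a), pseudocount = 0)
  expect_equal(unname(clr["s1", ]), unname(clr["s2", ]), tolerance = 1e-12)
  # rows sum to zero
  expect_lt(max(abs(rowSums(clr))), 1e-8)
  dup <- list(x = a, y = a)
  expect_error(combine_and_clr(dup), "duplicate")
})

test_that("the two CLR strategies coincide on a single rank", {
  a <- mk(rpois(8 * 5, 30) + 1L, 8, 5, rn = paste0("g:t", 1:8))
  cmp <- compare_clr_strategies(list(genus = a))
  expect_equal(cmp$mean_pearson, 1, tolerance = 1e-12)
  expect_equal(cmp$mean_spearman, 1, tolerance = 1e-12)
})

test_that("timepoint averaging takes subject means on the count scale", {
  cfg <- sim_config(n_case = 6, n_ctrl = 6, n_genes = 20, n_otus = 10,
                    genes_per_factor = 4, taxa_per_factor = 2,
                    n_direct_pairs = 1, n_timepoints = 2, seed = 21L)
  ds <- simulate_paired_dataset(cfg)$dataset
  avg <- average_timepoints(ds)
  expect_equal(ncol(avg$gene_counts), 12)
  s1 <- ds$metadata$sample_id[ds$metadata$subject == "sub001"]
  expect_equal(unname(avg$gene_counts[, "sub001"]),
               unname(rowMeans(ds$gene_counts[, s1])))
  # conflicting group labels abort
  bad <- ds
  bad$metadata$group[1] <- "ctrl"
  expect_error(average_timepoints(bad), "conflicting")
})

test_that("column standardization is exact, idempotent and drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(s <- standardize_columns(m), "constant")
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% colnames(s))
  s2 <- standardize_columns(s)
  expect_equal(unname(s2), unname(s), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("singleton lineage chains collapse to one combined-taxa column", {
  # one OTU alone in its genus/family/...: identical rows at every rank
  tx <- data.frame(otu_id = c("o1", "o2", "o3"),
                   phylum = c("pA", "pA", "pA"),
                   genus = c("gX", "gY", "gY"),
                   species = c("sX", "sY", "sZ"),
                   stringsAsFactors = FALSE)
  counts <- matrix(rpois(3 * 12, 400) + 50L, 3, 12,
                   dimnames = list(tx$otu_id, sprintf("s%02d", 1:12)))
  ds <- structure(list(gene_counts = matrix(rpois(20 * 12, 200) + 1L, 20, 12,
                         dimnames = list(sprintf("g%02d", 1:20),
                                         colnames(counts))),
                       otu_counts = counts, taxonomy = tx,
                       metadata = data.frame(sample_id = colnames(counts),
                                             group = "case", sex = 0,
                                             stringsAsFactors = FALSE),
                       cohort = "toy"),
                  class = "paired_dataset")
  prep <- preprocess_dataset(ds, var_quantile = 0)
  # o1's genus and species rows are identical; the most specific label wins
  expect_true("species:sX" %in% colnames(prep$taxa))
  expect_false("genus:gX" %in% colnames(prep$taxa))
  # the phylum row (sum of all three) is distinct and survives
  expect_true("phylum:pA" %in% colnames(prep$taxa))
  expect_gt(prep$counts$taxa_collapsed_duplicates, 0)
})
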