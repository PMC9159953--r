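test_that("planted supports echo the configuration", {
  cfg <- sim_config(n_case = 15, n_ctrl = 15, n_genes = 60, n_otus = 20,
                    n_latent = 1, genes_per_factor = 20, taxa_per_factor = 8,
                    n_direct_pairs = 3, seed = 5L)
  out <- simulate_paired_dataset(cfg)
  expect_length(out$truth$latent_gene_support[[1]], 20)
  expect_length(out$truth$latent_taxon_support[[1]], 8)
  expect_true(all(out$truth$latent_gene_support[[1]] %in%
                    rownames(out$dataset$gene_counts)))
  expect_true(all(out$truth$direct_pairs$taxon %in%
                    rownames(out$dataset$otu_counts)))
})

test_that("zero effects give independence between planted genes and taxa", {
  cfg <- sim_config(n_case = 25, n_ctrl = 25, n_genes = 120, n_otus = 30,
                    n_latent = 1, genes_per_factor = 10, taxa_per_factor = 4,
                    latent_effect = 0, n_direct_pairs = 10, direct_effect = 0,
                    seed = 7L)
  out <- simulate_paired_dataset(cfg)
  g <- log1p(out$dataset$gene_counts)
  x <- log1p(out$dataset$otu_counts)
  # |r| over 100 random gene/taxon pairs vs a permutation null of the same
  # pairs (independent oracle: breaking the sample pairing by permutation)
  set.seed(1)
  gi <- sample(nrow(g), 100, replace = TRUE)
  ti <- sample(nrow(x), 100, replace = TRUE)
  obs <- abs(vapply(1:100, function(k) cor(g[gi[k], ], x[ti[k], ]),
                    numeric(1)))
  perm <- replicate(40, {
    idx <- sample(ncol(g))
    mean(abs(vapply(1:100, function(k) cor(g[gi[k], idx], x[ti[k], ]),
                    numeric(1))), na.rm = TRUE)
  })
  se <- sd(perm) * sqrt(1 + 1 / length(perm))
  expect_lt(abs(mean(obs, na.rm = TRUE) - mean(perm)), 3 * se)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_case = 10, n_ctrl = 10, n_genes = 40, n_otus = 15,
                    seed = 11L, genes_per_factor = 5, taxa_per_factor = 3,
                    n_direct_pairs = 2)
  a <- simulate_paired_dataset(cfg)
  b <- simulate_paired_dataset(cfg)
  expect_identical(a$dataset$gene_counts, b$dataset$gene_counts)
  expect_identical(a$dataset$otu_counts, b$dataset$otu_counts)
  expect_identical(a$truth$direct_pairs, b$truth$direct_pairs)
})

test_that("taxa counts close to the drawn sequencing depth", {
  out <- fx_cohort()
  depths <- colSums(out$dataset$otu_counts)
  # multinomial closure: every sample's counts sum to its drawn depth
  expect_true(all(depths > 0))
  expect_true(all(abs(depths - mean(depths)) < 10 * sqrt(mean(depths)) +
                    0.2 * mean(depths)))
})

test_that("toy taxonomy has full lineages and is seed-stable", {
  tx <- simulate_taxonomy(4, 6, seed = 3L)
  expect_equal(nrow(tx), 4)
  expect_true(all(lengths(strsplit(tx$lineage, ";")) %in% 5:6))
  expect_identical(tx, simulate_taxonomy(4, 6, seed = 3L))
  expect_error(simulate_taxonomy(4, 7), "1..6")

  # genus-level summarization equals the sum of member OTU rows
  tx2 <- simulate_taxonomy(12, 6, seed = 8L)
  counts <- matrix(rpois(12 * 6, 40), 12,
                   dimnames = list(tx2$otu_id, paste0("s", 1:6)))
  ranks <- summarize_ranks(counts, tx2)
  g1 <- tx2$genus[1]
  members <- tx2$otu_id[!is.na(tx2$genus) & tx2$genus == g1]
  expect_equal(unname(ranks$genus[paste0("genus:", g1), ]),
               unname(colSums(counts[members, , drop = FALSE])))
})

test_that("gene sets honour the planted-membership floor", {
  universe <- sprintf("g%04d", 1:300)
  support <- universe[1:20]
  gs <- simulate_gene_sets(10, c(25, 35), support, universe, n_planted = 2,
                           seed = 4L)
  expect_length(gs$sets, 10)
  expect_equal(sum(gs$planted), 2)
  for (i in which(gs$planted)) {
    size <- length(gs$sets[[i]])
    floor_in <- min(length(support), ceiling(0.8 * size))
    expect_gte(length(intersect(gs$sets[[i]], support)), floor_in)
  }
  expect_error(simulate_gene_sets(5, c(10, 400), support, universe),
               "universe")
})

test_that("decoy-set overlap with a support follows the hypergeometric mean", {
  universe <- sprintf("g%04d", 1:300)
  support <- universe[1:30]
  gs <- simulate_gene_sets(200, c(40, 40), support, universe, n_planted = 0,
                           seed = 9L)
  overlaps <- vapply(gs$sets, function(s) length(intersect(s, support)),
                     numeric(1))
  # hypergeometric mean K*n/N and SE of the mean over 200 decoys
  m <- 40 * 30 / 300
  v <- 40 * (30 / 300) * (270 / 300) * (300 - 40) / 299
  expect_lt(abs(mean(overlaps) - m), 3 * sqrt(v / 200))
})

test_that("datasets round-trip through the TSV/GMT/JSON formats", {
  out <- fixture("small_rt", function() {
    cfg <- sim_config(n_case = 8, n_ctrl = 8, n_genes = 30, n_otus = 12,
                      genes_per_factor = 5, taxa_per_factor = 3,
                      n_direct_pairs = 2, seed = 13L)
    simulate_paired_dataset(cfg)
  })
  dir <- withr::local_tempdir()
  gs <- simulate_gene_sets(4, c(5, 10), rownames(out$dataset$gene_counts)[1:8],
                           rownames(out$dataset$gene_counts), seed = 2L)
  write_paired_dataset(out$dataset, dir, truth = out$truth, gene_sets = gs)
  back <- read_paired_dataset(dir)
  expect_equal(back$gene_counts, out$dataset$gene_counts)
  expect_equal(back$otu_counts, out$dataset$otu_counts)
  expect_equal(back$taxonomy$lineage, out$dataset$taxonomy$lineage)
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(gmt, gs$sets, ignore_attr = TRUE)
})
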