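#!/usr/bin/env Rscript
# Simulate three paired host-transcriptome / gut-microbiome cohorts with
# planted ground truth, mimicking a three-disease study design: all cohorts
# share one reference taxonomy and one common case-only gene~taxon effect
# (so the cross-cohort step has a shared association to find), and each
# cohort additionally gets its own latent gene-taxon factor and five
# cohort-specific case-only pairs. Writes the pipeline's input formats plus
# the ground truth under results/cohorts/.

suppressMessages(library(homico))

master_seed <- 20260920L
out_root <- "results/cohorts"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

n_otus <- 40
taxonomy <- simulate_taxonomy(n_otus, 6, seed = derive_seed(master_seed, 5L))
shared_pair <- data.frame(gene = "g0010", taxon = "otu005", effect = 2)

cohorts <- c("crohn", "colitis", "ibs")
for (i in seq_along(cohorts)) {
  seed_i <- derive_seed(master_seed, 10L, i)
  cfg <- sim_config(
    n_case = 60, n_ctrl = 40, n_genes = 150, n_otus = n_otus,
    n_latent = 1, genes_per_factor = 12, taxa_per_factor = 4,
    latent_effect = 1.5, n_direct_pairs = 6, direct_effect = 2,
    direct_group = "case", seq_depth_mean = 10000, seed = seed_i)
  # five cohort-specific pairs, distinct from the shared one
  set.seed(derive_seed(master_seed, 12L, i))
  own <- data.frame(
    gene = sprintf("g%04d", sample(setdiff(31:150, 10), 5)),
    taxon = sprintf("otu%03d", sample(setdiff(10:n_otus, 5), 5)),
    effect = 2 * sample(c(-1, 1), 5, replace = TRUE))
  pairs <- rbind(shared_pair, own)
  sim <- simulate_paired_dataset(cfg, taxonomy = taxonomy,
                                 direct_pairs = pairs)
  sim$dataset$cohort <- cohorts[i]
  gs <- simulate_gene_sets(
    n_pathways = 25, size_range = c(12, 40),
    planted_from = sim$truth$latent_gene_support[[1]],
    universe = rownames(sim$dataset$gene_counts), n_planted = 2,
    seed = derive_seed(master_seed, 11L, i))
  dir <- file.path(out_root, cohorts[i])
  write_paired_dataset(sim$dataset, dir, truth = sim$truth, gene_sets = gs)
  message(sprintf(
    "%s: %d genes x %d samples, %d OTUs; %d planted pairs (1 shared)",
    cohorts[i], nrow(sim$dataset$gene_counts),
    ncol(sim$dataset$gene_counts), nrow(sim$dataset$otu_counts),
    nrow(sim$truth$direct_pairs)))
}
message("inputs written under ", out_root)
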