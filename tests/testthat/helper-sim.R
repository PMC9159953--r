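# shared fixtures: small simulated cohorts, memoized so expensive objects are
# built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a mid-sized cohort with one latent factor and a few direct pairs
fx_cohort <- function() fixture("cohort", function() {
  cfg <- sim_config(n_case = 30, n_ctrl = 30, n_genes = 100, n_otus = 30,
                    n_latent = 1, genes_per_factor = 10, taxa_per_factor = 4,
                    latent_effect = 1.5, n_direct_pairs = 5,
                    direct_effect = 1.5, seq_depth_mean = 8000, seed = 42L)
  simulate_paired_dataset(cfg)
})

fx_prep <- function() fixture("prep", function()
  preprocess_dataset(fx_cohort()$dataset))

# OTU-level preprocessing (no rank combination), used by association tests
fx_prep_otu <- function() fixture("prep_otu", function()
  preprocess_dataset(fx_cohort()$dataset, combine_ranks = FALSE))

# standardized case-group matrices for sparse CCA tests
fx_xy <- function() fixture("xy", function() {
  prep <- fx_prep_otu()
  smp <- prep$metadata$sample_id[prep$metadata$group == "case"]
  list(X = standardize_columns(prep$taxa[smp, , drop = FALSE]),
       Y = standardize_columns(prep$expr[smp, , drop = FALSE]))
})

# simulate, preprocess at OTU level and run gene-wise associations for one
# group; used by recovery-style tests
run_assoc_sim <- function(seed, n_case = 80, n_genes = 200, n_otus = 50,
                          n_direct_pairs = 10, direct_effect = 1.5,
                          direct_group = "all", ...) {
  cfg <- sim_config(n_case = n_case, n_ctrl = 5, n_genes = n_genes,
                    n_otus = n_otus, n_latent = 0, genes_per_factor = 0,
                    taxa_per_factor = 0, n_direct_pairs = n_direct_pairs,
                    direct_effect = direct_effect,
                    direct_group = direct_group, seed = seed, ...)
  sim <- simulate_paired_dataset(cfg)
  prep <- preprocess_dataset(sim$dataset, combine_ranks = FALSE)
  assoc <- suppressWarnings(
    genewise_associations(prep, "case", seed = seed))
  truth_keys <- paste(sim$truth$direct_pairs$gene,
                      paste0("otu:", sim$truth$direct_pairs$taxon))
  found_keys <- paste(assoc$associations$gene, assoc$associations$predictor)
  list(sim = sim, prep = prep, assoc = assoc,
       truth_keys = truth_keys, found_keys = found_keys)
}
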