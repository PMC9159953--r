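#' Cohort analysis configuration
#'
#' All thresholds default to the study values: genes expressed in at least
#' half the samples, 25% variance quantile, taxa at 0.001 relative abundance
#' in at least 10% of samples, 10 sparse CCA components at FDR < 0.1,
#' gene-wise lasso with 100 stability rounds and f_thr 0.6 at FDR < 0.1,
#' 9999 permutations for the concordance tests.
#'
#' @param cohort cohort name.
#' @param seed master seed for every stage.
#' @param coding_ids,blocklist optional gene whitelist / lineage blocklist.
#' @param var_quantile,min_abund,min_prev,pseudocount preprocessing knobs.
#' @param combine_ranks combine taxonomic ranks before CLR (default TRUE).
#' @param n_perm concordance permutations.
#' @param scca_K,scca_fdr,scca_mode,grid_taxa,grid_genes sparse CCA knobs;
#'   fixed `lambda_taxa`/`lambda_genes` skip tuning.
#' @param lasso_fdr,f_thr,K_stab,nlambda,covariates lasso knobs.
#' @param fdr_diff differential-enrichment threshold.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(cohort = "cohort", seed = 1L, coding_ids = NULL,
                          blocklist = character(), var_quantile = 0.25,
                          min_abund = 0.001, min_prev = 0.10,
                          pseudocount = 1, combine_ranks = TRUE,
                          n_perm = 9999, scca_K = 10, scca_fdr = 0.1,
                          scca_mode = "full", grid_taxa = seq(0.1, 0.5, 0.1),
                          grid_genes = seq(0.1, 0.5, 0.1),
                          lambda_taxa = NULL, lambda_genes = NULL,
                          lasso_fdr = 0.1, f_thr = 0.6, K_stab = 100,
                          nlambda = 100, covariates = c("sex", "subtype"),
                          fdr_diff = 0.2) {
  structure(as.list(environment()), class = "cohort_config")
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

# genes carried by the significant components of a sparse CCA run
scca_interest_genes <- function(scca_res) {
  sig <- scca_res$summary$component[scca_res$summary$significant]
  unique(unlist(lapply(scca_res$components[sig], function(cm)
    names(cm$v)[cm$v != 0])))
}

# per-component enrichment over significant components, BH pooled across the
# combined rows within the cohort run
scca_enrichment <- function(scca_res, background, collection) {
  sig <- scca_res$summary$component[scca_res$summary$significant]
  rows <- lapply(sig, function(k) {
    genes <- names(scca_res$components[[k]]$v)[scca_res$components[[k]]$v != 0]
    genes <- intersect(genes, background)
    if (length(genes) == 0) return(NULL)
    er <- fisher_enrichment(genes, background, collection, profile = "scca")
    if (nrow(er)) er$component <- k
    er
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(pathway = character(), n1 = integer(), n2 = integer(),
                      n3 = integer(), n4 = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), component = integer(),
                      stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Run the full integration analysis for one cohort
#'
#' Preprocess, test overall concordance, then — separately for cases and
#' controls — fit sparse CCA with held-out significance and pathway
#' enrichment, and the gene-wise lasso with debiased inference and stability
#' selection; finally call case-specific associations and pathways. All
#' tables plus a manifest (parameters, seeds, per-stage feature counts) are
#' written to `out_dir`.
#'
#' @param dataset a `paired_dataset` (or a directory readable by
#'   [read_paired_dataset()]).
#' @param config a [cohort_config()].
#' @param out_dir run directory (created).
#' @param gene_sets optional named list of pathway gene sets for enrichment.
#' @return list with `prep`, `concordance`, `scca`, `lasso`,
#'   `case_specific`, `enrichment`, `manifest` (also serialized under
#'   `out_dir`).
#' @export
run_cohort <- function(dataset, config = cohort_config(), out_dir,
                       gene_sets = NULL) {
  if (is.character(dataset)) dataset <- read_paired_dataset(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  res <- list()

  prep <- preprocess_dataset(dataset, coding_ids = cfg$coding_ids,
                             blocklist = cfg$blocklist,
                             var_quantile = cfg$var_quantile,
                             min_abund = cfg$min_abund,
                             min_prev = cfg$min_prev,
                             pseudocount = cfg$pseudocount,
                             combine_ranks = cfg$combine_ranks)
  res$prep <- prep

  groups <- intersect(c("case", "ctrl"), unique(prep$metadata$group))
  conc <- scca <- lasso <- enr <- list()
  for (grp in groups) {
    smp <- prep$metadata$sample_id[prep$metadata$group == grp]
    expr_g <- prep$expr[smp, , drop = FALSE]
    taxa_g <- prep$taxa[smp, , drop = FALSE]
    raw_taxa <- t(dataset$otu_counts)[
      intersect(smp, colnames(dataset$otu_counts)), , drop = FALSE]
    conc[[grp]] <- concordance_test(standardize_columns(expr_g), raw_taxa,
                                    n_perm = cfg$n_perm,
                                    seed = derive_seed(cfg$seed, 21L,
                                                       match(grp, groups)))
    Xs <- standardize_columns(taxa_g)
    Ys <- standardize_columns(expr_g)
    scca[[grp]] <- scca_run(Xs, Ys, lambda_taxa = cfg$lambda_taxa,
                            lambda_genes = cfg$lambda_genes,
                            grid_taxa = cfg$grid_taxa,
                            grid_genes = cfg$grid_genes, K = cfg$scca_K,
                            fdr = cfg$scca_fdr, mode = cfg$scca_mode)
    lasso[[grp]] <- genewise_associations(prep, group = grp,
                                          fdr = cfg$lasso_fdr,
                                          f_thr = cfg$f_thr,
                                          K_stab = cfg$K_stab,
                                          covariates = cfg$covariates,
                                          nlambda = cfg$nlambda,
                                          seed = derive_seed(cfg$seed, 31L,
                                                             match(grp,
                                                                   groups)))
    write_tsv(scca[[grp]]$summary,
              file.path(out_dir, paste0("scca_summary_", grp, ".tsv")))
    write_tsv(lasso[[grp]]$records,
              file.path(out_dir, paste0("lasso_records_", grp, ".tsv")))
  }
  res$concordance <- conc; res$scca <- scca; res$lasso <- lasso

  # case-specific associations (pre-threshold overlap rule)
  if (all(c("case", "ctrl") %in% groups)) {
    cs <- case_specific_associations(lasso$case, lasso$ctrl)
  } else {
    cs <- list(associations = lasso[[groups[1]]]$associations,
               overlap = NULL, n_overlap = 0L)
  }
  res$case_specific <- cs
  write_tsv(cs$associations, file.path(out_dir,
                                       "case_specific_associations.tsv"))

  if (!is.null(gene_sets)) {
    background <- colnames(prep$expr)
    enr$scca <- lapply(scca, scca_enrichment, background = background,
                       collection = gene_sets)
    assoc_genes <- function(l, exclude = character())
      setdiff(unique(l$associations$gene), exclude)
    # case-specific genes only, per the case/ctrl comparison rule
    ctrl_genes <- if ("ctrl" %in% groups) assoc_genes(lasso$ctrl)
                  else character()
    enr$lasso <- list()
    for (grp in groups) {
      genes <- if (grp == "case") assoc_genes(lasso$case, ctrl_genes)
               else assoc_genes(lasso[[grp]])
      enr$lasso[[grp]] <-
        if (length(genes) >= 5)
          fisher_enrichment(genes, background, gene_sets, profile = "lasso")
        else fisher_enrichment(character(0), background, gene_sets,
                               profile = "lasso")[0, ]
    }
    if (all(c("case", "ctrl") %in% groups)) {
      enr$diff_scca <- differential_enrichment(enr$scca$case, enr$scca$ctrl)
      enr$case_pathways <- case_specific_pathways(enr$scca$case,
                                                  enr$scca$ctrl,
                                                  enr$diff_scca,
                                                  fdr_enrich = cfg$scca_fdr,
                                                  fdr_diff = cfg$fdr_diff)
      write_tsv(enr$case_pathways, file.path(out_dir,
                                             "case_specific_pathways.tsv"))
    }
    for (grp in names(enr$scca))
      write_tsv(enr$scca[[grp]],
                file.path(out_dir, paste0("scca_enrichment_", grp, ".tsv")))
  }
  res$enrichment <- enr

  manifest <- list(
    package_version = as.character(utils::packageVersion("homico")),
    cohort = cfg$cohort, seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("coding_ids", "blocklist"))],
    feature_counts = prep$counts,
    n_samples = nrow(prep$expr),
    n_associations = vapply(lasso, function(l) nrow(l$associations),
                            integer(1)),
    n_case_specific = nrow(cs$associations))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Combine completed cohort runs into the cross-cohort report
#'
#' Computes pairwise overlap coefficients for input and associated
#' genes/taxa, mines shared-taxon and shared-gene Venn-region networks from
#' the case-specific association tables, and exports each network as GraphML
#' plus an edge-list TSV.
#'
#' @param runs named list (cohort -> result of [run_cohort()]), or a named
#'   character vector of run directories.
#' @param out_dir output directory for the report files.
#' @return list with `overlaps`, `taxa_networks`, `gene_networks`.
#' @export
compare_cohorts <- function(runs, out_dir) {
  stopifnot(length(runs) >= 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(runs)) {
    dirs <- runs
    runs <- lapply(dirs, function(d) {
      list(case_specific = list(associations = utils::read.delim(
        file.path(d, "case_specific_associations.tsv"),
        stringsAsFactors = FALSE)))
    })
    names(runs) <- names(dirs) %||% basename(dirs)
  }
  assoc <- lapply(runs, function(r) r$case_specific$associations)

  overlaps <- list()
  grab <- function(field) lapply(runs, function(r)
    if (!is.null(r$prep)) colnames(r$prep[[field]]) else character())
  if (all(vapply(runs, function(r) !is.null(r$prep), logical(1)))) {
    overlaps$input_genes <- overlap_report(grab("expr"))
    overlaps$input_taxa <- overlap_report(grab("taxa"))
  }
  overlaps$assoc_genes <- overlap_report(lapply(assoc, function(a)
    unique(a$gene)))
  overlaps$assoc_taxa <- overlap_report(lapply(assoc, function(a)
    unique(a$predictor)))

  taxa_nets <- shared_taxa_networks(assoc)
  gene_nets <- shared_genes_networks(assoc)
  for (rn in names(taxa_nets)) {
    e <- taxa_nets[[rn]]$edges
    if (nrow(e))
      export_network(e, file.path(out_dir, paste0("taxa_net_", rn,
                                                  ".graphml")),
                     file.path(out_dir, paste0("taxa_net_", rn, ".tsv")))
  }
  for (rn in names(gene_nets)) {
    e <- gene_nets[[rn]]$edges
    if (nrow(e))
      export_network(e, file.path(out_dir, paste0("gene_net_", rn,
                                                  ".graphml")),
                     file.path(out_dir, paste0("gene_net_", rn, ".tsv")))
  }
  summ <- list(
    regions_taxa = lapply(taxa_nets, function(x)
      list(taxa = x$taxa, n_edges = nrow(x$edges))),
    regions_genes = lapply(gene_nets, function(x)
      list(genes = x$genes, n_edges = nrow(x$edges))),
    overlaps = overlaps)
  jsonlite::write_json(summ, file.path(out_dir, "cross_cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(overlaps = overlaps, taxa_networks = taxa_nets,
       gene_networks = gene_nets)
}
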