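#' Filter lowly expressed genes
#'
#' Keeps genes expressed (count > 0) in at least half of the samples,
#' optionally after restricting to a protein-coding ID list.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param coding_ids optional character vector; genes outside it are dropped
#'   first.
#' @return filtered count matrix, input row order preserved.
#' @export
filter_genes <- function(counts, coding_ids = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  n_noncoding <- 0L
  if (!is.null(coding_ids)) {
    keep_c <- rownames(counts) %in% coding_ids
    n_noncoding <- sum(!keep_c)
    counts <- counts[keep_c, , drop = FALSE]
  }
  need <- ceiling(ncol(counts) / 2)
  keep <- rowSums(counts > 0) >= need
  if (!any(keep))
    abort_stage("filter_genes",
                sprintf("no genes pass (%d non-coding, %d lowly expressed)",
                        n_noncoding, sum(!keep)))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' DESeq-style per-sample size factors: the median across genes of the ratio
#' of a sample's counts to the gene-wise geometric mean, computed over genes
#' with all-positive counts.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) abort_stage("size_factors", "no gene has all-positive counts")
  apply(counts, 2, function(cnt) exp(stats::median(log(cnt[use]) - loggeo[use])))
}

#' Variance-stabilizing log transform
#'
#' Divides each sample by its median-of-ratios size factor and applies
#' `log2(x + 1)`. A monotone transform that removes depth differences and
#' tames the count-variance relationship; not the reference regularized VST of
#' differential-expression packages, and documented as an approximation.
#'
#' @param counts filtered genes x samples count matrix.
#' @return transformed matrix of the same shape.
#' @export
variance_stabilize <- function(counts) {
  if (any(rowSums(counts) == 0))
    abort_stage("variance_stabilize", "all-zero gene rows present; filter first")
  sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Drop low-variance genes
#'
#' Removes genes whose across-sample variance falls below the given variance
#' quantile (linear-interpolation convention); genes at the boundary are kept.
#'
#' @param expr transformed genes x samples matrix.
#' @param quantile variance quantile cutoff (default 0.25).
#' @return filtered matrix.
#' @export
variance_filter <- function(expr, quantile = 0.25) {
  if (ncol(expr) < 2) abort_stage("variance_filter", "need at least 2 samples")
  v <- apply(expr, 1, stats::var)
  cut <- stats::quantile(v, quantile, names = FALSE)
  expr[v >= cut, , drop = FALSE]
}

#' Summarize an OTU table at each taxonomic rank
#'
#' After removing blocklisted lineages (known reagent/environmental
#' contaminants), sums member OTU rows at every available rank. OTUs without
#' a label at a rank are excluded from that rank's table only.
#'
#' @param otus OTUs x samples count matrix.
#' @param taxonomy data.frame with `otu_id` and one column per rank (as from
#'   [simulate_taxonomy()] or [read_paired_dataset()]).
#' @param blocklist character vector; an OTU is removed everywhere when any of
#'   its rank labels matches an entry.
#' @return named list of rank-level count matrices with qualified row names
#'   (`"rank:label"`).
#' @export
summarize_ranks <- function(otus, taxonomy, blocklist = character()) {
  orphans <- setdiff(rownames(otus), taxonomy$otu_id)
  if (length(orphans))
    abort_stage("summarize_ranks", "OTUs without lineage: ",
                paste(orphans, collapse = ", "))
  taxonomy <- taxonomy[match(rownames(otus), taxonomy$otu_id), , drop = FALSE]
  ranks <- intersect(TAXO_RANKS, colnames(taxonomy))
  if (length(blocklist)) {
    bad <- apply(taxonomy[, ranks, drop = FALSE], 1,
                 function(x) any(x %in% blocklist))
    otus <- otus[!bad, , drop = FALSE]
    taxonomy <- taxonomy[!bad, , drop = FALSE]
  }
  out <- list()
  for (r in ranks) {
    lbl <- taxonomy[[r]]
    ok <- !is.na(lbl) & lbl != ""
    if (!any(ok)) next
    agg <- rowsum(otus[ok, , drop = FALSE], group = lbl[ok], reorder = FALSE)
    rownames(agg) <- paste0(r, ":", rownames(agg))
    out[[r]] <- agg
  }
  out
}

#' Prevalence/abundance filter for a rank-level taxa table
#'
#' Keeps taxa observed at relative abundance at least `min_abund` in at least
#' `ceiling(min_prev * n)` samples (both boundaries inclusive).
#'
#' @param rank_table taxa x samples count matrix.
#' @param min_abund relative-abundance threshold (default 0.001).
#' @param min_prev sample-fraction threshold (default 0.10).
#' @return filtered matrix, input row order preserved.
#' @export
prevalence_filter <- function(rank_table, min_abund = 0.001, min_prev = 0.10) {
  tot <- colSums(rank_table)
  if (any(tot == 0))
    abort_stage("prevalence_filter", "zero-depth sample(s): ",
                paste(colnames(rank_table)[tot == 0], collapse = ", "))
  rel <- sweep(rank_table, 2, tot, "/")
  need <- ceiling(min_prev * ncol(rank_table))
  keep <- rowSums(rel >= min_abund) >= need
  rank_table[keep, , drop = FALSE]
}

clr_rows <- function(m) {
  lg <- log(m)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Combine rank tables and CLR-transform the combined matrix
#'
#' Concatenates the filtered per-rank count tables into one combined taxa
#' matrix, adds a pseudocount, and applies the centered log-ratio transform
#' per sample over the combined vector, so CLR values are comparable across
#' ranks. Rows of the result (samples) sum to zero.
#'
#' @param rank_tables list of taxa x samples count matrices with identical
#'   sample columns.
#' @param pseudocount added to every count before the log (default 1).
#' @return samples x taxa CLR matrix with qualified taxon column names.
#' @export
combine_and_clr <- function(rank_tables, pseudocount = 1) {
  combined <- do.call(rbind, rank_tables)
  if (anyDuplicated(rownames(combined)))
    abort_stage("combine_and_clr", "duplicate qualified taxon IDs")
  samples <- colnames(rank_tables[[1]])
  for (t in rank_tables)
    if (!identical(colnames(t), samples))
      abort_stage("combine_and_clr", "rank tables have mismatched samples")
  clr_rows(t(combined) + pseudocount)
}

#' Compare combined-then-CLR against CLR-then-combined transforms
#'
#' Strategy 1 CLR-transforms the concatenated count matrix; strategy 2
#' CLR-transforms each rank separately and concatenates the results. Reports
#' the per-sample Pearson and Spearman correlation between the two profiles;
#' samples whose profile is constant under either strategy are flagged and
#' excluded from the means.
#'
#' @inheritParams combine_and_clr
#' @return list with `per_sample` (data.frame of correlations), `mean_pearson`,
#'   `mean_spearman`, `degenerate` (excluded sample IDs).
#' @export
compare_clr_strategies <- function(rank_tables, pseudocount = 1) {
  s1 <- combine_and_clr(rank_tables, pseudocount)
  s2 <- do.call(cbind, lapply(rank_tables, function(tab)
    clr_rows(t(tab) + pseudocount)))
  s2 <- s2[rownames(s1), colnames(s1), drop = FALSE]
  degen <- apply(s1, 1, stats::sd) < 1e-12 | apply(s2, 1, stats::sd) < 1e-12
  pear <- spear <- rep(NA_real_, nrow(s1))
  ok <- !degen
  pear[ok] <- vapply(which(ok), function(i) stats::cor(s1[i, ], s2[i, ]),
                     numeric(1))
  spear[ok] <- vapply(which(ok), function(i)
    stats::cor(s1[i, ], s2[i, ], method = "spearman"), numeric(1))
  list(per_sample = data.frame(sample_id = rownames(s1), pearson = pear,
                               spearman = spear, stringsAsFactors = FALSE),
       mean_pearson = mean(pear, na.rm = TRUE),
       mean_spearman = mean(spear, na.rm = TRUE),
       degenerate = rownames(s1)[degen])
}

#' Average repeated timepoints within subjects
#'
#' Collapses a multi-timepoint cohort to one profile per subject by taking
#' the arithmetic mean of gene and taxon counts across the subject's
#' timepoints, on the count scale, before any transform.
#'
#' @param dataset a `paired_dataset` whose metadata has `subject` and
#'   `timepoint` columns.
#' @return a `paired_dataset` with one sample per subject.
#' @export
average_timepoints <- function(dataset) {
  meta <- dataset$metadata
  stopifnot(all(c("subject", "timepoint") %in% colnames(meta)))
  for (s in unique(meta$subject)) {
    g <- unique(meta$group[meta$subject == s])
    if (length(g) > 1)
      abort_stage("average_timepoints",
                  "conflicting group labels within subject ", s)
  }
  subj <- unique(meta$subject)
  first <- meta[match(subj, meta$subject), , drop = FALSE]
  avg <- function(m) {
    out <- vapply(subj, function(s)
      rowMeans(m[, meta$sample_id[meta$subject == s], drop = FALSE]),
      numeric(nrow(m)))
    colnames(out) <- subj
    out
  }
  meta2 <- data.frame(sample_id = subj,
                      first[, setdiff(colnames(first),
                                      c("sample_id", "timepoint")),
                            drop = FALSE],
                      stringsAsFactors = FALSE)
  rownames(meta2) <- NULL
  structure(list(gene_counts = avg(dataset$gene_counts),
                 otu_counts = avg(dataset$otu_counts),
                 taxonomy = dataset$taxonomy, metadata = meta2,
                 cohort = dataset$cohort),
            class = "paired_dataset")
}

#' Standardize matrix columns to mean 0, SD 1
#'
#' Sample-SD (n-1) convention; constant columns are dropped with a warning.
#'
#' @param m samples x features numeric matrix.
#' @return standardized matrix (possibly fewer columns).
#' @export
standardize_columns <- function(m) {
  stopifnot(nrow(m) >= 2)
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warning("dropping ", sum(sds < 1e-12), " constant column(s)")
    m <- m[, sds >= 1e-12, drop = FALSE]
    sds <- sds[sds >= 1e-12]
  }
  scale(m, center = TRUE, scale = sds)
}

#' Run the full preprocessing chain on a paired dataset
#'
#' Timepoint averaging (when present), gene filters and log transform,
#' rank summarization, prevalence filtering and combined-rank CLR, returning
#' aligned analysis-ready matrices.
#'
#' @param dataset a `paired_dataset`.
#' @param coding_ids optional coding-gene ID list.
#' @param blocklist contaminant lineage labels.
#' @param var_quantile variance-filter quantile.
#' @param min_abund,min_prev prevalence-filter thresholds.
#' @param pseudocount CLR pseudocount.
#' @param combine_ranks if FALSE, skip rank summarization and CLR the OTU
#'   table directly (taxon IDs qualified `"otu:"`).
#' @return list with `expr` (samples x genes, transformed), `taxa` (samples x
#'   taxa, CLR), `metadata`, `cohort`, and per-stage feature `counts`.
#' @export
preprocess_dataset <- function(dataset, coding_ids = NULL,
                               blocklist = character(), var_quantile = 0.25,
                               min_abund = 0.001, min_prev = 0.10,
                               pseudocount = 1, combine_ranks = TRUE) {
  if ("timepoint" %in% colnames(dataset$metadata) &&
      any(duplicated(dataset$metadata$subject)))
    dataset <- average_timepoints(dataset)
  counts <- list(genes_in = nrow(dataset$gene_counts),
                 otus_in = nrow(dataset$otu_counts))
  g <- filter_genes(dataset$gene_counts, coding_ids)
  counts$genes_expressed <- nrow(g)
  g <- variance_stabilize(g)
  g <- variance_filter(g, var_quantile)
  counts$genes_variable <- nrow(g)
  if (combine_ranks) {
    ranks <- summarize_ranks(dataset$otu_counts, dataset$taxonomy, blocklist)
    ranks <- lapply(ranks, prevalence_filter, min_abund = min_abund,
                    min_prev = min_prev)
    ranks <- ranks[vapply(ranks, nrow, integer(1)) > 0]
    combined <- do.call(rbind, ranks)
    # a lineage that is a singleton chain yields identical rows at several
    # ranks; collapse exact duplicates, keeping the most specific label
    # (rank tables are ordered phylum -> species)
    dup <- duplicated(combined, fromLast = TRUE)
    counts$taxa_collapsed_duplicates <- sum(dup)
    taxa <- combine_and_clr(list(combined[!dup, , drop = FALSE]),
                            pseudocount)
  } else {
    ot <- prevalence_filter(dataset$otu_counts, min_abund, min_prev)
    rownames(ot) <- paste0("otu:", rownames(ot))
    taxa <- combine_and_clr(list(otu = ot), pseudocount)
  }
  counts$taxa_combined <- ncol(taxa)
  meta <- dataset$metadata
  samples <- intersect(meta$sample_id, intersect(colnames(g), rownames(taxa)))
  if (length(samples) == 0)
    abort_stage("preprocess", "no samples shared across the three tables")
  list(expr = t(g)[samples, , drop = FALSE],
       taxa = taxa[samples, , drop = FALSE],
       metadata = meta[match(samples, meta$sample_id), , drop = FALSE],
       cohort = dataset$cohort, counts = counts)
}
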