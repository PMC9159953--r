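#' Simulation configuration for paired host/microbiome cohorts
#'
#' Bundles and validates every knob of the paired-data generator. Defaults
#' describe a small but realistic mucosal cohort: tens of samples per group,
#' a few hundred host genes, tens of OTUs, a handful of shared latent factors
#' linking gene and taxon subsets, and a few planted direct gene~taxon
#' regressions on top.
#'
#' @param n_case,n_ctrl number of case and control samples (subjects).
#' @param n_genes,n_otus number of host genes and microbial OTUs.
#' @param n_latent number of planted shared latent factors.
#' @param genes_per_factor,taxa_per_factor support sizes of each factor.
#' @param latent_effect loading magnitude of the latent factors (log scale).
#' @param n_direct_pairs number of planted direct gene~taxon regressions.
#' @param direct_effect regression coefficient magnitude of planted pairs
#'   (log-counts per CLR unit).
#' @param noise_sd residual standard deviation on the gene log-mean.
#' @param seq_depth_mean expected 16S reads per sample.
#' @param dispersion negative-binomial dispersion of gene counts
#'   (`size = 1/dispersion`).
#' @param taxonomy_depth number of taxonomic ranks (1..6, phylum downwards).
#' @param n_timepoints draws per subject (2 exercises timepoint averaging).
#' @param latent_group,direct_group which group carries the planted effects:
#'   `"all"`, `"case"` (case-only) or `"ctrl"` (control-only).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_case = 30, n_ctrl = 30, n_genes = 200, n_otus = 50,
                       n_latent = 1, genes_per_factor = 20, taxa_per_factor = 5,
                       latent_effect = 1.5, n_direct_pairs = 10,
                       direct_effect = 1.5, noise_sd = 0.5,
                       seq_depth_mean = 20000, dispersion = 0.1,
                       taxonomy_depth = 6, n_timepoints = 1,
                       latent_group = "all", direct_group = "all",
                       seed = 1L) {
  cfg <- list(
    n_case = n_case, n_ctrl = n_ctrl, n_genes = n_genes, n_otus = n_otus,
    n_latent = n_latent, genes_per_factor = genes_per_factor,
    taxa_per_factor = taxa_per_factor, latent_effect = latent_effect,
    n_direct_pairs = n_direct_pairs, direct_effect = direct_effect,
    noise_sd = noise_sd, seq_depth_mean = seq_depth_mean,
    dispersion = dispersion, taxonomy_depth = taxonomy_depth,
    n_timepoints = n_timepoints, latent_group = latent_group,
    direct_group = direct_group, seed = as.integer(seed))
  counts <- c("n_case", "n_ctrl", "n_genes", "n_otus", "seq_depth_mean",
              "n_timepoints")
  for (f in counts)
    if (cfg[[f]] < 1) stop("sim_config: ", f, " must be positive")
  if (cfg$n_latent < 0 || cfg$n_direct_pairs < 0)
    stop("sim_config: factor and pair counts must be non-negative")
  if (cfg$noise_sd <= 0) stop("sim_config: noise_sd must be > 0")
  if (cfg$dispersion <= 0) stop("sim_config: dispersion must be > 0")
  if (cfg$n_latent * cfg$genes_per_factor > cfg$n_genes)
    stop("sim_config: latent gene supports exceed n_genes")
  if (cfg$n_latent * cfg$taxa_per_factor > cfg$n_otus)
    stop("sim_config: latent taxon supports exceed n_otus")
  if (!cfg$taxonomy_depth %in% 1:6)
    stop("sim_config: taxonomy_depth must be in 1..6")
  if (!cfg$latent_group %in% c("all", "case", "ctrl") ||
      !cfg$direct_group %in% c("all", "case", "ctrl"))
    stop("sim_config: effect group must be 'all', 'case' or 'ctrl'")
  structure(cfg, class = "sim_config")
}

TAXO_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Simulate a toy bacterial taxonomy
#'
#' Builds random nested lineages over the ranks phylum..species by recursive
#' random partitioning, so sibling OTUs share ancestors the way a real 16S
#' table does. About a quarter of OTUs get no species-level label, matching
#' the incomplete classification of real reference databases.
#'
#' @param n_otus number of OTUs.
#' @param taxonomy_depth number of ranks from phylum downwards (1..6).
#' @param seed integer seed.
#' @return data.frame with `otu_id`, one column per rank (NA where
#'   unclassified) and a semicolon-delimited `lineage` string.
#' @export
simulate_taxonomy <- function(n_otus, taxonomy_depth = 6, seed = 1L) {
  stopifnot(n_otus >= 1)
  if (!taxonomy_depth %in% 1:6) stop("taxonomy_depth must be in 1..6")
  ranks <- TAXO_RANKS[seq_len(taxonomy_depth)]
  with_seed(seed, {
    lab <- matrix(NA_character_, n_otus, taxonomy_depth,
                  dimnames = list(NULL, ranks))
    counter <- integer(taxonomy_depth)
    split_group <- function(idx, r) {
      if (r > taxonomy_depth) return(invisible())
      k <- sample.int(min(3L, length(idx)), 1L)
      grp <- sample(rep_len(seq_len(k), length(idx)))
      for (g in seq_len(k)) {
        counter[r] <<- counter[r] + 1L
        members <- idx[grp == g]
        lab[members, r] <<- paste0(substr(ranks[r], 1, 1), counter[r])
        split_group(members, r + 1L)
      }
    }
    split_group(seq_len(n_otus), 1L)
    # species-level labels are incomplete, as in real classifications
    if (taxonomy_depth == 6L) {
      drop <- runif(n_otus) < 0.25
      lab[drop, "species"] <- NA_character_
    }
    lineage <- apply(lab, 1, function(x) paste(ifelse(is.na(x), "", x),
                                               collapse = ";"))
    out <- data.frame(otu_id = sprintf("otu%03d", seq_len(n_otus)),
                      lab, lineage = lineage, stringsAsFactors = FALSE)
    rownames(out) <- out$otu_id
    out
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Decoy pathways are uniform draws from the gene universe; planted pathways
#' draw at least 80% of their members (capped by the support size) from a
#' designated gene support, so enrichment of an interest set built on that
#' support is guaranteed in expectation.
#'
#' @param n_pathways total number of gene sets.
#' @param size_range length-2 integer range of set sizes.
#' @param planted_from character vector of support gene IDs for the planted
#'   sets.
#' @param universe character vector of all gene IDs.
#' @param n_planted how many of the sets are planted (default 2).
#' @param seed integer seed.
#' @return list with `sets` (named list of gene ID vectors) and `planted`
#'   (logical vector).
#' @export
simulate_gene_sets <- function(n_pathways, size_range, planted_from, universe,
                               n_planted = 2L, seed = 1L) {
  stopifnot(length(size_range) == 2, n_planted <= n_pathways)
  if (max(size_range) > length(universe))
    stop("size_range exceeds the gene universe")
  if (!all(planted_from %in% universe))
    stop("planted_from must be a subset of the universe")
  with_seed(seed, {
    sets <- vector("list", n_pathways)
    names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
    planted <- seq_len(n_pathways) <= n_planted
    for (i in seq_len(n_pathways)) {
      size <- if (size_range[1] == size_range[2]) size_range[1]
              else sample(seq(size_range[1], size_range[2]), 1L)
      if (planted[i]) {
        n_in <- min(length(planted_from), ceiling(0.8 * size))
        inside <- sample(planted_from, n_in)
        pool <- setdiff(universe, inside)
        sets[[i]] <- sort(c(inside, sample(pool, size - n_in)))
      } else {
        sets[[i]] <- sort(sample(universe, size))
      }
    }
    list(sets = sets, planted = planted)
  })
}

#' Simulate a paired host-expression / gut-microbiome cohort
#'
#' Taxa: per-sample log abundances combine a baseline, loadings of shared
#' latent factors on the planted taxon supports, and log-normal noise; they
#' are closed to the simplex and sampled multinomially at a Poisson
#' sequencing depth, giving compositional 16S-like counts. Genes: log-means
#' combine a baseline, loadings of the same latent factors on the planted
#' gene supports, planted direct effects of individual taxa (on the CLR scale
#' of the true compositions), covariate effects (sex, disease subtype) and
#' Gaussian noise; counts are negative binomial with per-sample size factors,
#' emulating RNA-seq overdispersion. Case-only (or control-only) regimes
#' multiply the planted effects by the group indicator.
#'
#' @param config a [sim_config()].
#' @param taxonomy optional taxonomy table (as from [simulate_taxonomy()])
#'   shared across cohorts; generated from the seed when NULL.
#' @param direct_pairs optional data.frame with columns `gene`, `taxon`
#'   (integer indices or IDs) and `effect`, planting specific gene~taxon
#'   regressions (e.g. the same pair in several cohorts); drawn at random
#'   when NULL.
#' @return list with `dataset` (a `paired_dataset`: `gene_counts` genes x
#'   samples, `otu_counts` OTUs x samples, `taxonomy`, `metadata`, `cohort`)
#'   and `truth` (a `synthetic_truth`: planted supports, direct pairs,
#'   group-specific flags).
#' @export
simulate_paired_dataset <- function(config, taxonomy = NULL,
                                    direct_pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (is.null(taxonomy))
    taxonomy <- simulate_taxonomy(cfg$n_otus, cfg$taxonomy_depth,
                                  seed = derive_seed(cfg$seed, 101L))
  stopifnot(nrow(taxonomy) == cfg$n_otus)
  with_seed(derive_seed(cfg$seed, 202L), {
    n_subj <- cfg$n_case + cfg$n_ctrl
    n <- n_subj * cfg$n_timepoints
    subj <- rep(seq_len(n_subj), each = cfg$n_timepoints)
    tp <- rep(seq_len(cfg$n_timepoints), times = n_subj)
    group <- rep(c(rep("case", cfg$n_case), rep("ctrl", cfg$n_ctrl)),
                 each = cfg$n_timepoints)
    sample_id <- sprintf("S%03d_t%d", subj, tp)
    gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
    otu_id <- taxonomy$otu_id

    sex <- rep(rbinom(n_subj, 1, 0.5), each = cfg$n_timepoints)
    subtype <- rep(rbinom(n_subj, 1, 0.5), each = cfg$n_timepoints)
    subtype[group == "ctrl"] <- 0L

    # planted latent supports: disjoint random blocks
    perm_g <- sample.int(cfg$n_genes)
    perm_t <- sample.int(cfg$n_otus)
    gene_support <- taxon_support <- list()
    if (cfg$n_latent > 0) {
      for (k in seq_len(cfg$n_latent)) {
        gene_support[[k]] <- sort(perm_g[(k - 1) * cfg$genes_per_factor +
                                           seq_len(cfg$genes_per_factor)])
        taxon_support[[k]] <- sort(perm_t[(k - 1) * cfg$taxa_per_factor +
                                            seq_len(cfg$taxa_per_factor)])
      }
    }
    Z <- matrix(rnorm(n_subj * max(cfg$n_latent, 1L)), n_subj)
    Zs <- Z[subj, , drop = FALSE]               # shared within subject

    lat_mask <- switch(cfg$latent_group, all = rep(1, n),
                       case = as.numeric(group == "case"),
                       ctrl = as.numeric(group == "ctrl"))
    dir_mask <- switch(cfg$direct_group, all = rep(1, n),
                       case = as.numeric(group == "case"),
                       ctrl = as.numeric(group == "ctrl"))

    # ---- taxa: log-normal factors closed to the simplex, multinomial reads
    a_t <- rnorm(cfg$n_otus, 0, 1.5)
    eta <- matrix(a_t, cfg$n_otus, n)
    if (cfg$n_latent > 0) {
      for (k in seq_len(cfg$n_latent)) {
        sgn <- sample(c(-1, 1), cfg$taxa_per_factor, replace = TRUE)
        eta[taxon_support[[k]], ] <- eta[taxon_support[[k]], ] +
          (cfg$latent_effect * sgn) %o% (Zs[, k] * lat_mask)
      }
    }
    eta <- eta + matrix(rnorm(cfg$n_otus * n, 0, 1.0), cfg$n_otus)
    rel <- apply(eta, 2, function(e) { p <- exp(e - max(e)); p / sum(p) })
    depth <- pmax(rpois(n, cfg$seq_depth_mean), cfg$n_otus)
    otu_counts <- vapply(seq_len(n),
                         function(i) rmultinom(1, depth[i], rel[, i])[, 1],
                         numeric(cfg$n_otus))
    dimnames(otu_counts) <- list(otu_id, sample_id)
    clr_true <- apply(rel, 2, function(p) log(p) - mean(log(p)))

    # ---- planted direct gene~taxon regressions, outside the latent supports
    if (is.null(direct_pairs)) {
      free_g <- setdiff(seq_len(cfg$n_genes), unlist(gene_support))
      free_t <- setdiff(seq_len(cfg$n_otus), unlist(taxon_support))
      if (cfg$n_direct_pairs > min(length(free_g), length(free_t)))
        stop("not enough free genes/taxa for the requested direct pairs")
      pg <- sample(free_g, cfg$n_direct_pairs)
      pt <- sample(free_t, cfg$n_direct_pairs)
      peff <- cfg$direct_effect * sample(c(-1, 1), cfg$n_direct_pairs,
                                         replace = TRUE)
    } else {
      pg <- direct_pairs$gene
      if (is.character(pg)) pg <- match(pg, gene_id)
      pt <- direct_pairs$taxon
      if (is.character(pt)) pt <- match(pt, otu_id)
      if (anyNA(pg) || anyNA(pt))
        stop("direct_pairs reference unknown genes or taxa")
      peff <- direct_pairs$effect
    }
    n_pairs <- length(pg)

    # ---- genes: NB counts around a structured log-mean
    b0 <- rnorm(cfg$n_genes, 6, 1)
    mu <- matrix(b0, cfg$n_genes, n)
    if (cfg$n_latent > 0) {
      for (k in seq_len(cfg$n_latent)) {
        sgn <- sample(c(-1, 1), cfg$genes_per_factor, replace = TRUE)
        mu[gene_support[[k]], ] <- mu[gene_support[[k]], ] +
          (cfg$latent_effect * sgn) %o% (Zs[, k] * lat_mask)
      }
    }
    if (n_pairs > 0) {
      for (j in seq_len(n_pairs)) {
        mu[pg[j], ] <- mu[pg[j], ] + peff[j] * clr_true[pt[j], ] * dir_mask
      }
    }
    cov_genes <- sample(setdiff(seq_len(cfg$n_genes), c(pg)),
                        max(1L, round(0.05 * cfg$n_genes)))
    mu[cov_genes, ] <- mu[cov_genes, ] + rep(1, length(cov_genes)) %o% sex
    lib <- rnorm(n, 0, 0.2)                      # per-sample size factor
    mu <- mu + matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes) +
      rep(1, cfg$n_genes) %o% lib
    gene_counts <- matrix(rnbinom(cfg$n_genes * n, mu = exp(mu),
                                  size = 1 / cfg$dispersion),
                          cfg$n_genes, dimnames = list(gene_id, sample_id))

    metadata <- data.frame(
      sample_id = sample_id,
      subject = sprintf("sub%03d", subj),
      timepoint = tp, group = group, sex = sex, subtype = subtype,
      stringsAsFactors = FALSE)

    dataset <- structure(list(gene_counts = gene_counts,
                              otu_counts = otu_counts,
                              taxonomy = taxonomy, metadata = metadata,
                              cohort = "synthetic"),
                         class = "paired_dataset")
    truth <- structure(list(
      latent_gene_support = lapply(gene_support, function(i) gene_id[i]),
      latent_taxon_support = lapply(taxon_support, function(i) otu_id[i]),
      direct_pairs = data.frame(gene = gene_id[pg], taxon = otu_id[pt],
                                effect = peff, stringsAsFactors = FALSE),
      covariate_genes = gene_id[sort(cov_genes)],
      group_specific_flags = list(latent = cfg$latent_group,
                                  direct = cfg$direct_group)),
      class = "synthetic_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Write a paired dataset in the pipeline's input formats
#'
#' Emits the same tab-delimited formats the pipeline reads: a taxa count table
#' with a `lineage` column, a gene count table, a metadata table, and
#' optionally a GMT gene-set file and a JSON ground-truth file.
#'
#' @param dataset a `paired_dataset`.
#' @param dir output directory (created if missing).
#' @param truth optional `synthetic_truth` written as `truth.json`.
#' @param gene_sets optional result of [simulate_gene_sets()] written as
#'   `gene_sets.gmt`.
#' @return `dir`, invisibly.
#' @export
write_paired_dataset <- function(dataset, dir, truth = NULL,
                                 gene_sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taxa <- data.frame(taxon_id = rownames(dataset$otu_counts),
                     lineage = dataset$taxonomy$lineage[
                       match(rownames(dataset$otu_counts),
                             dataset$taxonomy$otu_id)],
                     dataset$otu_counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(taxa, file.path(dir, "taxa_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes <- data.frame(gene_id = rownames(dataset$gene_counts),
                      dataset$gene_counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
  utils::write.table(genes, file.path(dir, "gene_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_sets))
    write_gmt(gene_sets$sets, file.path(dir, "gene_sets.gmt"))
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a paired dataset written by [write_paired_dataset()]
#'
#' @param dir directory holding `taxa_counts.tsv`, `gene_counts.tsv` and
#'   `metadata.tsv` (gzipped variants accepted).
#' @param cohort cohort name attached to the dataset.
#' @return a `paired_dataset`.
#' @export
read_paired_dataset <- function(dir, cohort = basename(dir)) {
  find1 <- function(base) {
    for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing input file: ", base, " in ", dir)
  }
  taxa <- utils::read.delim(find1("taxa_counts.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  genes <- utils::read.delim(find1("gene_counts.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  meta <- utils::read.delim(find1("metadata.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  otu_counts <- as.matrix(taxa[, setdiff(colnames(taxa),
                                         c("taxon_id", "lineage"))])
  rownames(otu_counts) <- taxa$taxon_id
  gene_counts <- as.matrix(genes[, setdiff(colnames(genes), "gene_id")])
  rownames(gene_counts) <- genes$gene_id
  ranks_from_lineage <- function(lin) {
    parts <- strsplit(lin, ";", fixed = TRUE)
    depth <- max(lengths(parts))
    m <- t(vapply(parts, function(p) {
      p <- c(p, rep("", depth - length(p)))
      ifelse(p == "", NA_character_, p)
    }, character(depth)))
    colnames(m) <- TAXO_RANKS[seq_len(depth)]
    m
  }
  taxonomy <- data.frame(otu_id = taxa$taxon_id,
                         ranks_from_lineage(taxa$lineage),
                         lineage = taxa$lineage, stringsAsFactors = FALSE)
  rownames(taxonomy) <- taxonomy$otu_id
  structure(list(gene_counts = gene_counts, otu_counts = otu_counts,
                 taxonomy = taxonomy, metadata = meta, cohort = cohort),
            class = "paired_dataset")
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated gene IDs.
#'
#' @param sets named list of gene ID vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file.
#' @return named list of gene ID vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)
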