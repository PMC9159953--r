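#' Overlap coefficient between two sets
#'
#' `|A n B| / min(|A|, |B|)`.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return value in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0)
    abort_stage("overlap_coefficient", "empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Deduplicate redundant pathways by connected components
#'
#' Takes the `top_n` most significant pathways (input order = significance
#' order), links every pair whose gene-set overlap coefficient exceeds
#' `threshold`, computes connected components, and keeps one representative
#' per component: the pathway with the most genes, ties broken by
#' lexicographically smallest ID. Singletons represent themselves.
#'
#' @param pathway_sets named list of member gene sets, sorted by
#'   significance.
#' @param top_n number of pathways considered (default 15).
#' @param threshold redundancy cut-off on the overlap coefficient (default
#'   0.5, strictly greater links).
#' @return data.frame with `pathway`, `component`, `representative`.
#' @export
dedup_pathways <- function(pathway_sets, top_n = 15, threshold = 0.5) {
  sets <- pathway_sets[seq_len(min(top_n, length(pathway_sets)))]
  nms <- names(sets)
  k <- length(sets)
  if (k == 0)
    return(data.frame(pathway = character(), component = integer(),
                      representative = logical(), stringsAsFactors = FALSE))
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  igraph::V(g)$name <- nms
  if (k > 1) {
    pairs <- utils::combn(k, 2)
    on <- apply(pairs, 2, function(pr)
      overlap_coefficient(sets[[pr[1]]], sets[[pr[2]]]) > threshold)
    if (any(on))
      g <- igraph::add_edges(g, as.vector(pairs[, on, drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  out <- data.frame(pathway = nms, component = unname(comp[nms]),
                    stringsAsFactors = FALSE)
  sizes <- lengths(sets)
  out$representative <- FALSE
  for (cc in unique(out$component)) {
    members <- out$pathway[out$component == cc]
    best <- members[order(-sizes[members], members)][1]
    out$representative[out$pathway == best] <- TRUE
  }
  out
}

# exact Venn region membership: cohorts in `members`, none of the others
venn_regions <- function(cohorts) {
  regions <- list(all = cohorts)
  if (length(cohorts) > 2) {
    prs <- utils::combn(cohorts, 2, simplify = FALSE)
    names(prs) <- vapply(prs, paste, character(1), collapse = "+")
    regions <- c(regions, prs)
  }
  regions
}

# round-robin edge picking: taxa ordered by their best q; pass r takes each
# taxon's r-th best association until the cap is reached
round_robin_pick <- function(tab, key_col, cap = 10) {
  if (nrow(tab) == 0) return(tab)
  tab <- tab[order(tab$q, tab$gene, tab$taxon), , drop = FALSE]
  keys <- unique(tab[[key_col]])     # already in best-q order
  picked <- integer(0)
  r <- 1
  while (length(picked) < cap) {
    got <- FALSE
    for (k in keys) {
      rows <- which(tab[[key_col]] == k)
      if (length(rows) >= r) {
        picked <- c(picked, rows[r]); got <- TRUE
        if (length(picked) >= cap) break
      }
    }
    if (!got) break
    r <- r + 1
  }
  tab[sort(picked), , drop = FALSE]
}

# normalize an association table to gene/taxon/q/rho edges
as_edges <- function(assoc, cohort) {
  if (nrow(assoc) == 0)
    return(data.frame(gene = character(), taxon = character(),
                      cohort = character(), q = numeric(),
                      spearman_rho = numeric(), stringsAsFactors = FALSE))
  data.frame(gene = assoc$gene, taxon = assoc$predictor, cohort = cohort,
             q = assoc$q, spearman_rho = assoc$spearman_rho,
             stringsAsFactors = FALSE)
}

#' Cross-cohort networks keyed by shared taxa
#'
#' For every Venn region of two or more cohorts (the full intersection plus
#' each pair-only region), finds taxa with at least one association in every
#' member cohort and in no non-member cohort, then per member cohort picks
#' edges round-robin by taxon in ascending q order, capped at 10 per cohort.
#'
#' @param assoc_tables named list (cohort -> association data.frame with
#'   `gene`, `predictor`, `q`, `spearman_rho`).
#' @param cap maximum edges per cohort per region (default 10).
#' @return named list of regions, each with `taxa` and `edges`.
#' @export
shared_taxa_networks <- function(assoc_tables, cap = 10) {
  stopifnot(length(assoc_tables) >= 2)
  cohorts <- names(assoc_tables)
  edges <- do.call(rbind, lapply(cohorts, function(co)
    as_edges(assoc_tables[[co]], co)))
  taxa_by_cohort <- lapply(cohorts, function(co)
    unique(edges$taxon[edges$cohort == co]))
  names(taxa_by_cohort) <- cohorts
  out <- list()
  for (rn in names(venn_regions(cohorts))) {
    members <- venn_regions(cohorts)[[rn]]
    others <- setdiff(cohorts, members)
    shared <- Reduce(intersect, taxa_by_cohort[members])
    if (length(others))
      shared <- setdiff(shared, unique(unlist(taxa_by_cohort[others])))
    picked <- do.call(rbind, lapply(members, function(co)
      round_robin_pick(edges[edges$cohort == co & edges$taxon %in% shared, ,
                             drop = FALSE], "taxon", cap)))
    out[[rn]] <- list(taxa = sort(shared),
                      edges = picked %||%
                        edges[0, , drop = FALSE])
  }
  out
}

#' Cross-cohort networks keyed by shared genes
#'
#' Analogous to [shared_taxa_networks()] with gene-keyed regions: shared
#' genes are ranked lexicographically by their best q in each member cohort
#' (cohort order of `assoc_tables`), the top 10 genes retained, and at most
#' the top `cap` associations involving them kept per cohort.
#'
#' @inheritParams shared_taxa_networks
#' @param top_genes number of shared genes retained per region (default 10).
#' @return named list of regions, each with `genes` and `edges`.
#' @export
shared_genes_networks <- function(assoc_tables, cap = 10, top_genes = 10) {
  stopifnot(length(assoc_tables) >= 2)
  cohorts <- names(assoc_tables)
  edges <- do.call(rbind, lapply(cohorts, function(co)
    as_edges(assoc_tables[[co]], co)))
  genes_by_cohort <- lapply(cohorts, function(co)
    unique(edges$gene[edges$cohort == co]))
  names(genes_by_cohort) <- cohorts
  out <- list()
  for (rn in names(venn_regions(cohorts))) {
    members <- venn_regions(cohorts)[[rn]]
    others <- setdiff(cohorts, members)
    shared <- Reduce(intersect, genes_by_cohort[members])
    if (length(others))
      shared <- setdiff(shared, unique(unlist(genes_by_cohort[others])))
    if (length(shared)) {
      # lexicographic ordering by best q per member cohort
      qmat <- vapply(members, function(co) {
        e <- edges[edges$cohort == co, ]
        vapply(shared, function(g) {
          qq <- e$q[e$gene == g]
          if (length(qq)) min(qq) else Inf
        }, numeric(1))
      }, numeric(length(shared)))
      qmat <- matrix(qmat, nrow = length(shared))
      ord <- do.call(order, c(as.data.frame(qmat), list(shared)))
      shared <- shared[ord][seq_len(min(top_genes, length(shared)))]
    }
    picked <- do.call(rbind, lapply(members, function(co) {
      e <- edges[edges$cohort == co & edges$gene %in% shared, , drop = FALSE]
      e <- e[order(e$q, e$gene, e$taxon), , drop = FALSE]
      e[seq_len(min(cap, nrow(e))), , drop = FALSE]
    }))
    out[[rn]] <- list(genes = sort(shared),
                      edges = picked %||% edges[0, , drop = FALSE])
  }
  out
}

#' Export a bipartite gene-taxon association network
#'
#' Nodes are typed `gene`/`taxon` with a cohort attribute (`"shared"` for
#' nodes appearing in two or more cohorts); edges carry sign
#' (of the Spearman rho), weight (its absolute value) and q. Writes GraphML
#' plus an edge-list TSV whose round trip through [import_network()]
#' reconstructs the edges exactly.
#'
#' @param edges data.frame with `gene`, `taxon`, `cohort`, `q`,
#'   `spearman_rho`.
#' @param graphml_path,tsv_path output paths (either may be NULL to skip).
#' @return the annotated edge data.frame, invisibly.
#' @export
export_network <- function(edges, graphml_path = NULL, tsv_path = NULL) {
  stopifnot(all(c("gene", "taxon", "cohort", "q", "spearman_rho") %in%
                  colnames(edges)))
  if (anyNA(edges$gene) || anyNA(edges$taxon))
    abort_stage("export_network", "dangling node references")
  edges$sign <- ifelse(edges$spearman_rho >= 0, "+", "-")
  edges$weight <- abs(edges$spearman_rho)
  node_cohort <- function(ids) {
    vapply(ids, function(id) {
      cs <- unique(edges$cohort[edges$gene == id | edges$taxon == id])
      if (length(cs) > 1) "shared" else cs
    }, character(1))
  }
  genes <- unique(edges$gene); taxa <- unique(edges$taxon)
  nodes <- data.frame(name = c(genes, taxa),
                      type = c(rep("gene", length(genes)),
                               rep("taxon", length(taxa))),
                      cohort = node_cohort(c(genes, taxa)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("gene", "taxon", "cohort", "sign", "weight", "q")],
    directed = FALSE, vertices = nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path))
    utils::write.table(
      edges[, c("gene", "taxon", "cohort", "sign", "weight", "q",
                "spearman_rho")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Re-read an exported edge-list TSV
#'
#' @param tsv_path file written by [export_network()].
#' @return edge data.frame.
#' @export
import_network <- function(tsv_path)
  utils::read.delim(tsv_path, stringsAsFactors = FALSE)

#' Pairwise overlap report across cohorts
#'
#' Overlap coefficients between cohorts for arbitrary named sets (input
#' genes, input taxa, associated genes, associated taxa).
#'
#' @param sets named list (cohort -> character vector).
#' @return data.frame with `cohort_a`, `cohort_b`, `overlap`.
#' @export
overlap_report <- function(sets) {
  cohorts <- names(sets)
  prs <- utils::combn(cohorts, 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr)
    data.frame(cohort_a = pr[1], cohort_b = pr[2],
               overlap = if (length(sets[[pr[1]]]) && length(sets[[pr[2]]]))
                 overlap_coefficient(sets[[pr[1]]], sets[[pr[2]]])
               else NA_real_,
               stringsAsFactors = FALSE)))
}
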