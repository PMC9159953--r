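#' Fisher exact pathway enrichment
#'
#' Builds the 2x2 table (`n1` = pathway & interest, `n2` = pathway &
#' background-only, `n3` = non-pathway & interest, `n4` = non-pathway &
#' background-only) for every pathway after intersecting sets with the
#' background and applying the profile's size filters (sparse CCA:
#' 25 <= |set| <= 300; lasso: 10 <= |set| <= 85; both require overlap >= 5),
#' then tests one-sided (enrichment) by Fisher's exact test with BH
#' correction across surviving pathways. The reported odds ratio is the
#' sample odds ratio `n1 n4 / (n2 n3)` with Haldane +0.5 applied to all cells
#' when any cell is zero, matching the differential-enrichment statistic.
#'
#' @param interest character vector of genes of interest (subset of
#'   background).
#' @param background character vector of background genes.
#' @param collection named list of pathway gene sets.
#' @param profile `"scca"` or `"lasso"` (size-filter presets).
#' @param alternative Fisher sidedness (default `"greater"`).
#' @return data.frame with `pathway`, `n1`..`n4`, `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(interest, background, collection,
                              profile = c("scca", "lasso"),
                              alternative = "greater") {
  profile <- match.arg(profile)
  if (!all(interest %in% background))
    abort_stage("fisher_enrichment", "interest set not within background")
  lims <- switch(profile, scca = c(25, 300), lasso = c(10, 85))
  interest <- unique(interest); background <- unique(background)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], background)
    if (length(set) < lims[1] || length(set) > lims[2]) return(NULL)
    n1 <- length(intersect(set, interest))
    if (n1 < 5) return(NULL)
    n2 <- length(set) - n1
    n3 <- length(interest) - n1
    n4 <- length(background) - n1 - n2 - n3
    tab <- matrix(c(n1, n2, n3, n4), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    cells <- c(n1, n2, n3, n4)
    h <- if (any(cells == 0)) cells + 0.5 else cells
    data.frame(pathway = nm, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
               odds_ratio = h[1] * h[4] / (h[2] * h[3]), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(), n1 = integer(), n2 = integer(),
                      n3 = integer(), n4 = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

# log odds ratio and its Woolf standard error with Haldane +0.5 correction
log_or_se <- function(n1, n2, n3, n4) {
  cells <- cbind(n1, n2, n3, n4)
  zero <- rowSums(cells == 0) > 0
  cells[zero, ] <- cells[zero, , drop = FALSE] + 0.5
  list(log_or = log(cells[, 1] * cells[, 4] / (cells[, 2] * cells[, 3])),
       se = sqrt(rowSums(1 / cells)))
}

#' Differential pathway enrichment between cases and controls
#'
#' For every pathway present in both record sets, computes the per-arm
#' z-score of the log odds ratio, `z = log(delta)/SE(delta)` with
#' `SE = sqrt(1/n1 + 1/n2 + 1/n3 + 1/n4)` (Haldane +0.5 on all cells of a
#' table containing a zero), and the comparative statistic
#' `z_diff = (log delta_case - log delta_ctrl) / sqrt(SE_case^2 +
#' SE_ctrl^2)`, with two-sided normal p-values BH-corrected across tested
#' pathways.
#'
#' @param case_recs,ctrl_recs enrichment tables from [fisher_enrichment()].
#' @return data.frame with `pathway`, `z_case`, `z_ctrl`, `z_diff`, `p_diff`,
#'   `q_diff`.
#' @export
differential_enrichment <- function(case_recs, ctrl_recs) {
  common <- intersect(case_recs$pathway, ctrl_recs$pathway)
  skipped <- setdiff(union(case_recs$pathway, ctrl_recs$pathway), common)
  if (length(skipped))
    message("differential_enrichment: skipping ", length(skipped),
            " pathway(s) missing in one arm")
  if (length(common) == 0)
    return(data.frame(pathway = character(), z_case = numeric(),
                      z_ctrl = numeric(), z_diff = numeric(),
                      p_diff = numeric(), q_diff = numeric(),
                      stringsAsFactors = FALSE))
  ca <- case_recs[match(common, case_recs$pathway), ]
  co <- ctrl_recs[match(common, ctrl_recs$pathway), ]
  lca <- log_or_se(ca$n1, ca$n2, ca$n3, ca$n4)
  lco <- log_or_se(co$n1, co$n2, co$n3, co$n4)
  z_diff <- (lca$log_or - lco$log_or) / sqrt(lca$se^2 + lco$se^2)
  p_diff <- 2 * stats::pnorm(-abs(z_diff))
  data.frame(pathway = common, z_case = lca$log_or / lca$se,
             z_ctrl = lco$log_or / lco$se, z_diff = z_diff, p_diff = p_diff,
             q_diff = stats::p.adjust(p_diff, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Case-specific pathway calling
#'
#' Two-part rule: (1) pathways significantly enriched in cases
#' (`q < fdr_enrich`) but not in controls; (2) pathways significant in both
#' arms that are differentially enriched (`q_diff < fdr_diff`). The union is
#' returned; with a multi-component source, each pathway is tagged with the
#' component in which it was most significant.
#'
#' @param case_recs,ctrl_recs enrichment tables (optionally with a
#'   `component` column).
#' @param diff_recs differential table from [differential_enrichment()].
#' @param fdr_enrich enrichment threshold (default 0.1).
#' @param fdr_diff differential threshold (default 0.2).
#' @return data.frame with `pathway`, `part` (1 or 2), `q_case`, and
#'   `component` when available.
#' @export
case_specific_pathways <- function(case_recs, ctrl_recs, diff_recs,
                                   fdr_enrich = 0.1, fdr_diff = 0.2) {
  sig_case <- case_recs$pathway[case_recs$q < fdr_enrich]
  sig_ctrl <- ctrl_recs$pathway[ctrl_recs$q < fdr_enrich]
  part1 <- setdiff(sig_case, sig_ctrl)
  both <- intersect(sig_case, sig_ctrl)
  sig_diff <- diff_recs$pathway[diff_recs$q_diff < fdr_diff]
  part2 <- intersect(both, sig_diff)
  pws <- c(part1, part2)
  if (length(pws) == 0)
    return(data.frame(pathway = character(), part = integer(),
                      q_case = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(pathway = pws,
                    part = c(rep(1L, length(part1)), rep(2L, length(part2))),
                    stringsAsFactors = FALSE)
  # most significant record per pathway (handles multi-component sources)
  best <- case_recs[order(case_recs$p), ]
  best <- best[!duplicated(best$pathway), ]
  idx <- match(out$pathway, best$pathway)
  out$q_case <- best$q[idx]
  if ("component" %in% colnames(best)) out$component <- best$component[idx]
  out[order(out$q_case, out$pathway), , drop = FALSE]
}
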