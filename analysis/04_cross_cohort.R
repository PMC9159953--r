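#!/usr/bin/env Rscript
# Combine the three cohort runs at the last step, mirroring a meta-analysis
# stance: pairwise overlap coefficients for input and associated features,
# shared-taxon and shared-gene Venn-region networks, and GraphML/TSV
# exports under results/cross_cohort/.

suppressMessages(library(homico))

dirs <- c(crohn = "results/runs/crohn", colitis = "results/runs/colitis",
          ibs = "results/runs/ibs")
cmp <- compare_cohorts(dirs, "results/cross_cohort")

for (nm in names(cmp$overlaps)) {
  message("overlap [", nm, "]:")
  print(cmp$overlaps[[nm]], row.names = FALSE)
}
for (rn in names(cmp$taxa_networks)) {
  tn <- cmp$taxa_networks[[rn]]
  message(sprintf("taxa network '%s': %d shared taxa, %d edges", rn,
                  length(tn$taxa), nrow(tn$edges)))
}
for (rn in names(cmp$gene_networks)) {
  gn <- cmp$gene_networks[[rn]]
  message(sprintf("gene network '%s': %d shared genes, %d edges", rn,
                  length(gn$genes), nrow(gn$edges)))
}
message("cross-cohort outputs under results/cross_cohort/")
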