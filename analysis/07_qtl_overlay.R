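#!/usr/bin/env Rscript
# QTL candidate genes: build marker-bounded intervals, enumerate contained
# genes, and overlay per-contrast DE status, ranking candidates by maximum
# |log2 fold change|.

suppressMessages(library(stressmem))
deg_tables <- read_deg_table("results/de/deg_tables.tsv")
spans <- read_gene_positions("results/sim/genes.gff3")
markers <- read_markers("results/sim/markers.tsv")
dir.create("results/qtl", recursive = TRUE, showWarnings = FALSE)

intervals <- marker_interval(markers)
write.table(intervals, "results/qtl/intervals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cands <- list()
for (i in seq_len(nrow(intervals))) {
  iv <- intervals[i, ]
  genes <- genes_in_interval(spans, iv)
  cand <- overlay_deg(genes, deg_tables, qtl = iv$qtl)
  cands[[iv$qtl]] <- cand
  top <- cand$gene_id[1]
  cat(iv$qtl, " (", iv$chromosome, ":", iv$start, "-", iv$end, "): ",
      nrow(cand), " genes, ", sum(cand$de_anywhere), " DE; top candidate ",
      top, " (max |log2FC| ", round(cand$max_abs_log2fc[1], 2), ")\n",
      sep = "")
}
write.table(do.call(rbind, cands), "results/qtl/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
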