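#!/usr/bin/env Rscript
# Differential expression: NB exact test per gene for every stress x
# timepoint contrast against the same-timepoint control, per tissue,
# excluding QC outliers. Writes the per-contrast DEG tables and the
# DEG count summary (down/up/total per contrast).

suppressMessages(library(stressmem))
cm <- read_counts("results/sim/counts.tsv", "results/sim/samples.tsv")
qc <- read.delim("results/qc/mds_report.tsv")
cm <- subset_samples(cm, !cm$samples$sample_id %in%
                       qc$sample_id[qc$outlier])
dir.create("results/de", recursive = TRUE, showWarnings = FALSE)

deg_tables <- list()
for (ti in unique(cm$samples$tissue)) {
  sub <- subset_samples(cm, cm$samples$tissue == ti)
  deg_tables <- c(deg_tables, call_all_degs(sub, ti))
}
write_deg_table(deg_tables, "results/de/deg_tables.tsv")

counts <- summarize_deg_counts(deg_tables)
write.table(counts, "results/de/deg_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("DEG counts per contrast:\n")
print(counts)

# expression heatmap input: per-tissue Z-score matrix over significant genes
for (ti in unique(cm$samples$tissue)) {
  tabs <- deg_tables[grep(paste0("^", ti, "\\."), names(deg_tables))]
  z <- zscore_matrix(tabs)
  cl <- cluster_genes(z, k = min(7, nrow(z)))
  write.table(data.frame(gene_id = rownames(z), z, cluster = cl,
                         check.names = FALSE),
              paste0("results/de/zscores_", ti, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(ti, ":", nrow(z), "DEGs in", max(cl), "expression clusters\n")
}
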