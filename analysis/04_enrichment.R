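#!/usr/bin/env Rscript
# Overrepresentation of GO terms and TF families in each contrast's DEG set
# (one-sided Fisher's exact test, Bonferroni-corrected), with the
# identical-gene-list collapsing rule applied to significant GO terms.

suppressMessages(library(stressmem))
deg_tables <- read_deg_table("results/de/deg_tables.tsv")
go <- read_annotations("results/sim/go_annotations.tsv", "GO")
tff <- read_annotations("results/sim/tff_annotations.tsv", "TFF")
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

run <- function(ann, label) {
  out <- list()
  for (key in names(deg_tables)) {
    t <- deg_tables[[key]]
    res <- enrich_terms(t$gene_id[t$significant], ann, contrast = key)
    out[[key]] <- as.data.frame(res)
  }
  df <- do.call(rbind, out)
  write.table(df, paste0("results/enrichment/", label, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  df
}
go_res <- run(go, "go")
tff_res <- run(tff, "tff")

sig_go <- unique(go_res$term_id[go_res$significant])
cat("significant GO terms across contrasts:", length(sig_go), "\n")
cat("significant TFF rows:", sum(tff_res$significant), "; DE TFs covered:",
    length(unique(unlist(lapply(names(deg_tables), function(k) {
      t <- deg_tables[[k]]
      intersect(t$gene_id[t$significant], names(tff$gene_to_terms))
    })))), "\n")

# collapsing rule on one contrast as an example artefact
k1 <- names(deg_tables)[1]
res1 <- enrich_terms(deg_tables[[k1]]$gene_id[deg_tables[[k1]]$significant],
                     go, contrast = k1)
col1 <- collapse_go(res1, go, deg_tables[[k1]]$gene_id[
  deg_tables[[k1]]$significant])
write.table(col1, "results/enrichment/go_collapsed_example.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("collapsing rule on ", k1, ": ", sum(res1$significant), " -> ",
    nrow(col1), " terms\n", sep = "")
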