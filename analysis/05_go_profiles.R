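#!/usr/bin/env Rscript
# GO-percentage profiles: per tissue, the percentage of each significant
# term's genome-wide gene set that is differentially expressed per
# (stress, timepoint, direction) column; clustered and annotated by the
# most prevalent terms. Also decomposes DE transcription factors by family
# and GO cluster.

suppressMessages(library(stressmem))
deg_tables <- read_deg_table("results/de/deg_tables.tsv")
go <- read_annotations("results/sim/go_annotations.tsv", "GO")
tff <- read_annotations("results/sim/tff_annotations.tsv", "TFF")
enr <- read.delim("results/enrichment/go.tsv")
dir.create("results/profiles", recursive = TRUE, showWarnings = FALSE)

k_profile <- c(leaf = 7, root = 3)
k_top <- c(leaf = 5, root = 10)
tissues <- unique(sub("\\..*$", "", names(deg_tables)))
for (ti in tissues) {
  tabs <- deg_tables[grep(paste0("^", ti, "\\."), names(deg_tables))]
  sig <- unique(enr$term_id[enr$significant &
                              grepl(paste0("^", ti, "\\."), enr$contrast)])
  if (length(sig) < 2) { cat(ti, ": too few significant terms\n"); next }
  mat <- go_profile_matrix(sig, tabs, go)
  k <- min(unname(k_profile[ti]), nrow(mat))
  cl <- cluster_profiles(mat, k)
  write.table(data.frame(term_id = rownames(mat), mat,
                         cluster = cl[rownames(mat)], check.names = FALSE),
              paste0("results/profiles/go_profiles_", ti, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  annot <- annotate_clusters(cl, go, k_top = unname(k_top[ti]))
  write.table(annot, paste0("results/profiles/cluster_annotation_", ti,
                            ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tf <- tf_by_cluster(tabs, tff, cl, go)
  write.table(tf, paste0("results/profiles/tf_by_cluster_", ti, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(ti, ":", nrow(mat), "terms in", k, "profile clusters;",
      sum(tf$n_tf), "DE-TF x cluster assignments\n")
}
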