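#!/usr/bin/env Rscript
# Replicate quality control: per-tissue MDS of log normalized counts and
# outlier flagging at 3x the median within-condition centroid distance.
# Writes MDS coordinates, flags and size factors.

suppressMessages(library(stressmem))
cm <- read_counts("results/sim/counts.tsv", "results/sim/samples.tsv")
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

all_rows <- list()
for (ti in unique(cm$samples$tissue)) {
  sub <- subset_samples(cm, cm$samples$tissue == ti)
  qc <- replicate_qc(sub, threshold = 3)
  rows <- data.frame(sample_id = rownames(qc$coords),
                     tissue = ti,
                     mds1 = qc$coords[, 1], mds2 = qc$coords[, 2],
                     centroid_dist = qc$centroid_dist,
                     outlier = qc$outlier)
  all_rows[[ti]] <- rows
  cat(ti, ": ", sum(qc$outlier), " outlier(s)",
      if (length(qc$removed)) paste0(" (", paste(qc$removed, collapse = ", "),
                                     ")"),
      "\n", sep = "")
}
qc_tab <- do.call(rbind, all_rows)
write.table(qc_tab, "results/qc/mds_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

keep <- !cm$samples$sample_id %in% qc_tab$sample_id[qc_tab$outlier]
cm <- subset_samples(cm, keep)
sf <- unlist(lapply(unique(cm$samples$tissue), function(ti)
  size_factors(subset_samples(cm, cm$samples$tissue == ti))))
write.table(data.frame(sample_id = names(sf), size_factor = sf),
            "results/qc/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("size factors span [", round(min(sf), 3), ",", round(max(sf), 3),
    "] after renormalization on", sum(keep), "retained samples\n")
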