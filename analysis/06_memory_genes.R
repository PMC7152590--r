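#!/usr/bin/env Rscript
# Stress-memory genes: per tissue and stress, (i) genes significant at both
# T1T2 and T2 with opposite direction, and (ii) genes significant only at
# T1T2; plus Fe/Pi overlaps of each class.

suppressMessages(library(stressmem))
deg_tables <- read_deg_table("results/de/deg_tables.tsv")
dir.create("results/memory", recursive = TRUE, showWarnings = FALSE)

sets <- list(); overlap_rows <- list()
tissues <- unique(sub("\\..*$", "", names(deg_tables)))
for (ti in tissues) {
  per_stress <- list()
  for (st in c("Fe", "Pi")) {
    tabs <- deg_tables[paste(ti, st, c("T1", "T1Rec", "T1T2", "T2"),
                             sep = ".")]
    mem <- memory_genes(tabs)
    per_stress[[st]] <- mem
    sets <- c(sets, mem)
    cat(ti, st, ": opposite", nrow(mem$opposite$genes),
        "| T1T2-unique", nrow(mem$t1t2_unique$genes), "\n")
  }
  for (cls in c("opposite", "t1t2_unique")) {
    ov <- cross_stress_overlap(per_stress$Fe[[cls]], per_stress$Pi[[cls]])
    overlap_rows[[paste(ti, cls)]] <- data.frame(
      tissue = ti, class = cls, t(ov))
    cat(ti, cls, ": Fe-only", ov["n_fe_only"], "| Pi-only", ov["n_pi_only"],
        "| common", ov["n_common"], "\n")
  }
}
write_memory_genes(sets, "results/memory/memory_genes.tsv")
write.table(do.call(rbind, overlap_rows), "results/memory/overlap.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
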