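#!/usr/bin/env Rscript
# Generate the synthetic study: a 2-tissue x (control, -Fe, -Pi) x
# (T1, T1Rec, T1T2, T2) design, 3 replicates, NB counts with planted DEGs,
# memory genes, enriched GO terms, TF families and QTL intervals.
# Writes the pipeline's input files plus the truth manifest.

suppressMessages(library(stressmem))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1

cfg <- sim_config(seed = seed)
study <- generate_study(cfg)
write_study(study, "results/sim")

cat("simulated", nrow(study$cm$counts), "genes x", ncol(study$cm$counts),
    "samples (", length(unique(stressmem:::condition_key(study$cm$samples))),
    "conditions )\n")
cat("planted truth:", sum(rowSums(abs(study$truth$l2fc) > 1) > 0),
    "DE genes;", nrow(study$truth$memory), "memory-gene records;",
    length(study$annotations$enriched_terms), "enriched GO terms;",
    length(study$genome$qtl_truth), "QTLs\n")
cat("inputs written under results/sim\n")
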