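#' Simulation configuration
#'
#' Defines the synthetic experiment: a two-tissue, control/Fe/Pi,
#' four-timepoint hydroponic stress design (controls harvested at T1, T1Rec
#' and T2; 11 groups per tissue) with negative-binomial counts
#' (variance = mu + alpha mu^2), planted differentially expressed genes,
#' planted memory genes of both classes, planted enriched GO terms, a
#' transcription-factor-family labelling seeded from genome-scale family
#' sizes, and QTL intervals bracketing known gene runs.
#'
#' Planted effects use |log2fc| = `effect_size` and baselines floored at
#' `min_de_baseline` so every planted gene is a true DEG under the
#' fold-change > 2 calling rule.
#'
#' @param n_genes number of genes (default 5000).
#' @param tissues tissues to simulate (default leaf and root).
#' @param replicates biological replicates per group (default 3).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale normal for gene
#'   baseline means (defaults 5 and 2).
#' @param min_de_baseline floor on the baseline mean of planted genes
#'   (default 50).
#' @param min_memory_baseline floor on the baseline mean of planted memory
#'   genes, both classes (default 100).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param dispersion_shape gamma shape for per-gene dispersion variation;
#'   `Inf` (default) keeps alpha constant at `dispersion`.
#' @param effect_size planted |log2 fold change| (default 2).
#' @param n_t1,n_t1rec,n_shared,n_opposite,n_unique,n_t2only planted gene
#'   counts per (tissue, stress): DE at T1 only, at T1Rec only, same
#'   direction at both T1T2 and T2, opposite directions at T1T2 vs T2
#'   (memory class 1), T1T2 only (memory class 2), and T2 only.
#' @param n_unique_common of the `n_unique` genes, how many are shared
#'   between the Fe and Pi stresses of a tissue (default 30).
#' @param sf_range true sample size-factor range, drawn log-uniform
#'   (default c(0.5, 2)).
#' @param n_terms,term_size_range GO term count and log-uniform size range
#'   (defaults 200 and c(10, 500)).
#' @param n_enriched planted enriched GO terms (default 10).
#' @param enriched_size_min minimum size of planted enriched terms (default
#'   50): below roughly this size an overrepresented term carries too few
#'   expected DEG members to be detectable at the Bonferroni level, so
#'   planting smaller terms would plant undetectable truth.
#' @param enrich_or odds-ratio with which planted-term genes are drawn from
#'   the target DEG set (default 8).
#' @param enriched_target contrast whose true DEG set seeds the planted
#'   enrichment (default `"leaf.Fe.T1"`).
#' @param tff_sizes named genome family sizes; defaults to the nine-family
#'   genome profile (AP2-EREBP 343, AUX-IAA-ARF 117, E2F/DP 12, GRAS 113,
#'   Homeodomain 274, NAC 187, TPR 279, WRKY 174, ZIM 24).
#' @param tff_scale scaling applied to `tff_sizes` so the TF complement fits
#'   the simulated gene count (default 0.3).
#' @param n_chrom chromosomes (default 3).
#' @param n_qtl QTL intervals (default 3).
#' @param qtl_genes genes bracketed by each QTL (default 20).
#' @param seed master seed; per-stage child seeds derive from it.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 5000, tissues = c("leaf", "root"),
                       replicates = 3, baseline_log2_mean = 5,
                       baseline_log2_sd = 2, min_de_baseline = 50,
                       min_memory_baseline = 100,
                       dispersion = 0.1, dispersion_shape = Inf,
                       effect_size = 2,
                       n_t1 = 150, n_t1rec = 100, n_shared = 40,
                       n_opposite = 100, n_unique = 350,
                       n_unique_common = 30, n_t2only = 60,
                       sf_range = c(0.5, 2),
                       n_terms = 200, term_size_range = c(10, 500),
                       n_enriched = 10, enriched_size_min = 50,
                       enrich_or = 8,
                       enriched_target = "leaf.Fe.T1",
                       tff_sizes = c("AP2-EREBP" = 343, "AUX-IAA-ARF" = 117,
                                     "E2F/DP" = 12, "GRAS" = 113,
                                     "Homeodomain" = 274, "NAC" = 187,
                                     "TPR" = 279, "WRKY" = 174, "ZIM" = 24),
                       tff_scale = 0.3,
                       n_chrom = 3, n_qtl = 3, qtl_genes = 20,
                       seed = 1) {
  cfg <- as.list(environment())
  per_stress <- n_t1 + n_t1rec + n_shared + n_opposite + n_unique + n_t2only
  budget <- n_unique_common + 2 * (per_stress - n_unique_common)
  if (budget > n_genes)
    stop("planted gene counts exceed the gene budget", call. = FALSE)
  if (n_unique_common > n_unique)
    stop("n_unique_common exceeds n_unique", call. = FALSE)
  if (effect_size <= 1)
    stop("effect_size must exceed 1 (|log2fc| > 1 for planted truth)",
         call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage) %% 2147483647)
}

contrast_keys <- function(cfg) {
  grid <- expand.grid(tp = TIMEPOINTS, st = c("Fe", "Pi"),
                      ti = cfg$tissues, stringsAsFactors = FALSE)
  paste(grid$ti, grid$st, grid$tp, sep = ".")
}

#' Generate a synthetic count matrix with planted truth
#'
#' Counts are drawn as NB(mean = sf_j * mu_g * 2^log2fc, dispersion alpha_g)
#' where log2fc is the planted effect of the sample's (tissue, stress,
#' timepoint) condition (0 for controls and unplanted genes). Size factors
#' are log-uniform in `sf_range`. Planted classes per (tissue, stress)
#' follow the config counts; the truth manifest records every planted
#' effect, so each downstream stage can be scored.
#'
#' @param cfg a [sim_config()].
#' @return list with `cm` (a [count_matrix()]) and `truth` (list with
#'   `baseline`, `alpha`, `sf`, `l2fc` gene x contrast matrix, and `memory`
#'   data.frame of planted memory classes).
#' @export
generate_experiment <- function(cfg) {
  set.seed(child_seed(cfg$seed, 1))
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  baseline <- 2^rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                      cfg$baseline_log2_sd)
  names(baseline) <- genes
  alpha <- if (is.finite(cfg$dispersion_shape))
    stats::rgamma(cfg$n_genes, shape = cfg$dispersion_shape,
                  scale = cfg$dispersion / cfg$dispersion_shape)
  else rep(cfg$dispersion, cfg$n_genes)
  names(alpha) <- genes

  keys <- contrast_keys(cfg)
  l2fc <- matrix(0, cfg$n_genes, length(keys),
                 dimnames = list(genes, keys))
  es <- cfg$effect_size
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  memory_planted <- character(0)

  for (ti in cfg$tissues) {
    pool <- genes
    common_unique <- sample(pool, cfg$n_unique_common)
    pool <- setdiff(pool, common_unique)
    for (st in c("Fe", "Pi")) {
      sizes <- c(t1 = cfg$n_t1, t1rec = cfg$n_t1rec, shared = cfg$n_shared,
                 opposite = cfg$n_opposite,
                 unique = cfg$n_unique - cfg$n_unique_common,
                 t2only = cfg$n_t2only)
      drawn <- sample(pool, sum(sizes))
      pool <- setdiff(pool, drawn)
      sets <- split(drawn, rep(names(sizes), sizes))
      key <- function(tp) paste(ti, st, tp, sep = ".")
      l2fc[sets$t1, key("T1")] <- es * rsign(length(sets$t1))
      l2fc[sets$t1rec, key("T1Rec")] <- es * rsign(length(sets$t1rec))
      sh <- es * rsign(length(sets$shared))
      l2fc[sets$shared, key("T1T2")] <- sh
      l2fc[sets$shared, key("T2")] <- sh
      op <- es * rsign(length(sets$opposite))
      l2fc[sets$opposite, key("T1T2")] <- op
      l2fc[sets$opposite, key("T2")] <- -op
      uni <- c(sets$unique, common_unique)
      l2fc[uni, key("T1T2")] <- es * rsign(length(uni))
      l2fc[sets$t2only, key("T2")] <- es * rsign(length(sets$t2only))
      memory_planted <- union(memory_planted, c(sets$opposite, uni))
    }
  }
  planted <- rowSums(abs(l2fc)) > 0
  baseline[planted] <- pmax(baseline[planted], cfg$min_de_baseline)
  baseline[memory_planted] <- pmax(baseline[memory_planted],
                                   cfg$min_memory_baseline)

  # sample sheet: stresses Fe/Pi at all 4 timepoints, controls at T1/T1Rec/T2
  grp <- expand.grid(timepoint = TIMEPOINTS, stress = c("Fe", "Pi"),
                     tissue = cfg$tissues, stringsAsFactors = FALSE)
  ctl <- expand.grid(timepoint = c("T1", "T1Rec", "T2"), stress = "control",
                     tissue = cfg$tissues, stringsAsFactors = FALSE)
  grp <- rbind(grp, ctl)
  samples <- grp[rep(seq_len(nrow(grp)), each = cfg$replicates),
                 c("tissue", "stress", "timepoint")]
  samples$replicate <- rep(seq_len(cfg$replicates), nrow(grp))
  samples$sample_id <- with(samples,
    paste(tissue, stress, timepoint, paste0("r", replicate), sep = "_"))
  samples <- samples[order(samples$tissue, samples$stress,
                           match(samples$timepoint, TIMEPOINTS),
                           samples$replicate),
                     c("sample_id", "tissue", "stress", "timepoint",
                       "replicate")]
  rownames(samples) <- NULL

  sf <- exp(runif(nrow(samples), log(cfg$sf_range[1]), log(cfg$sf_range[2])))
  names(sf) <- samples$sample_id

  counts <- matrix(0L, cfg$n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    fc <- if (s$stress == "control") rep(0, cfg$n_genes) else
      l2fc[, paste(s$tissue, s$stress, s$timepoint, sep = ".")]
    mu <- sf[j] * baseline * 2^fc
    counts[, j] <- if (all(alpha == 0)) stats::rpois(cfg$n_genes, mu) else
      rnbinom(cfg$n_genes, size = 1 / pmax(alpha, 1e-12), mu = mu)
  }

  truth <- list(baseline = baseline, alpha = alpha, sf = sf, l2fc = l2fc,
                memory = truth_memory_classes(l2fc, cfg))
  list(cm = count_matrix(counts, samples), truth = truth)
}

# derive planted memory classes from the truth log2fc matrix by the same
# definitions the classifier applies (significance <=> |log2fc| > 1)
truth_memory_classes <- function(l2fc, cfg) {
  rows <- list()
  for (ti in cfg$tissues) for (st in c("Fe", "Pi")) {
    key <- function(tp) paste(ti, st, tp, sep = ".")
    sig <- abs(l2fc[, vapply(TIMEPOINTS, key, character(1))]) > 1
    colnames(sig) <- TIMEPOINTS
    opp <- sig[, "T1T2"] & sig[, "T2"] &
      sign(l2fc[, key("T1T2")]) != sign(l2fc[, key("T2")])
    uni <- sig[, "T1T2"] & !sig[, "T1"] & !sig[, "T1Rec"] & !sig[, "T2"]
    g <- rownames(l2fc)
    if (any(opp))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = ti, stress = st, class = "opposite", gene_id = g[opp],
        stringsAsFactors = FALSE)
    if (any(uni))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = ti, stress = st, class = "t1t2_unique", gene_id = g[uni],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate GO and TFF annotations with planted enrichment
#'
#' GO term sizes are log-uniform in `term_size_range`. The first
#' `n_enriched` terms draw their genes with odds ratio `enrich_or` in favour
#' of the true DEG set of the `enriched_target` contrast, planting real
#' overrepresentation; the remaining terms sample genes uniformly. TFF
#' labels partition a TF complement whose family sizes are the scaled
#' genome profile; each gene gets at most one family.
#'
#' @param cfg a [sim_config()].
#' @param truth the truth component of [generate_experiment()].
#' @return list with `go` and `tff` ([annotation_map()]s) and
#'   `enriched_terms` (planted term ids).
#' @export
generate_annotations <- function(cfg, truth) {
  set.seed(child_seed(cfg$seed, 2))
  genes <- rownames(truth$l2fc)
  target <- genes[abs(truth$l2fc[, cfg$enriched_target]) > 1]
  sizes <- round(exp(runif(cfg$n_terms, log(cfg$term_size_range[1]),
                           log(cfg$term_size_range[2]))))
  lo <- max(cfg$enriched_size_min, cfg$term_size_range[1])
  sizes[seq_len(cfg$n_enriched)] <-
    round(exp(runif(cfg$n_enriched, log(lo), log(cfg$term_size_range[2]))))
  sizes <- pmin(sizes, cfg$n_genes)
  term_ids <- sprintf("GO:%07d", seq_len(cfg$n_terms))
  w_enriched <- ifelse(genes %in% target, cfg$enrich_or, 1)
  rows <- lapply(seq_len(cfg$n_terms), function(i) {
    w <- if (i <= cfg$n_enriched) w_enriched else rep(1, length(genes))
    data.frame(gene_id = sample(genes, sizes[i], prob = w),
               term_id = term_ids[i],
               term_name = paste0("process ", i),
               stringsAsFactors = FALSE)
  })
  go <- annotation_map(do.call(rbind, rows), "GO")

  fam_sizes <- round(cfg$tff_sizes * cfg$tff_scale)
  fam_sizes[fam_sizes < 1] <- 1
  n_tf <- sum(fam_sizes)
  if (n_tf > cfg$n_genes) stop("TFF sizes exceed gene count", call. = FALSE)
  tf_genes <- sample(genes, n_tf)
  tff <- annotation_map(data.frame(
    gene_id = tf_genes,
    term_id = rep(names(fam_sizes), fam_sizes),
    stringsAsFactors = FALSE), "TFF")

  list(go = go, tff = tff,
       enriched_terms = term_ids[seq_len(cfg$n_enriched)])
}

#' Generate gene coordinates and QTL markers
#'
#' Genes are laid non-overlapping along chromosomes with random widths and
#' gaps. Each QTL brackets a contiguous run of `qtl_genes` genes with four
#' SNP markers, the outer pair placed just outside the run so the truth
#' membership is exactly that run.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids gene identifiers (rownames of the truth log2fc matrix).
#' @return list with `spans` (gene position data.frame), `markers`
#'   (marker data.frame) and `qtl_truth` (named list of in-interval gene ids
#'   per QTL).
#' @export
generate_genome <- function(cfg, gene_ids) {
  set.seed(child_seed(cfg$seed, 3))
  n <- length(gene_ids)
  chrom <- paste0("Chr", sprintf("%02d", rep(seq_len(cfg$n_chrom),
                                             length.out = n)))
  chrom <- sort(chrom)
  widths <- round(runif(n, 1000, 5000))
  gaps <- round(runif(n, 500, 5000))
  start <- integer(n); end <- integer(n)
  pos <- 1
  for (i in seq_len(n)) {
    if (i > 1 && chrom[i] != chrom[i - 1]) pos <- 1
    start[i] <- pos + gaps[i]
    end[i] <- start[i] + widths[i] - 1
    pos <- end[i]
  }
  spans <- data.frame(gene_id = gene_ids, chromosome = chrom,
                      start = start, end = end,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)

  markers <- list(); qtl_truth <- list()
  per_chrom <- split(seq_len(n), chrom)
  for (q in seq_len(cfg$n_qtl)) {
    cc <- names(per_chrom)[1 + (q - 1) %% length(per_chrom)]
    idx <- per_chrom[[cc]]
    first <- sample(seq_len(length(idx) - cfg$qtl_genes + 1), 1)
    run <- idx[first:(first + cfg$qtl_genes - 1)]
    lab <- paste0("QTL", q)
    lo <- spans$start[run[1]] - 100
    hi <- spans$end[run[length(run)]] + 100
    inner <- sort(round(runif(2, lo, hi)))
    markers[[q]] <- data.frame(
      marker_id = paste0(lab, "_m", 1:4),
      chromosome = cc,
      position = c(lo, inner, hi),
      qtl = lab, stringsAsFactors = FALSE)
    qtl_truth[[lab]] <- spans$gene_id[run]
  }
  list(spans = spans, markers = do.call(rbind, markers),
       qtl_truth = qtl_truth)
}

#' Generate the full synthetic study
#'
#' Runs [generate_experiment()], [generate_annotations()] and
#' [generate_genome()] under the config's master seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `cm`, `truth`, `annotations`, `genome` and `cfg`.
#' @export
generate_study <- function(cfg = sim_config()) {
  exp <- generate_experiment(cfg)
  ann <- generate_annotations(cfg, exp$truth)
  gen <- generate_genome(cfg, rownames(exp$truth$l2fc))
  list(cm = exp$cm, truth = exp$truth, annotations = ann, genome = gen,
       cfg = cfg)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits counts TSV + sample sheet, GO and TFF annotation TSVs, a GFF3 gene
#' position file, marker TSV and BED, truth manifest TSVs and the config as
#' YAML. All files are synthetic data generated by this package.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_counts(study$cm, fp("counts.tsv"), fp("samples.tsv"))
  write_annotations(study$annotations$go, fp("go_annotations.tsv"))
  write_annotations(study$annotations$tff, fp("tff_annotations.tsv"))
  write_gene_positions(study$genome$spans, fp("genes.gff3"))
  write.table(study$genome$markers, fp("markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_markers(study$genome$markers, fp("markers.bed"))
  tr <- study$truth
  manifest <- data.frame(gene_id = rownames(tr$l2fc),
                         baseline = unname(tr$baseline),
                         alpha = unname(tr$alpha), tr$l2fc,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write.table(manifest, fp("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tr$memory, fp("truth_memory.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(
    data.frame(term_id = study$annotations$enriched_terms),
    fp("truth_enriched_terms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- study$cfg
  cfg$tff_sizes <- as.list(cfg$tff_sizes)
  yaml::write_yaml(unclass(cfg), fp("config.yaml"))
  invisible(dir)
}

#' Simulate GO-percentage profile archetypes
#'
#' Builds a term x column percentage matrix from `k` planted archetype
#' profiles plus Gaussian noise (in percentage points), for testing profile
#' clustering recovery.
#'
#' @param n_terms terms to simulate (default 60).
#' @param k archetypes (default 3).
#' @param n_cols profile columns (default 16).
#' @param noise_sd noise in percentage points (default 2).
#' @param seed RNG seed.
#' @return list with `mat` (matrix, values clipped to [0, 100]) and `labels`
#'   (true archetype per term).
#' @export
simulate_go_archetypes <- function(n_terms = 60, k = 3, n_cols = 16,
                                   noise_sd = 2, seed = 1) {
  set.seed(seed)
  arch <- matrix(runif(k * n_cols, 0, 40), k, n_cols)
  labels <- rep(seq_len(k), length.out = n_terms)
  mat <- arch[labels, ] + matrix(rnorm(n_terms * n_cols, 0, noise_sd),
                                 n_terms, n_cols)
  mat <- pmin(pmax(mat, 0), 100)
  rownames(mat) <- sprintf("GO:%07d", seq_len(n_terms))
  colnames(mat) <- paste0("col", seq_len(n_cols))
  list(mat = mat, labels = setNames(labels, rownames(mat)))
}

#' Simulate gene expression Z-profile groups
#'
#' Generates per-gene log2fc profiles from `k` well-separated planted
#' archetypes plus noise, for testing expression-cluster recovery.
#'
#' @param n_genes genes (default 100).
#' @param k planted groups (default 2).
#' @param n_cols contrast columns (default 8).
#' @param noise_sd noise on log2fc (default 0.3).
#' @param seed RNG seed.
#' @return list with `mat` (log2fc matrix) and `labels`.
#' @export
simulate_expression_groups <- function(n_genes = 100, k = 2, n_cols = 8,
                                       noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  arch <- matrix(rnorm(k * n_cols, 0, 3), k, n_cols)
  labels <- rep(seq_len(k), length.out = n_genes)
  mat <- arch[labels, ] + matrix(rnorm(n_genes * n_cols, 0, noise_sd),
                                 n_genes, n_cols)
  rownames(mat) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(mat) <- paste0("c", seq_len(n_cols))
  list(mat = mat, labels = setNames(labels, rownames(mat)))
}
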