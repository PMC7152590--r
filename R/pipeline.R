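#' Run the full analysis pipeline on a synthetic or loaded study
#'
#' Stage order: replicate QC -> normalization -> differential expression for
#' every stress x timepoint contrast of every tissue -> DEG count summary
#' (Table-1 analogue) -> GO and TFF overrepresentation per contrast ->
#' GO-percentage profiles with clustering and cluster annotation -> TF by
#' family and GO cluster -> memory gene classes and cross-stress overlaps ->
#' QTL interval candidate tables. Deterministic given the study, so rerunning
#' on the same inputs reproduces every artefact.
#'
#' @param study a [generate_study()] result, or a list with the same
#'   components loaded from disk (`cm`, `annotations$go`, `annotations$tff`,
#'   `genome$spans`, `genome$markers`).
#' @param k_profile named per-tissue cluster counts for GO profiles
#'   (defaults: leaf 7, root 3, matching the original full-scale analysis).
#' @param k_top named per-tissue top-term counts for cluster annotation
#'   (defaults: leaf 5, root 10).
#' @param qc_threshold MDS outlier multiplier; samples flagged at this
#'   threshold are dropped and the data renormalized before DE.
#' @param ... passed to [call_degs()].
#' @return list of class `ReportBundle` with elements `qc`, `deg_tables`,
#'   `deg_counts`, `enrichment_go`, `enrichment_tff`, `go_profiles`
#'   (per-tissue matrix, clusters, cluster annotation), `tf_clusters`,
#'   `memory`, `memory_overlap`, `qtl` (intervals and candidate tables).
#' @export
run_pipeline <- function(study, k_profile = c(leaf = 7, root = 3),
                         k_top = c(leaf = 5, root = 10), qc_threshold = 3,
                         ...) {
  cm <- study$cm
  tissues <- unique(cm$samples$tissue)

  qc <- lapply(setNames(tissues, tissues), function(ti) {
    sub <- subset_samples(cm, cm$samples$tissue == ti)
    replicate_qc(sub, threshold = qc_threshold)
  })
  removed <- unlist(lapply(qc, function(q) q$removed), use.names = FALSE)
  if (length(removed))
    cm <- subset_samples(cm, !cm$samples$sample_id %in% removed)

  deg_tables <- list()
  for (ti in tissues) {
    sub <- subset_samples(cm, cm$samples$tissue == ti)
    deg_tables <- c(deg_tables, call_all_degs(sub, ti, ...))
  }
  deg_counts <- summarize_deg_counts(deg_tables)

  go <- study$annotations$go
  tff <- study$annotations$tff
  enrichment_go <- lapply(deg_tables, function(t)
    enrich_terms(t$gene_id[t$significant], go,
                 contrast = paste(t$tissue[1], t$stress[1], t$timepoint[1],
                                  sep = ".")))
  enrichment_tff <- lapply(deg_tables, function(t)
    enrich_terms(t$gene_id[t$significant], tff,
                 contrast = paste(t$tissue[1], t$stress[1], t$timepoint[1],
                                  sep = ".")))

  go_profiles <- list(); tf_clusters <- list()
  for (ti in tissues) {
    tabs <- deg_tables[grep(paste0("^", ti, "\\."), names(deg_tables))]
    sig_terms <- unique(unlist(lapply(
      enrichment_go[names(tabs)], function(e) e$term_id[e$significant])))
    if (length(sig_terms) < 2) {
      go_profiles[[ti]] <- NULL
      next
    }
    mat <- go_profile_matrix(sig_terms, tabs, go)
    k <- min(unname(k_profile[ti]), nrow(mat))
    clusters <- cluster_profiles(mat, k)
    go_profiles[[ti]] <- list(
      matrix = mat, clusters = clusters,
      annotation = annotate_clusters(clusters, go,
                                     k_top = unname(k_top[ti])))
    tf_clusters[[ti]] <- tf_by_cluster(tabs, tff, clusters, go)
  }

  memory <- list(); overlap <- list()
  for (ti in tissues) {
    sets <- list()
    for (st in c("Fe", "Pi")) {
      tabs <- deg_tables[paste(ti, st, TIMEPOINTS, sep = ".")]
      sets[[st]] <- memory_genes(tabs)
      memory[[paste(ti, st, sep = ".")]] <- sets[[st]]
    }
    for (cls in c("opposite", "t1t2_unique"))
      overlap[[paste(ti, cls, sep = ".")]] <-
        cross_stress_overlap(sets$Fe[[cls]], sets$Pi[[cls]])
  }

  intervals <- marker_interval(study$genome$markers)
  qtl <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    genes <- genes_in_interval(study$genome$spans, iv)
    overlay_deg(genes, deg_tables, qtl = iv$qtl)
  })
  names(qtl) <- intervals$qtl

  structure(list(qc = qc, removed_samples = removed,
                 deg_tables = deg_tables, deg_counts = deg_counts,
                 enrichment_go = enrichment_go,
                 enrichment_tff = enrichment_tff,
                 go_profiles = go_profiles, tf_clusters = tf_clusters,
                 memory = memory, memory_overlap = overlap,
                 qtl_intervals = intervals, qtl = qtl),
            class = "ReportBundle")
}

#' Subset a CountMatrix by sample
#' @param cm a [count_matrix()].
#' @param keep logical or integer index over samples.
#' @return the subsetted [count_matrix()].
#' @export
subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$samples[keep, , drop = FALSE])
}

#' Score a pipeline run against the planted truth
#'
#' Computes sensitivity and precision of DEG calls per contrast and overall
#' (truth: planted |log2fc| > 1), the realized false discovery proportion,
#' recovery of both memory classes, detection of planted enriched GO terms
#' in the target contrast, and sensitivity/precision of QTL candidate
#' DE-anywhere flags against planted interval truth.
#'
#' @param bundle a [run_pipeline()] result.
#' @param study the [generate_study()] result it was run on.
#' @return data.frame with columns `metric`, `value`, `n`.
#' @export
score_against_truth <- function(bundle, study) {
  truth <- study$truth
  if (!all(rownames(truth$l2fc) %in% study$cm$gene_ids))
    stop("truth/bundle gene-id mismatch", call. = FALSE)
  metrics <- list()
  add <- function(name, value, n)
    metrics[[length(metrics) + 1L]] <<- data.frame(
      metric = name, value = value, n = n, stringsAsFactors = FALSE)

  tp <- 0; fp <- 0; fn <- 0
  for (key in names(bundle$deg_tables)) {
    if (!key %in% colnames(truth$l2fc)) next
    t <- bundle$deg_tables[[key]]
    called <- t$gene_id[t$significant]
    true_de <- rownames(truth$l2fc)[abs(truth$l2fc[, key]) > 1]
    tp <- tp + length(intersect(called, true_de))
    fp <- fp + length(setdiff(called, true_de))
    fn <- fn + length(setdiff(true_de, called))
  }
  add("deg_sensitivity", if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      tp + fn)
  add("deg_fdp", if (tp + fp > 0) fp / (tp + fp) else NA_real_, tp + fp)

  for (cls in c("opposite", "t1t2_unique")) {
    called <- unlist(lapply(names(bundle$memory), function(k)
      paste(sub("\\.", "_", k),
            bundle$memory[[k]][[cls]]$genes$gene_id, sep = ":")))
    tm <- truth$memory[truth$memory$class == cls, ]
    truth_keys <- paste(paste(tm$tissue, tm$stress, sep = "_"), tm$gene_id,
                        sep = ":")
    s <- if (length(truth_keys))
      length(intersect(called, truth_keys)) / length(truth_keys) else
        NA_real_
    p <- if (length(called))
      length(intersect(called, truth_keys)) / length(called) else NA_real_
    add(paste0("memory_", cls, "_sensitivity"), s, length(truth_keys))
    add(paste0("memory_", cls, "_precision"), p, length(called))
  }

  target <- study$cfg$enriched_target
  planted <- study$annotations$enriched_terms
  e <- bundle$enrichment_go[[target]]
  det <- if (is.null(e)) NA_real_ else
    mean(planted %in% e$term_id[e$significant])
  add("enriched_term_detection", det, length(planted))

  qtl_tp <- 0; qtl_fp <- 0; qtl_fn <- 0
  keys <- intersect(names(bundle$deg_tables), colnames(truth$l2fc))
  true_any <- rownames(truth$l2fc)[
    rowSums(abs(truth$l2fc[, keys, drop = FALSE]) > 1) > 0]
  for (lab in names(bundle$qtl)) {
    cand <- bundle$qtl[[lab]]
    flagged <- cand$gene_id[cand$de_anywhere]
    truth_genes <- intersect(study$genome$qtl_truth[[lab]], true_any)
    qtl_tp <- qtl_tp + length(intersect(flagged, truth_genes))
    qtl_fp <- qtl_fp + length(setdiff(flagged, truth_genes))
    qtl_fn <- qtl_fn + length(setdiff(truth_genes, flagged))
  }
  add("qtl_flag_sensitivity",
      if (qtl_tp + qtl_fn > 0) qtl_tp / (qtl_tp + qtl_fn) else NA_real_,
      qtl_tp + qtl_fn)
  add("qtl_flag_precision",
      if (qtl_tp + qtl_fp > 0) qtl_tp / (qtl_tp + qtl_fp) else NA_real_,
      qtl_tp + qtl_fp)

  out <- do.call(rbind, metrics)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster labellings, delegated to
#' mclust's implementation.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' Write the report bundle as TSV files
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  wt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  write_deg_table(bundle$deg_tables, fp("deg_tables.tsv"))
  wt(bundle$deg_counts, "deg_counts.tsv")
  wt(do.call(rbind, lapply(bundle$enrichment_go, as.data.frame)),
     "enrichment_go.tsv")
  wt(do.call(rbind, lapply(bundle$enrichment_tff, as.data.frame)),
     "enrichment_tff.tsv")
  for (ti in names(bundle$go_profiles)) {
    gp <- bundle$go_profiles[[ti]]
    wt(data.frame(term_id = rownames(gp$matrix), gp$matrix,
                  cluster = gp$clusters[rownames(gp$matrix)],
                  check.names = FALSE),
       paste0("go_profiles_", ti, ".tsv"))
    wt(gp$annotation, paste0("go_cluster_annotation_", ti, ".tsv"))
  }
  tfc <- do.call(rbind, bundle$tf_clusters)
  if (!is.null(tfc)) wt(tfc, "tf_by_cluster.tsv")
  write_memory_genes(unlist(lapply(bundle$memory, unname),
                            recursive = FALSE),
                     fp("memory_genes.tsv"))
  ov <- do.call(rbind, bundle$memory_overlap)
  if (!is.null(ov))
    wt(data.frame(set = names(bundle$memory_overlap), ov), "memory_overlap.tsv")
  wt(bundle$qtl_intervals, "qtl_intervals.tsv")
  wt(do.call(rbind, bundle$qtl), "qtl_candidates.tsv")
  invisible(dir)
}
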