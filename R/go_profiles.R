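#' GO-percentage profile matrix
#'
#' For each significant GO term of a tissue and each (stress, timepoint,
#' direction) column, the cell holds 100 times the number of significant
#' DEGs of that direction annotated to the term, divided by the term's
#' genome-wide gene count. Percentages give small and large terms equal
#' visual weight. Terms with no DEGs in a column get 0.
#'
#' @param sig_terms character vector of term ids (the union of significant
#'   terms across the tissue's contrasts).
#' @param deg_tables named list of `DEGTable`s for the tissue.
#' @param ann the GO [annotation_map()].
#' @return numeric matrix, rows = terms, columns =
#'   `stress.timepoint.direction` (direction `up`/`down`), values in
#'   [0, 100].
#' @export
go_profile_matrix <- function(sig_terms, deg_tables, ann) {
  K <- lengths(ann$term_to_genes)[sig_terms]
  if (any(is.na(K)) || any(K == 0))
    stop("term with no genome genes in the annotation map", call. = FALSE)
  cols <- unlist(lapply(deg_tables, function(t)
    paste(t$stress[1], t$timepoint[1], c("up", "down"), sep = ".")))
  mat <- matrix(0, nrow = length(sig_terms), ncol = length(cols),
                dimnames = list(sig_terms, cols))
  for (t in deg_tables) {
    for (dirn in c("up", "down")) {
      genes <- t$gene_id[t$significant & t$direction == dirn]
      col <- paste(t$stress[1], t$timepoint[1], dirn, sep = ".")
      mat[, col] <- 100 * vapply(sig_terms, function(tid)
        sum(ann$term_to_genes[[tid]] %in% genes), numeric(1)) / K
    }
  }
  mat
}

#' Cluster GO-percentage profiles
#'
#' Rows are standardized to Z-scores and clustered agglomeratively
#' (Euclidean distance, average linkage), cutting the tree at `k` clusters
#' with the same deterministic relabelling as [cluster_genes()].
#'
#' @param mat a [go_profile_matrix()] result.
#' @param k number of clusters (7 was used for leaves and 3 for roots in the
#'   original full-scale analysis).
#' @return integer cluster labels named by term id.
#' @export
cluster_profiles <- function(mat, k) {
  cluster_genes(zscore_rows(mat), k)
}

#' Annotate profile clusters by their most prevalent terms
#'
#' Each cluster is summarized by its `k_top` terms ranked by genome-wide
#' gene count (prevalence), ties broken lexicographically by term id;
#' clusters smaller than `k_top` return all their terms.
#'
#' @param clusters labels from [cluster_profiles()].
#' @param ann the GO [annotation_map()].
#' @param k_top terms per cluster (5 for leaves, 10 for roots in the
#'   original analysis).
#' @return data.frame with columns `cluster`, `term_id`, `term_name`, `K`,
#'   `rank`.
#' @export
annotate_clusters <- function(clusters, ann, k_top = 5) {
  out <- lapply(sort(unique(clusters)), function(cl) {
    terms <- names(clusters)[clusters == cl]
    K <- lengths(ann$term_to_genes)[terms]
    ord <- order(-K, terms)
    take <- head(ord, k_top)
    data.frame(cluster = cl, term_id = terms[take],
               term_name = if (is.null(ann$term_names)) NA_character_ else
                 unname(ann$term_names[terms[take]]),
               K = unname(K[take]), rank = seq_along(take),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Differentially expressed transcription factors by family and GO cluster
#'
#' A TF contributes to a (family, cluster, contrast) cell when it is
#' significant in that contrast and annotated to at least one GO term of the
#' cluster; a TF annotated to terms of several clusters is counted once per
#' cluster.
#'
#' @param deg_tables named list of `DEGTable`s.
#' @param tff_map the TFF [annotation_map()] (gene -> family).
#' @param clusters GO cluster labels from [cluster_profiles()].
#' @param ann the GO [annotation_map()].
#' @return data.frame with columns `tff`, `cluster`, `contrast`, `n_tf`.
#' @export
tf_by_cluster <- function(deg_tables, tff_map, clusters, ann) {
  term_cluster <- clusters
  rows <- list()
  for (key in names(deg_tables)) {
    t <- deg_tables[[key]]
    de <- t$gene_id[t$significant]
    tfs <- de[de %in% names(tff_map$gene_to_terms)]
    if (!length(tfs)) next
    for (g in tfs) {
      fam <- tff_map$gene_to_terms[[g]][1]
      terms <- intersect(ann$gene_to_terms[[g]], names(term_cluster))
      if (!length(terms)) next
      cls <- unique(term_cluster[terms])
      rows[[length(rows) + 1L]] <- data.frame(
        tff = fam, cluster = cls, contrast = key, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tff = character(), cluster = integer(),
                      contrast = character(), n_tf = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  agg <- aggregate(list(n_tf = rep(1L, nrow(df))),
                   by = df[, c("tff", "cluster", "contrast")], FUN = sum)
  agg[order(agg$contrast, agg$tff, agg$cluster), , drop = FALSE]
}
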