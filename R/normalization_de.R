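#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed by the median-of-ratios method: each
#' sample's factor is the median, over genes with a positive geometric mean
#' across samples, of that sample's count divided by the gene's geometric
#' mean. No post-hoc rescaling is applied, so the factors are
#' scale-equivariant: multiplying one sample's counts by c multiplies its
#' factor by c.
#'
#' @param cm a [count_matrix()] object or a bare counts matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  loggeo <- rowMeans(log(counts))          # -Inf where any count is 0
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene with positive counts in all samples", call. = FALSE)
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor", call. = FALSE)
  sf
}

# counts scaled to a common library: counts[, j] / sf[j]
normalized_counts <- function(cm, sf = NULL) {
  counts <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}

#' Replicate quality control by multidimensional scaling
#'
#' Projects samples into two dimensions by classical MDS of pairwise
#' Euclidean distances between log2 normalized expression profiles, then
#' flags a sample as an outlier when its distance to its condition's
#' replicate centroid exceeds `threshold` times the median such distance
#' across all samples. Conditions with fewer than two replicates are skipped
#' with a warning. Removing flagged samples and renormalizing is the
#' caller's responsibility.
#'
#' @param cm a [count_matrix()] object.
#' @param threshold outlier multiplier on the median centroid distance
#'   (default 3).
#' @return list of class `QCReport` with `coords` (samples x 2 MDS matrix),
#'   `centroid_dist`, `outlier` (logical per sample) and `removed`
#'   (flagged sample ids).
#' @export
replicate_qc <- function(cm, threshold = 3) {
  sf <- size_factors(cm)
  logn <- log2(normalized_counts(cm, sf) + 1)
  d <- dist(t(logn))
  k <- min(2, ncol(cm$counts) - 1)
  # degenerate configurations (e.g. identical replicates) yield fewer than
  # k positive eigenvalues; pad missing coordinates with zero
  coords <- suppressWarnings(cmdscale(d, k = k))
  while (ncol(coords) < 2) coords <- cbind(coords, 0)
  rownames(coords) <- cm$samples$sample_id
  cond <- condition_key(cm$samples)
  cd <- rep(NA_real_, nrow(coords))
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    if (length(idx) < 2) {
      warning("condition ", cc, " has <2 replicates; skipped in QC")
      next
    }
    centroid <- colMeans(coords[idx, , drop = FALSE])
    cd[idx] <- sqrt(colSums((t(coords[idx, , drop = FALSE]) - centroid)^2))
  }
  med <- median(cd, na.rm = TRUE)
  outlier <- !is.na(cd) & med > 0 & cd > threshold * med
  # removal must leave >= 2 replicates per condition; when more replicates
  # of one condition flag than can be removed, keep the least outlying ones
  # (a group-level shift is biology, not a replicate outlier)
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    excess <- sum(outlier[idx]) - (length(idx) - 2)
    if (excess > 0) {
      flagged <- idx[outlier[idx]]
      keep <- flagged[order(cd[flagged])][seq_len(excess)]
      outlier[keep] <- FALSE
    }
  }
  structure(list(coords = coords, centroid_dist = cd, outlier = outlier,
                 removed = cm$samples$sample_id[outlier]),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport:", nrow(x$coords), "samples,",
      sum(x$outlier), "flagged\n")
  if (length(x$removed)) cat("removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Method-of-moments negative-binomial dispersion
#'
#' For each gene, the raw dispersion is the within-condition
#' method-of-moments estimate `max(0, (v - m) / m^2)` of the NB dispersion
#' alpha (variance = mu + alpha * mu^2) on normalized counts, averaged over
#' conditions with at least two replicates and positive mean. The common
#' dispersion is the 10%-trimmed mean of the per-gene values; per-gene
#' estimates are shrunk toward it with weight `shrink` (default 0.5),
#' reflecting how unstable n = 3 per-gene moments are.
#'
#' @param cm a [count_matrix()] object.
#' @param sf size factors; computed when `NULL`.
#' @param shrink weight on the common dispersion in the shrunk estimate.
#' @return list of class `DispersionEstimate` with `per_gene` (raw), `common`
#'   and `shrunk` components.
#' @export
estimate_dispersion <- function(cm, sf = NULL, shrink = 0.5) {
  norm <- normalized_counts(cm, sf)
  if (all(norm == 0)) stop("all counts are zero", call. = FALSE)
  cond <- condition_key(cm$samples)
  reps <- table(cond)
  usable <- names(reps)[reps >= 2]
  if (!length(usable))
    stop("no condition with >= 2 replicates", call. = FALSE)
  alpha_sum <- numeric(nrow(norm))
  alpha_n <- numeric(nrow(norm))
  for (cc in usable) {
    sub <- norm[, cond == cc, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ok <- m > 0
    a <- pmax(0, (v[ok] - m[ok]) / m[ok]^2)
    alpha_sum[ok] <- alpha_sum[ok] + a
    alpha_n[ok] <- alpha_n[ok] + 1
  }
  per_gene <- ifelse(alpha_n > 0, alpha_sum / pmax(alpha_n, 1), NA_real_)
  common <- mean(per_gene[!is.na(per_gene)], trim = 0.1)
  shrunk <- ifelse(is.na(per_gene), common,
                   (1 - shrink) * per_gene + shrink * common)
  names(shrunk) <- names(per_gene) <- rownames(norm)
  structure(list(per_gene = per_gene, common = common, shrunk = shrunk),
            class = "DispersionEstimate")
}

#' Exact negative-binomial two-group test for one gene
#'
#' Counts in each group are scaled to a common effective library size (the
#' geometric mean of the size factors) and summed. Conditional on the total
#' t, the two-sided p-value is the sum of the probabilities of all splits
#' (a, t - a) whose conditional probability does not exceed that of the
#' observed split. The conditional law treats the group sums as independent
#' NB variables with sizes n1/alpha and n2/alpha and means proportional to
#' the group effective sizes; at alpha = 0 this reduces to the conditional
#' binomial of the Poisson two-sample exact test.
#'
#' @param y_treat,y_ctrl integer count vectors for the two groups.
#' @param sf_treat,sf_ctrl size factors for the corresponding samples
#'   (default 1).
#' @param alpha NB dispersion (variance = mu + alpha mu^2).
#' @return two-sided p-value in (0, 1]; 1 when the total is zero.
#' @export
exact_nb_test <- function(y_treat, y_ctrl, sf_treat = rep(1, length(y_treat)),
                          sf_ctrl = rep(1, length(y_ctrl)), alpha = 0) {
  if (!length(y_treat) || !length(y_ctrl))
    stop("both groups must be non-empty", call. = FALSE)
  ref <- exp(mean(log(c(sf_treat, sf_ctrl))))
  t1 <- round(sum(y_treat / sf_treat * ref))
  t2 <- round(sum(y_ctrl / sf_ctrl * ref))
  t <- t1 + t2
  if (t == 0) return(1)
  n1 <- length(y_treat); n2 <- length(y_ctrl)
  a <- 0:t
  if (alpha <= 0) {
    logp <- dbinom(a, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu1 <- t * n1 / (n1 + n2)
    mu2 <- t * n2 / (n1 + n2)
    logp <- dnbinom(a, size = n1 / alpha, mu = mu1, log = TRUE) +
      dnbinom(t - a, size = n2 / alpha, mu = mu2, log = TRUE)
    logp <- logp - max(logp)
  }
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[t1 + 1]
  min(1, sum(p[p <= obs * (1 + 1e-8)]))
}

#' Resolve a contrast to treatment / control column indices
#'
#' @param cm a [count_matrix()] object.
#' @param tissue,stress,timepoint contrast labels (stress != "control").
#' @param control_timepoint timepoint of the reference control group;
#'   defaults to `timepoint`, except `"T1T2"` which references the `"T2"`
#'   control (same plant age as the repeated-stress harvest).
#' @return list with integer vectors `treat` and `ctrl`.
#' @export
contrast_spec <- function(cm, tissue, stress, timepoint,
                          control_timepoint = NULL) {
  stopifnot(stress %in% c("Fe", "Pi"))
  if (is.null(control_timepoint))
    control_timepoint <- if (timepoint == "T1T2") "T2" else timepoint
  s <- cm$samples
  treat <- which(s$tissue == tissue & s$stress == stress &
                 s$timepoint == timepoint)
  ctrl <- which(s$tissue == tissue & s$stress == "control" &
                s$timepoint == control_timepoint)
  if (!length(ctrl))
    stop("missing control group (", tissue, ", ", control_timepoint, ")",
         call. = FALSE)
  if (!length(treat))
    stop("missing treatment group (", tissue, ", ", stress, ", ", timepoint,
         ")", call. = FALSE)
  list(treat = treat, ctrl = ctrl,
       tissue = tissue, stress = stress, timepoint = timepoint,
       control_timepoint = control_timepoint)
}

#' Call differentially expressed genes for one contrast
#'
#' Genes whose normalized mean is below `min_mean` in both groups are
#' excluded from testing. For the rest, log2 fold change is computed on
#' normalized group means with pseudo-count `pseudo_count`, the p-value from
#' [exact_nb_test()] at the gene's shrunk dispersion, and the FDR by
#' Benjamini-Hochberg across tested genes. A gene is significant when
#' |log2fc| > log2(`fc_threshold`), p < `p_threshold` and
#' fdr < `fdr_threshold`.
#'
#' @param cm a [count_matrix()] object.
#' @param contrast a [contrast_spec()] result.
#' @param sf size factors (computed when `NULL`).
#' @param dispersion a [estimate_dispersion()] result (computed when `NULL`).
#' @param fc_threshold,p_threshold,fdr_threshold significance cutoffs
#'   (defaults 2, 0.05, 0.05).
#' @param pseudo_count added to normalized group means before the log ratio
#'   (default 0.5).
#' @param min_mean low-count filter on normalized group means (default 1).
#' @return a [deg_table()] for the tested genes.
#' @export
call_degs <- function(cm, contrast, sf = NULL, dispersion = NULL,
                      fc_threshold = 2, p_threshold = 0.05,
                      fdr_threshold = 0.05, pseudo_count = 0.5,
                      min_mean = 1) {
  if (is.null(sf)) sf <- size_factors(cm)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(cm, sf)
  norm <- normalized_counts(cm, sf)
  ti <- contrast$treat; ci <- contrast$ctrl
  m_t <- rowMeans(norm[, ti, drop = FALSE])
  m_c <- rowMeans(norm[, ci, drop = FALSE])
  keep <- m_t >= min_mean | m_c >= min_mean
  genes <- cm$gene_ids[keep]
  l2fc <- log2((m_t[keep] + pseudo_count) / (m_c[keep] + pseudo_count))
  alpha <- dispersion$shrunk[keep]
  cnt <- cm$counts
  pv <- vapply(seq_along(genes), function(i) {
    g <- which(keep)[i]
    exact_nb_test(cnt[g, ti], cnt[g, ci], sf[ti], sf[ci], alpha[i])
  }, numeric(1))
  fdr <- p.adjust(pv, method = "BH")
  deg_table(genes, l2fc, pv, fdr,
            tissue = contrast$tissue, stress = contrast$stress,
            timepoint = contrast$timepoint,
            fc_threshold = fc_threshold, p_threshold = p_threshold,
            fdr_threshold = fdr_threshold)
}

#' Call DEGs for every stress x timepoint contrast of a tissue
#'
#' @param cm a [count_matrix()] object.
#' @param tissue tissue to analyse.
#' @param stresses,timepoints contrasts to run (defaults: Fe and Pi at all
#'   four timepoints).
#' @param ... passed to [call_degs()].
#' @return named list of `DEGTable`s, names `tissue.stress.timepoint`.
#' @export
call_all_degs <- function(cm, tissue, stresses = c("Fe", "Pi"),
                          timepoints = TIMEPOINTS, ...) {
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  out <- list()
  for (st in stresses) for (tp in timepoints) {
    cs <- contrast_spec(cm, tissue, st, tp)
    out[[paste(tissue, st, tp, sep = ".")]] <-
      call_degs(cm, cs, sf = sf, dispersion = disp, ...)
  }
  out
}

#' Row-wise Z-score matrix of per-contrast log2 fold changes
#'
#' Builds the gene x contrast log2fc matrix over the union of significant
#' genes across the supplied tables and standardizes each row to mean 0 and
#' sd 1; constant rows map to all-zero.
#'
#' @param tables named list of `DEGTable`s for one tissue (one column per
#'   table, in list order).
#' @param union_genes optional gene set for the rows; defaults to the union
#'   of significant genes across tables.
#' @return numeric matrix of Z-scores, rows = genes, columns = contrasts.
#' @export
zscore_matrix <- function(tables, union_genes = NULL) {
  if (is.null(union_genes))
    union_genes <- unique(unlist(lapply(tables, function(t)
      t$gene_id[t$significant])))
  fc <- sapply(tables, function(t) {
    v <- setNames(t$log2fc, t$gene_id)[union_genes]
    ifelse(is.na(v), 0, v)
  })
  fc <- matrix(fc, nrow = length(union_genes),
               dimnames = list(union_genes, names(tables)))
  zscore_rows(fc)
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Hierarchical clustering of Z-score profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' rows, cut at `k` clusters. Cluster labels are renumbered deterministically
#' by the cluster mean of the first column, ties broken by decreasing
#' cluster size, so the labelling is stable under row permutation.
#'
#' @param zmat numeric matrix, rows = genes (or terms).
#' @param k number of clusters (1 <= k <= nrow).
#' @return integer vector of cluster labels in 1..k, named by rownames.
#' @export
cluster_genes <- function(zmat, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(zmat))
    stop("k exceeds the number of rows", call. = FALSE)
  if (k == 1)
    return(setNames(rep(1L, nrow(zmat)), rownames(zmat)))
  hc <- hclust(dist(zmat), method = "average")
  raw <- cutree(hc, k = k)
  renumber_clusters(raw, zmat)
}

# stable relabelling: order clusters by mean of first column, then by size
renumber_clusters <- function(labels, mat) {
  m1 <- tapply(mat[, 1], labels, mean)
  sz <- table(labels)
  ord <- order(m1, -as.numeric(sz[names(m1)]))
  map <- setNames(seq_along(ord), names(m1)[ord])
  out <- map[as.character(labels)]
  names(out) <- rownames(mat)
  out
}
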