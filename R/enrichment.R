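#' One-sided hypergeometric overrepresentation p-value
#'
#' Probability of drawing at least `a` term members when `n` genes are drawn
#' without replacement from a background of `N` genes of which `K` belong to
#' the term: `P(X >= a)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' one-sided Fisher's exact test for overrepresentation.
#'
#' @param a observed term members in the gene set.
#' @param K term members in the background.
#' @param n size of the gene set.
#' @param N background (universe) size.
#' @return upper-tail p-value in (0, 1].
#' @export
fisher_overrep <- function(a, K, n, N) {
  if (any(a < 0) || any(K > N) || any(n > N) || any(a > pmin(K, n)))
    stop("inconsistent hypergeometric margins", call. = FALSE)
  phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p_raw vector of raw p-values.
#' @param m number of tests (>= length of `p_raw`).
#' @return p-values multiplied by `m` and capped at 1.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < length(p_raw)) stop("m smaller than the number of p-values",
                              call. = FALSE)
  pmin(1, p_raw * m)
}

#' Term overrepresentation in a DEG set
#'
#' Tests every annotation term with at least one member in the gene set for
#' overrepresentation relative to the annotation universe, using the
#' one-sided Fisher's exact test with Bonferroni correction. Genes absent
#' from the annotation universe are dropped (their count is recorded in the
#' result attributes). The Bonferroni divisor m is by default the number of
#' testable terms (those with a >= 1); set `m_all_terms = TRUE` to divide by
#' the full term count of the namespace instead.
#'
#' @param deg_set character vector of gene ids.
#' @param ann an [annotation_map()].
#' @param alpha significance level on the corrected p-value (default 0.05).
#' @param universe_size background size N; defaults to the annotation map's
#'   `genome_size` (distinct annotated genes).
#' @param m_all_terms use all namespace terms as the Bonferroni divisor.
#' @param contrast optional contrast label carried through to the result.
#' @return data.frame of class `EnrichmentResult` with columns `term_id`,
#'   `term_name`, `a`, `K`, `n`, `N`, `p_raw`, `p_corrected`, `significant`,
#'   sorted by `p_corrected`; attributes `m` and `n_unannotated`.
#' @export
enrich_terms <- function(deg_set, ann, alpha = 0.05, universe_size = NULL,
                         m_all_terms = FALSE, contrast = NA_character_) {
  deg_set <- unique(deg_set)
  annotated <- names(ann$gene_to_terms)
  in_univ <- deg_set[deg_set %in% annotated]
  n_unannotated <- length(deg_set) - length(in_univ)
  N <- universe_size %||% ann$genome_size
  empty <- data.frame(term_id = character(), term_name = character(),
                      a = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(),
                      p_corrected = numeric(), significant = logical(),
                      contrast = character(), stringsAsFactors = FALSE)
  if (!length(in_univ)) {
    warning("empty DEG set after intersecting with the annotation universe")
    attr(empty, "m") <- 0L
    attr(empty, "n_unannotated") <- n_unannotated
    class(empty) <- c("EnrichmentResult", "data.frame")
    return(empty)
  }
  a <- vapply(ann$term_to_genes, function(g) sum(g %in% in_univ), integer(1))
  testable <- a >= 1
  m <- if (m_all_terms) length(ann$term_to_genes) else sum(testable)
  K <- lengths(ann$term_to_genes)[testable]
  a <- a[testable]
  n <- length(in_univ)
  p_raw <- fisher_overrep(a, K, n, N)
  p_corr <- bonferroni(p_raw, m)
  res <- data.frame(
    term_id = names(ann$term_to_genes)[testable],
    term_name = if (is.null(ann$term_names)) NA_character_ else
      unname(ann$term_names[names(ann$term_to_genes)[testable]]),
    a = unname(a), K = unname(K), n = n, N = N,
    p_raw = unname(p_raw), p_corrected = unname(p_corr),
    significant = unname(p_corr < alpha),
    contrast = contrast, stringsAsFactors = FALSE)
  res <- res[order(res$p_corrected, res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "n_unannotated") <- n_unannotated
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Collapse significant GO terms with identical DEG gene lists
#'
#' Terms whose intersections with the DEG set are identical are merged into
#' a single representative: the term with the largest genome annotation set
#' (the most general term available without an ontology graph), ties broken
#' by lexicographic term id. Merged member ids are recorded in a
#' `members_merged` column; the union of DEG genes covered is unchanged.
#'
#' @param res an [enrich_terms()] result.
#' @param ann the [annotation_map()] used for the enrichment.
#' @param deg_set the gene set that was tested.
#' @return the significant rows of `res`, one per merged group, with a
#'   `members_merged` column (comma-separated absorbed term ids, `""` when
#'   none).
#' @export
collapse_go <- function(res, ann, deg_set) {
  sig <- res[res$significant, , drop = FALSE]
  if (!nrow(sig)) {
    sig$members_merged <- character(0)
    return(sig)
  }
  deg_set <- unique(deg_set)
  key <- vapply(sig$term_id, function(tid)
    paste(sort(intersect(ann$term_to_genes[[tid]], deg_set)),
          collapse = "|"), character(1))
  out <- lapply(split(seq_len(nrow(sig)), key), function(idx) {
    grp <- sig[idx, , drop = FALSE]
    grp <- grp[order(-grp$K, grp$term_id), , drop = FALSE]
    rep_row <- grp[1, , drop = FALSE]
    rep_row$members_merged <- paste(grp$term_id[-1], collapse = ",")
    rep_row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p_corrected, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
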