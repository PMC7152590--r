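#' Opposite-direction stress-memory genes
#'
#' Genes significant after both a repeated stress (T1T2) and a late single
#' stress (T2) of the same tissue and stress, but with opposite directions
#' of expression — evidence that the earlier exposure reversed the response
#' to the second one.
#'
#' @param deg_t1t2,deg_t2 `DEGTable`s for the T1T2 and T2 contrasts of the
#'   same tissue and stress.
#' @return list of class `MemoryGeneSet` with `class = "opposite"`,
#'   `tissue`, `stress` and a `genes` data.frame (`gene_id`, `log2fc_T1T2`,
#'   `log2fc_T2`).
#' @export
opposite_memory_genes <- function(deg_t1t2, deg_t2) {
  check_same_contrast_pair(deg_t1t2, deg_t2)
  s1 <- deg_t1t2[deg_t1t2$significant, c("gene_id", "log2fc")]
  s2 <- deg_t2[deg_t2$significant, c("gene_id", "log2fc")]
  both <- merge(s1, s2, by = "gene_id", suffixes = c("_T1T2", "_T2"))
  opp <- both[sign(both$log2fc_T1T2) != sign(both$log2fc_T2), , drop = FALSE]
  opp <- opp[order(opp$gene_id), , drop = FALSE]
  rownames(opp) <- NULL
  structure(list(class = "opposite",
                 tissue = deg_t1t2$tissue[1], stress = deg_t1t2$stress[1],
                 genes = opp),
            class = "MemoryGeneSet")
}

check_same_contrast_pair <- function(a, b) {
  if (!identical(a$tissue[1], b$tissue[1]) ||
      !identical(a$stress[1], b$stress[1]))
    stop("DEG tables must come from the same tissue and stress",
         call. = FALSE)
  if (!identical(a$timepoint[1], "T1T2") || !identical(b$timepoint[1], "T2"))
    stop("expected DEG tables for timepoints T1T2 and T2", call. = FALSE)
}

#' Repeated-stress-unique (T1T2-only) memory genes
#'
#' Genes significant at the repeated stress timepoint T1T2 and at no other
#' timepoint of the same stress and tissue — differential expression that
#' requires a prior stress exposure. With `mode = "t1_only"` only the first
#' exposure (T1) is required non-significant, the looser reading of
#' "not differentially expressed in response to an initial stress exposure".
#'
#' @param deg_tables named list holding the `DEGTable`s for timepoints T1,
#'   T1Rec, T1T2 and T2 of one tissue and stress.
#' @param mode `"all_other"` (default: non-significant at T1, T1Rec and T2)
#'   or `"t1_only"`.
#' @return list of class `MemoryGeneSet` with `class = "t1t2_unique"` and a
#'   `genes` data.frame (`gene_id`, `log2fc_T1T2`).
#' @export
t1t2_unique_genes <- function(deg_tables, mode = c("all_other", "t1_only")) {
  mode <- match.arg(mode)
  tps <- vapply(deg_tables, function(t) t$timepoint[1], character(1))
  names(deg_tables) <- tps
  need <- c("T1", "T1Rec", "T1T2", "T2")
  if (!all(need %in% tps))
    stop("missing contrast(s): ", paste(setdiff(need, tps), collapse = ", "),
         call. = FALSE)
  lab <- unique(t(vapply(deg_tables, function(t)
    c(t$tissue[1], t$stress[1]), character(2))))
  if (nrow(lab) != 1)
    stop("DEG tables must come from the same tissue and stress",
         call. = FALSE)
  sig_at <- function(tp) deg_tables[[tp]]$gene_id[deg_tables[[tp]]$significant]
  others <- if (mode == "all_other") c("T1", "T1Rec", "T2") else "T1"
  uniq <- setdiff(sig_at("T1T2"), unique(unlist(lapply(others, sig_at))))
  t1t2 <- deg_tables[["T1T2"]]
  genes <- data.frame(
    gene_id = sort(uniq),
    log2fc_T1T2 = setNames(t1t2$log2fc, t1t2$gene_id)[sort(uniq)],
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(class = "t1t2_unique",
                 tissue = lab[1, 1], stress = lab[1, 2], genes = genes),
            class = "MemoryGeneSet")
}

#' @export
print.MemoryGeneSet <- function(x, ...) {
  cat("MemoryGeneSet [", x$class, "] ", x$tissue, "/", x$stress, ": ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Cross-stress overlap of two memory gene sets
#'
#' @param set_fe,set_pi `MemoryGeneSet`s of the same tissue and class for
#'   the two stresses.
#' @return named integer vector `(n_fe_only, n_pi_only, n_common)`.
#' @export
cross_stress_overlap <- function(set_fe, set_pi) {
  if (!identical(set_fe$class, set_pi$class))
    stop("memory class mismatch", call. = FALSE)
  if (!identical(set_fe$tissue, set_pi$tissue))
    stop("tissue mismatch", call. = FALSE)
  a <- set_fe$genes$gene_id
  b <- set_pi$genes$gene_id
  c(n_fe_only = length(setdiff(a, b)),
    n_pi_only = length(setdiff(b, a)),
    n_common = length(intersect(a, b)))
}

#' Classify both memory gene classes for one tissue and stress
#'
#' Convenience wrapper producing the opposite and T1T2-unique classes from
#' the four timepoint contrasts; the two classes are disjoint by
#' construction (the opposite class requires significance at T2, which the
#' unique class forbids) and this is asserted on every run.
#'
#' @param deg_tables named list of the four timepoint `DEGTable`s for one
#'   tissue and stress.
#' @param mode passed to [t1t2_unique_genes()].
#' @return list with elements `opposite` and `t1t2_unique`.
#' @export
memory_genes <- function(deg_tables, mode = "all_other") {
  tps <- vapply(deg_tables, function(t) t$timepoint[1], character(1))
  names(deg_tables) <- tps
  opp <- opposite_memory_genes(deg_tables[["T1T2"]], deg_tables[["T2"]])
  uni <- t1t2_unique_genes(deg_tables, mode = mode)
  stopifnot(length(intersect(opp$genes$gene_id, uni$genes$gene_id)) == 0)
  list(opposite = opp, t1t2_unique = uni)
}

#' Write memory gene sets as TSV
#' @param sets list of `MemoryGeneSet`s.
#' @param path output TSV path.
#' @export
write_memory_genes <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    g <- s$genes
    if (!nrow(g))
      return(NULL)
    g$class <- s$class; g$tissue <- s$tissue; g$stress <- s$stress
    if (!"log2fc_T2" %in% names(g)) g$log2fc_T2 <- NA_real_
    g[, c("gene_id", "class", "tissue", "stress", "log2fc_T1T2", "log2fc_T2")]
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df))
    df <- data.frame(gene_id = character(), class = character(),
                     tissue = character(), stress = character(),
                     log2fc_T1T2 = numeric(), log2fc_T2 = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
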