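#' @importFrom stats median var dist cmdscale hclust cutree p.adjust phyper
#'   dnbinom dbinom rnorm rnbinom runif rbinom sd setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

TISSUES    <- c("leaf", "root")
STRESSES   <- c("control", "Fe", "Pi")
TIMEPOINTS <- c("T1", "T1Rec", "T1T2", "T2")

#' Construct a count matrix with sample metadata
#'
#' The raw-input container of the pipeline: a gene x sample matrix of
#' non-negative integer counts together with a sample sheet describing each
#' column's tissue, stress, timepoint and replicate index.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers.
#' @param samples data.frame with columns `sample_id`, `tissue`, `stress`,
#'   `timepoint`, `replicate`, one row per column of `counts`, in column
#'   order.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `samples` and `gene_ids`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  req <- c("sample_id", "tissue", "stress", "timepoint", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples)[, req]
  if (nrow(samples) != ncol(counts))
    stop("sample sheet rows must match count columns", call. = FALSE)
  if (!all(samples$sample_id == colnames(counts)))
    stop("sample sheet order must match count matrix columns", call. = FALSE)
  if (!all(samples$tissue %in% TISSUES))
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "),
         call. = FALSE)
  if (!all(samples$stress %in% STRESSES))
    stop("stress must be one of: ", paste(STRESSES, collapse = ", "),
         call. = FALSE)
  if (!all(samples$timepoint %in% TIMEPOINTS))
    stop("timepoint must be one of: ", paste(TIMEPOINTS, collapse = ", "),
         call. = FALSE)
  key <- with(samples, paste(tissue, stress, timepoint, replicate))
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate) in sample sheet", call. = FALSE)
  structure(list(counts = counts, samples = samples,
                 gene_ids = rownames(counts)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("conditions:",
      length(unique(condition_key(x$samples))), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

# (tissue, stress, timepoint) label shared by replicates
condition_key <- function(samples) {
  paste(samples$tissue, samples$stress, samples$timepoint, sep = ".")
}

#' Read a count matrix and its sample sheet from TSV
#'
#' The counts file has a `gene_id` first column and one column per sample;
#' the sample sheet has columns `sample_id`, `tissue`, `stress`, `timepoint`,
#' `replicate` and is the single source of condition metadata. Count columns
#' are reordered to sample-sheet order.
#'
#' @param path counts TSV path.
#' @param meta_path sample sheet TSV path.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path, meta_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "gene_id")
    stop("first column of counts file must be gene_id", call. = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  cnt <- raw[, -1, drop = FALSE]
  num <- vapply(cnt, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric count column(s): ",
         paste(names(cnt)[!num], collapse = ", "), call. = FALSE)
  cnt <- as.matrix(cnt)
  if (any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  missing <- setdiff(colnames(cnt), meta$sample_id)
  if (length(missing))
    stop("samples in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- meta[meta$sample_id %in% colnames(cnt), , drop = FALSE]
  cnt <- cnt[, meta$sample_id, drop = FALSE]
  rownames(cnt) <- raw$gene_id
  count_matrix(cnt, meta)
}

#' Write a count matrix and sample sheet as TSV
#'
#' @param cm a [count_matrix()] object.
#' @param path counts TSV path to write.
#' @param meta_path sample sheet TSV path to write.
#' @export
write_counts <- function(cm, path, meta_path) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(cm)
}

#' Build an annotation map from a gene-to-term table
#'
#' @param tab data.frame with columns `gene_id`, `term_id` and optionally
#'   `term_name`; duplicate rows are collapsed.
#' @param namespace `"GO"` or `"TFF"`. Under `"TFF"` a gene may belong to at
#'   most one family.
#' @return An `AnnotationMap`: list with `term_to_genes`, `gene_to_terms`,
#'   `term_names`, `namespace` and `genome_size` (number of distinct genes in
#'   the table, the default enrichment background).
#' @export
annotation_map <- function(tab, namespace = c("GO", "TFF")) {
  namespace <- match.arg(namespace)
  if (nrow(tab) == 0) stop("empty annotation table", call. = FALSE)
  tab <- unique(tab[, intersect(c("gene_id", "term_id", "term_name"),
                                names(tab)), drop = FALSE])
  if (namespace == "TFF") {
    nfam <- tapply(tab$term_id, tab$gene_id, function(x) length(unique(x)))
    bad <- names(nfam)[nfam > 1]
    if (length(bad))
      stop("gene(s) assigned to more than one TF family: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  term_to_genes <- split(tab$gene_id, tab$term_id)
  term_to_genes <- lapply(term_to_genes, unique)
  gene_to_terms <- split(tab$term_id, tab$gene_id)
  gene_to_terms <- lapply(gene_to_terms, unique)
  term_names <- NULL
  if ("term_name" %in% names(tab)) {
    nm <- unique(tab[, c("term_id", "term_name")])
    term_names <- setNames(nm$term_name, nm$term_id)
  }
  structure(list(term_to_genes = term_to_genes,
                 gene_to_terms = gene_to_terms,
                 term_names = term_names,
                 namespace = namespace,
                 genome_size = length(unique(tab$gene_id))),
            class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat("AnnotationMap [", x$namespace, "]: ",
      length(x$term_to_genes), " terms, ",
      x$genome_size, " genes\n", sep = "")
  invisible(x)
}

#' Read a gene-to-term annotation TSV
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param namespace `"GO"` or `"TFF"`.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, namespace = c("GO", "TFF")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  annotation_map(tab, namespace)
}

#' Write an annotation map as TSV
#'
#' @param ann an [annotation_map()].
#' @param path output TSV path.
#' @export
write_annotations <- function(ann, path) {
  tab <- data.frame(
    gene_id = unlist(ann$term_to_genes, use.names = FALSE),
    term_id = rep(names(ann$term_to_genes),
                  lengths(ann$term_to_genes)),
    stringsAsFactors = FALSE)
  if (!is.null(ann$term_names))
    tab$term_name <- unname(ann$term_names[tab$term_id])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Read gene positions from GFF3 or a 4-column TSV
#'
#' GFF3 input is parsed with rtracklayer and restricted to features of type
#' `gene` (coordinates 1-based inclusive). TSV input needs columns
#' `gene_id`, `chromosome`, `start`, `end` and optionally `strand`.
#'
#' @param path file path; format detected from the `.gff`/`.gff3` extension.
#' @return data.frame of gene spans sorted by (chromosome, start) with
#'   columns `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gene_positions <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0) {
      warning("no features of type 'gene' in ", path)
      return(data.frame(gene_id = character(), chromosome = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    spans <- data.frame(
      gene_id = as.character(ids),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    spans <- read.delim(path, stringsAsFactors = FALSE)
    if (!"strand" %in% names(spans)) spans$strand <- "*"
    spans <- spans[, c("gene_id", "chromosome", "start", "end", "strand")]
  }
  if (any(spans$start > spans$end))
    stop("gene span with start > end", call. = FALSE)
  if (any(spans$start < 1))
    stop("gene coordinates must be 1-based (start >= 1)", call. = FALSE)
  spans <- spans[order(spans$chromosome, spans$start), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Write gene spans to GFF3
#'
#' @param spans data.frame as returned by [read_gene_positions()].
#' @param path output GFF3 path.
#' @export
write_gene_positions <- function(spans, path) {
  strand <- ifelse(spans$strand %in% c("+", "-"), spans$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = spans$chromosome,
    ranges = IRanges::IRanges(spans$start, spans$end),
    strand = strand)
  gr$type <- "gene"
  gr$ID <- spans$gene_id
  gr$source <- "stressmem"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(spans)
}

#' Construct a per-contrast differential-expression table
#'
#' A DEG table holds one row per tested gene for a single contrast
#' (stress vs same-timepoint control, within tissue). A gene is significant
#' when the fold change exceeds 2 (|log2fc| > 1), the raw p-value is below
#' 0.05 and the BH-adjusted p-value (FDR) is below 0.05.
#'
#' @param gene_id,log2fc,pvalue,fdr vectors of equal length.
#' @param tissue,stress,timepoint scalar contrast labels.
#' @param fc_threshold fold-change cutoff on the linear scale (default 2).
#' @param p_threshold,fdr_threshold significance cutoffs (default 0.05).
#' @return data.frame of class `DEGTable` with columns `gene_id`, `log2fc`,
#'   `pvalue`, `fdr`, `direction`, `significant`, `tissue`, `stress`,
#'   `timepoint`.
#' @export
deg_table <- function(gene_id, log2fc, pvalue, fdr, tissue, stress,
                      timepoint, fc_threshold = 2, p_threshold = 0.05,
                      fdr_threshold = 0.05) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene within one contrast table", call. = FALSE)
  stopifnot(all(pvalue >= 0 & pvalue <= 1), all(fdr >= 0 & fdr <= 1))
  df <- data.frame(
    gene_id = as.character(gene_id),
    log2fc = log2fc, pvalue = pvalue, fdr = fdr,
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = abs(log2fc) > log2(fc_threshold) &
      pvalue < p_threshold & fdr < fdr_threshold,
    tissue = tissue, stress = stress, timepoint = timepoint,
    stringsAsFactors = FALSE)
  class(df) <- c("DEGTable", "data.frame")
  df
}

DEG_COLUMNS <- c("gene_id", "log2fc", "pvalue", "fdr", "direction",
                 "significant", "tissue", "stress", "timepoint")

#' Write a DEG table (or list of them) as TSV
#' @param tables a `DEGTable` or list of `DEGTable`s (rows are concatenated).
#' @param path output TSV path.
#' @export
write_deg_table <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)[DEG_COLUMNS]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read DEG tables from TSV, split back into one table per contrast
#' @param path TSV written by [write_deg_table()].
#' @return named list of `DEGTable`s, names `tissue.stress.timepoint`.
#' @export
read_deg_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(DEG_COLUMNS %in% names(df)))
  key <- paste(df$tissue, df$stress, df$timepoint, sep = ".")
  lapply(split(df, key), function(d) {
    rownames(d) <- NULL
    class(d) <- c("DEGTable", "data.frame")
    d
  })
}

#' Tally significant DEGs per contrast (Table-1 analogue)
#'
#' For each (tissue, stress, timepoint) contrast, counts significant down-
#' and upregulated genes and their total.
#'
#' @param tables list of `DEGTable`s.
#' @return data.frame with columns `tissue`, `stress`, `timepoint`, `down`,
#'   `up`, `total`, one row per contrast, ordered by (tissue, stress,
#'   timepoint).
#' @export
summarize_deg_counts <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  rows <- lapply(tables, function(t) {
    if (anyDuplicated(t$gene_id))
      stop("duplicate gene within one contrast table", call. = FALSE)
    sig <- t[t$significant, , drop = FALSE]
    data.frame(tissue = t$tissue[1] %||% NA_character_,
               stress = t$stress[1] %||% NA_character_,
               timepoint = t$timepoint[1] %||% NA_character_,
               down = sum(sig$direction == "down"),
               up = sum(sig$direction == "up"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$total <- out$down + out$up
  out <- out[order(out$tissue, out$stress,
                   match(out$timepoint, TIMEPOINTS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
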