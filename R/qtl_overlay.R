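#' Read SNP markers from TSV or BED
#'
#' TSV input needs columns `marker_id`, `chromosome`, `position` (1-based
#' bp) and `qtl`. BED input (0-based half-open) is converted to 1-based on
#' read; the BED name field carries `qtl|marker_id` (or just the marker id,
#' in which case the QTL label defaults to the marker prefix before the
#' first underscore).
#'
#' @param path marker file; format detected from the `.bed` extension.
#' @return data.frame with columns `marker_id`, `chromosome`, `position`,
#'   `qtl`.
#' @export
read_markers <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- as.character(gr$name)
    has_qtl <- grepl("|", nm, fixed = TRUE)
    qtl <- ifelse(has_qtl, sub("\\|.*$", "", nm), sub("_.*$", "", nm))
    mid <- ifelse(has_qtl, sub("^.*\\|", "", nm), nm)
    data.frame(marker_id = mid,
               chromosome = as.character(GenomicRanges::seqnames(gr)),
               position = GenomicRanges::start(gr),  # rtracklayer converts
               qtl = qtl, stringsAsFactors = FALSE)
  } else {
    m <- read.delim(path, stringsAsFactors = FALSE)
    m[, c("marker_id", "chromosome", "position", "qtl")]
  }
}

#' Write markers as BED (0-based half-open)
#' @param markers data.frame as from [read_markers()].
#' @param path output BED path.
#' @export
write_markers <- function(markers, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = markers$chromosome,
    ranges = IRanges::IRanges(markers$position, width = 1),
    name = paste(markers$qtl, markers$marker_id, sep = "|"))
  rtracklayer::export(gr, path, format = "bed")
  invisible(markers)
}

#' QTL interval spanned by a marker set
#'
#' The genomic region between a QTL's SNP markers: `[min position, max
#' position]` on their shared chromosome. Each QTL label needs at least two
#' markers (a single flanking marker defines no interval and is rejected)
#' on a single chromosome.
#'
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `position`, `qtl`; may hold several QTL labels.
#' @return data.frame with one row per QTL: `qtl`, `chromosome`, `start`,
#'   `end`.
#' @export
marker_interval <- function(markers) {
  out <- lapply(split(markers, markers$qtl), function(m) {
    if (length(unique(m$chromosome)) > 1)
      stop("markers of QTL ", m$qtl[1], " lie on multiple chromosomes",
           call. = FALSE)
    if (nrow(m) < 2)
      stop("QTL ", m$qtl[1], " has fewer than two markers", call. = FALSE)
    data.frame(qtl = m$qtl[1], chromosome = m$chromosome[1],
               start = min(m$position), end = max(m$position),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genes overlapping a QTL interval
#'
#' Returns the gene spans overlapping the interval by at least 1 bp (1-based
#' inclusive coordinates), sorted by start; with `strict = TRUE` only genes
#' fully contained in the interval are returned.
#'
#' @param spans gene spans from [read_gene_positions()].
#' @param interval one row of a [marker_interval()] result (or any list with
#'   `chromosome`, `start`, `end`).
#' @param strict require full containment instead of any overlap.
#' @return the overlapping rows of `spans`, sorted by start.
#' @export
genes_in_interval <- function(spans, interval, strict = FALSE) {
  g <- GenomicRanges::GRanges(spans$chromosome,
                              IRanges::IRanges(spans$start, spans$end))
  iv <- GenomicRanges::GRanges(interval$chromosome,
                               IRanges::IRanges(interval$start, interval$end))
  hits <- GenomicRanges::findOverlaps(
    g, iv, type = if (strict) "within" else "any")
  out <- spans[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlay DE status onto QTL interval genes
#'
#' Builds the candidate-gene table for an interval: one row per contained
#' gene with the significant log2 fold change per contrast (0 when the gene
#' is not a DEG in that contrast), the maximum absolute log2fc across
#' contrasts and a DE-anywhere flag; ranked by decreasing max |log2fc| so
#' the most differentially expressed candidate leads.
#'
#' @param genes gene spans from [genes_in_interval()] (or a character vector
#'   of gene ids).
#' @param deg_tables named list of `DEGTable`s.
#' @param qtl optional interval label carried into the output.
#' @return data.frame with columns `gene_id`, `qtl`, one `log2fc.<contrast>`
#'   column per table, `max_abs_log2fc`, `de_anywhere`.
#' @export
overlay_deg <- function(genes, deg_tables, qtl = NA_character_) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  out <- data.frame(gene_id = ids, qtl = qtl, stringsAsFactors = FALSE)
  for (key in names(deg_tables)) {
    t <- deg_tables[[key]]
    sig <- t[t$significant, , drop = FALSE]
    v <- setNames(sig$log2fc, sig$gene_id)[ids]
    out[[paste0("log2fc.", key)]] <- ifelse(is.na(v), 0, v)
  }
  fc_cols <- grep("^log2fc\\.", names(out))
  out$max_abs_log2fc <- if (length(fc_cols))
    apply(abs(as.matrix(out[, fc_cols, drop = FALSE])), 1, max) else 0
  out$de_anywhere <- out$max_abs_log2fc > 0
  out <- out[order(-out$max_abs_log2fc, match(out$gene_id, ids)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
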