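# shared fixture builders -- everything is generated in code

# minimal DEG table with given numbers of significant down/up genes plus
# optional non-significant filler rows
toy_deg_table <- function(n_down, n_up, n_ns = 0, tissue = "leaf",
                          stress = "Fe", timepoint = "T1",
                          prefix = paste0(tissue, stress, timepoint)) {
  n <- n_down + n_up + n_ns
  gene_id <- sprintf("%s_g%06d", prefix, seq_len(n))
  log2fc <- c(rep(-2, n_down), rep(2, n_up), rep(0.2, n_ns))
  p <- c(rep(1e-4, n_down + n_up), rep(0.8, n_ns))
  deg_table(gene_id, log2fc, p, p, tissue, stress, timepoint)
}

# DEG tables whose per-cell significant counts reproduce a count fixture
deg_tables_from_counts <- function(counts) {
  lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    toy_deg_table(r$down, r$up, n_ns = 5, tissue = r$tissue,
                  stress = r$stress, timepoint = r$timepoint)
  })
}

fullscale_count_fixture <- function() {
  read.delim(system.file("extdata", "fullscale_deg_counts.tsv",
                         package = "stressmem"),
             stringsAsFactors = FALSE)
}

# DEG table with chosen gene ids and significance flags (log2fc sign gives
# direction); used by the memory-class tests
deg_table_from_effects <- function(effects, tissue, stress, timepoint) {
  sig <- abs(effects) > 1
  deg_table(names(effects), effects,
            pvalue = ifelse(sig, 1e-5, 0.5),
            fdr = ifelse(sig, 1e-4, 0.6),
            tissue = tissue, stress = stress, timepoint = timepoint)
}

# small annotation table builder
toy_annotation <- function(terms, namespace = "GO") {
  tab <- data.frame(
    gene_id = unlist(terms, use.names = FALSE),
    term_id = rep(names(terms), lengths(terms)),
    stringsAsFactors = FALSE)
  annotation_map(tab, namespace)
}

# brute-force one-sided hypergeometric tail from binomial coefficients;
# independent of phyper
hyper_tail_bruteforce <- function(a, K, n, N) {
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# brute-force two-sided binomial exact test on a split (a, t - a)
binom_twosided_bruteforce <- function(a, t, prob = 0.5) {
  probs <- vapply(0:t, function(x) choose(t, x) * prob^x *
                    (1 - prob)^(t - x), numeric(1))
  sum(probs[probs <= probs[a + 1] * (1 + 1e-8)])
}

# tiny simulated count matrix: two conditions, optional planted log2fc
toy_count_matrix <- function(n_genes = 200, n_rep = 3, mu = 100, alpha = 0.1,
                             l2fc = NULL, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  fc <- if (is.null(l2fc)) rep(0, n_genes) else l2fc
  mk <- function(mu_g) {
    if (alpha == 0) rpois(n_genes, mu_g) else
      rnbinom(n_genes, size = 1 / alpha, mu = mu_g)
  }
  cnt <- cbind(
    sapply(seq_len(n_rep), function(i) mk(mu)),
    sapply(seq_len(n_rep), function(i) mk(mu * 2^fc)))
  colnames(cnt) <- c(paste0("ctl", seq_len(n_rep)),
                     paste0("trt", seq_len(n_rep)))
  rownames(cnt) <- genes
  samples <- data.frame(
    sample_id = colnames(cnt),
    tissue = "leaf",
    stress = rep(c("control", "Fe"), each = n_rep),
    timepoint = "T1",
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
  count_matrix(cnt, samples)
}
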