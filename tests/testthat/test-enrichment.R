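test_that("fisher_overrep matches the hand-computed tail", {
  # (C(5,4) C(15,2) + C(5,5) C(15,1)) / C(20,6)
  expect_equal(fisher_overrep(4, 5, 6, 20),
               (choose(5, 4) * choose(15, 2) + choose(5, 5) * choose(15, 1)) /
                 choose(20, 6),
               tolerance = 1e-12)
  expect_equal(fisher_overrep(0, 5, 6, 20), 1)
  expect_equal(fisher_overrep(5, 5, 5, 5), 1)
  expect_error(fisher_overrep(6, 5, 6, 20), "margins")
})

test_that("fisher_overrep equals brute-force enumeration for all margins N <= 14", {
  for (N in 1:14) for (K in 0:N) for (n in 0:N) {
    amin <- max(0, K + n - N)
    for (a in amin:min(K, n)) {
      expect_equal(fisher_overrep(a, K, n, N),
                   hyper_tail_bruteforce(a, K, n, N),
                   tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d a=%d", N, K, n, a))
    }
  }
})

test_that("bonferroni scales and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.3, 5), 1)
  expect_equal(bonferroni(0.04, 1), 0.04)   # m = 1 is the identity
  expect_error(bonferroni(c(0.1, 0.2), 1), "smaller")
})

test_that("enrich_terms detects a planted term and records margins", {
  set.seed(81)
  genes <- sprintf("g%04d", 1:5000)
  deg <- sample(genes, 300)
  term_genes <- c(sample(deg, 30), sample(setdiff(genes, deg), 20))
  other <- lapply(1:20, function(i) sample(genes, 50))
  names(other) <- sprintf("GO:%04d", i <- 1:20)
  terms <- c(list("GO:planted" = term_genes), other)
  # make the universe all 5000 genes by adding a catch-all term
  terms$`GO:universe` <- genes
  ann <- toy_annotation(terms)
  res <- enrich_terms(deg, ann)
  row <- res[res$term_id == "GO:planted", ]
  expect_true(row$significant)
  expect_equal(row$a, 30)
  expect_equal(row$K, 50)
  expect_equal(row$N, 5000)
  expect_equal(attr(res, "m"), sum(res$a >= 1))

  expect_warning(empty <- enrich_terms(character(0), ann), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("enrichment on random DEG sets controls family-wise error", {
  set.seed(82)
  genes <- sprintf("g%04d", 1:2000)
  terms <- lapply(1:50, function(i) sample(genes, 40))
  names(terms) <- sprintf("GO:%04d", 1:50)
  terms$`GO:universe` <- genes
  ann <- toy_annotation(terms)
  hits <- vapply(1:100, function(i) {
    deg <- sample(genes, 100)
    any(enrich_terms(deg, ann)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("enrichment p-value is monotone in term membership of the DEG set", {
  genes <- sprintf("g%03d", 1:200)
  term <- genes[1:40]
  ann <- toy_annotation(list("GO:1" = term, "GO:universe" = genes))
  deg <- c(genes[1:5], genes[51:80])
  p1 <- enrich_terms(deg, ann)
  p2 <- enrich_terms(c(deg, genes[6]), ann)  # one more term member
  expect_lte(p2$p_raw[p2$term_id == "GO:1"],
             p1$p_raw[p1$term_id == "GO:1"])
})

test_that("TFF enrichment carries genome family sizes from the background", {
  fam <- list(ZIM = sprintf("zim%02d", 1:24), `E2F/DP` = sprintf("e2f%02d", 1:12),
              NAC = sprintf("nac%03d", 1:187))
  ann <- toy_annotation(fam, "TFF")
  deg <- c(fam$ZIM[1:10], fam$`E2F/DP`[1:3], fam$NAC[1:5])
  res <- enrich_terms(deg, ann)
  expect_equal(res$K[res$term_id == "ZIM"], 24)
  expect_equal(res$K[res$term_id == "E2F/DP"], 12)
  expect_equal(res$K[res$term_id == "NAC"], 187)
})

test_that("collapse_go merges identical DEG lists into the most general term", {
  genes <- sprintf("g%03d", 1:500)
  deg <- genes[1:30]
  big <- c(deg[1:10], genes[101:210])     # K = 120
  small <- c(deg[1:10], genes[301:330])   # K = 40
  ann <- toy_annotation(list("GO:big" = big, "GO:small" = small,
                             "GO:universe" = genes))
  res <- enrich_terms(deg, ann, universe_size = 500)
  res$significant <- res$term_id %in% c("GO:big", "GO:small")
  col <- collapse_go(res, ann, deg)
  expect_equal(nrow(col), 1)
  expect_equal(col$term_id, "GO:big")
  expect_equal(col$members_merged, "GO:small")

  # three-way merge keeps one representative, records two members
  ann3 <- toy_annotation(list("GO:a" = big, "GO:b" = small,
                              "GO:c" = c(deg[1:10], genes[401:420]),
                              "GO:universe" = genes))
  res3 <- enrich_terms(deg, ann3, universe_size = 500)
  res3$significant <- res3$term_id != "GO:universe"
  col3 <- collapse_go(res3, ann3, deg)
  expect_equal(nrow(col3), 1)
  expect_equal(col3$term_id, "GO:a")
  expect_setequal(strsplit(col3$members_merged, ",")[[1]],
                  c("GO:b", "GO:c"))

  # no duplicate lists: identity (plus empty members_merged)
  ann2 <- toy_annotation(list("GO:x" = c(deg[1:5], genes[101:120]),
                              "GO:y" = c(deg[6:20], genes[201:220]),
                              "GO:universe" = genes))
  res2 <- enrich_terms(deg, ann2, universe_size = 500)
  res2$significant <- res2$term_id %in% c("GO:x", "GO:y")
  col2 <- collapse_go(res2, ann2, deg)
  expect_equal(sort(col2$term_id), c("GO:x", "GO:y"))
  expect_equal(col2$members_merged, c("", ""))

  # the union of covered DEG genes is preserved
  covered_before <- unique(unlist(lapply(
    res3$term_id[res3$significant],
    function(t) intersect(ann3$term_to_genes[[t]], deg))))
  covered_after <- unique(unlist(lapply(
    col3$term_id, function(t) intersect(ann3$term_to_genes[[t]], deg))))
  expect_setequal(covered_after, covered_before)
})
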