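test_that("size factors follow the median-of-ratios definition", {
  # sample B = 2 x sample A, counts A = (2,4,6): geometric means are
  # sqrt(8), sqrt(32), sqrt(72); every ratio is 1/sqrt(2) resp. sqrt(2)
  cnt <- matrix(c(2, 4, 6, 4, 8, 12), 3, 2,
                dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- size_factors(cnt)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  same <- cbind(A = c(5, 9, 2), B = c(5, 9, 2))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))

  single <- matrix(c(5, 9, 2), dimnames = list(paste0("g", 1:3), "A"))
  expect_equal(unname(size_factors(single)), 1)

  # scale equivariance of factor ratios: scaling one sample's counts by c
  # scales its factor relative to the others by c (the geometric-mean
  # reference absorbs c^(1/m), so only ratios are equivariant)
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 7
  sf2 <- size_factors(cnt2)
  expect_equal(sf2[["B"]] / sf2[["A"]], 7 * sf[["B"]] / sf[["A"]],
               tolerance = 1e-10)

  allzero <- matrix(c(0, 5, 3, 0), 2, 2,
                    dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(size_factors(allzero), "positive")
})

test_that("size factors agree with the DESeq implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  cnt <- matrix(rnbinom(600, size = 10, mu = 80), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  ours <- size_factors(cnt)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("replicate QC flags a planted outlier and only that sample", {
  set.seed(21)
  n <- 400
  base <- rnbinom(n, size = 10, mu = 100)
  cnt <- sapply(1:8, function(i) base + rpois(n, 5))
  # perturb replicate 4 of condition 2: half the genes x100
  cnt[1:200, 8] <- cnt[1:200, 8] * 100
  rownames(cnt) <- sprintf("g%03d", 1:n)
  colnames(cnt) <- paste0("s", 1:8)
  samples <- data.frame(sample_id = colnames(cnt), tissue = "leaf",
                        stress = rep(c("control", "Fe"), each = 4),
                        timepoint = "T1", replicate = rep(1:4, 2),
                        stringsAsFactors = FALSE)
  cm <- count_matrix(cnt, samples)
  qc <- replicate_qc(cm, threshold = 3)
  expect_equal(qc$removed, "s8")

  # identical replicates: nothing flagged
  cm2 <- count_matrix(sapply(1:8, function(i) base) |>
                        (\(m) {dimnames(m) <- dimnames(cnt); m})(),
                      samples)
  expect_equal(length(replicate_qc(cm2, 3)$removed), 0)

  # infinite threshold: nothing flagged
  expect_equal(length(replicate_qc(cm, threshold = Inf)$removed), 0)
})

test_that("QC never removes a condition below two replicates and warns on singletons", {
  set.seed(22)
  n <- 300
  base <- rnbinom(n, size = 10, mu = 100)
  cnt <- sapply(1:7, function(i) base + rpois(n, 5))
  cnt[1:150, 6] <- cnt[1:150, 6] * 50   # two perturbed reps of one condition
  cnt[151:300, 7] <- cnt[151:300, 7] * 50
  rownames(cnt) <- sprintf("g%03d", 1:n)
  colnames(cnt) <- paste0("s", 1:7)
  samples <- data.frame(sample_id = colnames(cnt), tissue = "leaf",
                        stress = c(rep("control", 3), rep("Fe", 3), "Pi"),
                        timepoint = "T1",
                        replicate = c(1:3, 1:3, 1),
                        stringsAsFactors = FALSE)
  cm <- count_matrix(cnt, samples)
  expect_warning(qc <- replicate_qc(cm, threshold = 3), "<2 replicates")
  # at most one of the three Fe replicates may be removed
  expect_lte(sum(qc$removed %in% c("s4", "s5", "s6")), 1)
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  cm_pois <- toy_count_matrix(n_genes = 2000, mu = 100, alpha = 0, seed = 31)
  d0 <- estimate_dispersion(cm_pois)
  expect_lte(d0$common, 0.01)

  cm_nb <- toy_count_matrix(n_genes = 2000, mu = 100, alpha = 0.1, seed = 32)
  d1 <- estimate_dispersion(cm_nb)
  expect_gte(d1$common, 0.07)
  expect_lte(d1$common, 0.13)

  # variance below mean floors the raw estimate at zero
  cnt <- matrix(c(10, 10, 10, 9, 10, 11), 2, 3, byrow = TRUE,
                dimnames = list(c("gA", "gB"), paste0("s", 1:3)))
  samples <- data.frame(sample_id = paste0("s", 1:3), tissue = "leaf",
                        stress = "control", timepoint = "T1",
                        replicate = 1:3, stringsAsFactors = FALSE)
  d <- estimate_dispersion(count_matrix(cnt, samples),
                           sf = c(1, 1, 1), shrink = 0)
  expect_equal(unname(d$per_gene["gA"]), 0)  # zero variance
  expect_equal(unname(d$per_gene["gB"]), 0)  # var (1) < mean (10)
})

test_that("the exact NB test matches its stated conventions", {
  expect_equal(exact_nb_test(5, 5, 1, 1, alpha = 0), 1)
  expect_equal(exact_nb_test(0, 10, 1, 1, alpha = 0), 2 / 1024,
               tolerance = 1e-12)
  expect_equal(exact_nb_test(0, 0, 1, 1, alpha = 0.1), 1)
})

test_that("at alpha = 0 the exact test equals brute-force binomial enumeration", {
  for (t in c(1, 2, 5, 10, 25, 50)) {
    for (a in unique(c(0, 1, floor(t / 3), floor(t / 2), t))) {
      expect_equal(exact_nb_test(a, t - a, 1, 1, alpha = 0),
                   binom_twosided_bruteforce(a, t),
                   tolerance = 1e-10,
                   label = sprintf("split (%d, %d)", a, t - a))
    }
  }
})

test_that("exact test p-values are valid under the null", {
  # NB counts, no effect: p < 0.05 fraction near nominal
  set.seed(41)
  n <- 4000
  p <- vapply(seq_len(n), function(i) {
    y1 <- rnbinom(3, size = 10, mu = 100)
    y2 <- rnbinom(3, size = 10, mu = 100)
    exact_nb_test(y1, y2, alpha = 0.1)
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("DEG calling applies thresholds, BH and the low-count filter", {
  set.seed(51)
  n <- 1000
  l2fc <- rep(0, n); l2fc[1:100] <- 2 * sample(c(-1, 1), 100, replace = TRUE)
  cm <- toy_count_matrix(n_genes = n, mu = 100, alpha = 0.1, l2fc = l2fc,
                         seed = 51)
  tab <- call_degs(cm, contrast_spec(cm, "leaf", "Fe", "T1"))
  planted <- cm$gene_ids[1:100]
  sens <- mean(planted %in% tab$gene_id[tab$significant])
  expect_gte(sens, 0.9)
  false <- setdiff(tab$gene_id[tab$significant], planted)
  expect_lte(length(false) / max(1, sum(tab$significant)), 0.1)

  # BH: fdr is monotone in p-rank and >= p at the largest p
  o <- order(tab$pvalue)
  expect_true(all(diff(p.adjust(tab$pvalue[o], "BH")) >= -1e-12))
  expect_gte(tab$fdr[which.max(tab$pvalue)], max(tab$pvalue) - 1e-12)

  # significance flag is exactly the three-way rule
  expect_equal(tab$significant,
               abs(tab$log2fc) > 1 & tab$pvalue < 0.05 & tab$fdr < 0.05)

  # missing control group errors
  expect_error(contrast_spec(cm, "leaf", "Fe", "T2"), "missing control")
})

test_that("self-contrast by label permutation controls type-I error", {
  # full multi-condition design with no planted effects: the stress group
  # is distributionally identical to its control
  cfg <- sim_config(n_genes = 5000, tissues = "leaf", n_t1 = 0, n_t1rec = 0,
                    n_shared = 0, n_opposite = 0, n_unique = 0,
                    n_unique_common = 0, n_t2only = 0, seed = 52)
  cm <- generate_experiment(cfg)$cm
  tab <- call_degs(cm, contrast_spec(cm, "leaf", "Fe", "T1"))
  expect_gte(mean(tab$pvalue < 0.05), 0.035)
  expect_lte(mean(tab$pvalue < 0.05), 0.065)
})

test_that("Z-score rows are standardized and constant rows map to zero", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 2, 2))
  z <- stressmem:::zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  # any row: mean 0, sd in {0, 1}
  set.seed(61)
  r <- matrix(rnorm(50), 5)
  zr <- stressmem:::zscore_rows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 5), tolerance = 1e-12)
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-12 |
                    apply(zr, 1, sd) == 0))
})

test_that("gene clustering recovers planted groups and honours edge cases", {
  sim <- simulate_expression_groups(n_genes = 80, k = 2, seed = 71)
  z <- stressmem:::zscore_rows(sim$mat)
  cl <- cluster_genes(z, 2)
  expect_equal(adjusted_rand(cl, sim$labels), 1)

  expect_equal(unname(cluster_genes(z, 1)), rep(1L, nrow(z)))
  expect_error(cluster_genes(z, nrow(z) + 1), "exceeds")

  # duplicated rows always share a cluster
  zz <- rbind(z, dup = z[1, ])
  cl2 <- cluster_genes(zz, 3)
  expect_equal(unname(cl2["dup"]), unname(cl2[1]))

  # labelling is invariant to row permutation
  perm <- sample(nrow(z))
  cl3 <- cluster_genes(z[perm, ], 2)
  expect_equal(cl3[names(cl)], cl)
})
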