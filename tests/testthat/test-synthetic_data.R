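test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 300, tissues = "leaf", n_t1 = 20, n_t1rec = 10,
                    n_shared = 5, n_opposite = 10, n_unique = 15,
                    n_unique_common = 5, n_t2only = 5, tff_scale = 0.05,
                    seed = 131)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth$l2fc, b$truth$l2fc)
  expect_identical(a$annotations$go$term_to_genes,
                   b$annotations$go$term_to_genes)
  expect_identical(a$genome$markers, b$genome$markers)
})

test_that("simulated counts match NB moments within 5%", {
  set.seed(141)
  mu <- 200; alpha <- 0.1
  draws <- rnbinom(10000, size = 1 / alpha, mu = mu)
  expect_lt(abs(mean(draws) - mu) / mu, 0.05)
  v_expect <- mu + alpha * mu^2
  expect_lt(abs(var(draws) - v_expect) / v_expect, 0.05)

  # and the generator's counts reproduce baseline x size factor means
  cfg <- sim_config(n_genes = 5000, tissues = "leaf", n_t1 = 0, n_t1rec = 0,
                    n_shared = 0, n_opposite = 0, n_unique = 0,
                    n_unique_common = 0, n_t2only = 0, seed = 142)
  study <- generate_experiment(cfg)
  s1 <- study$cm$samples$sample_id[1]
  expected <- study$truth$sf[s1] * study$truth$baseline
  # high-expression genes: relative error of each draw is ~sqrt(alpha)
  hi <- expected > 100
  ratio <- study$cm$counts[hi, s1] / expected[hi]
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("planted memory truth encodes the class definitions", {
  cfg <- sim_config(n_genes = 500, tissues = "leaf", n_t1 = 10, n_t1rec = 10,
                    n_shared = 10, n_opposite = 25, n_unique = 30,
                    n_unique_common = 10, n_t2only = 10, seed = 151)
  study <- generate_experiment(cfg)
  l2fc <- study$truth$l2fc
  mem <- study$truth$memory
  expect_equal(sum(mem$class == "opposite" & mem$stress == "Fe"), 25)
  expect_equal(sum(mem$class == "t1t2_unique" & mem$stress == "Fe"), 30)
  opp <- mem$gene_id[mem$class == "opposite" & mem$stress == "Fe"]
  expect_true(all(sign(l2fc[opp, "leaf.Fe.T1T2"]) !=
                    sign(l2fc[opp, "leaf.Fe.T2"])))
  expect_true(all(abs(l2fc[opp, "leaf.Fe.T1T2"]) > 1))
  uni <- mem$gene_id[mem$class == "t1t2_unique" & mem$stress == "Fe"]
  expect_true(all(abs(l2fc[uni, "leaf.Fe.T1T2"]) > 1))
  expect_true(all(abs(l2fc[uni, c("leaf.Fe.T1", "leaf.Fe.T1Rec",
                                  "leaf.Fe.T2")]) <= 1))
  # the configured cross-stress common unique genes are shared
  uni_pi <- mem$gene_id[mem$class == "t1t2_unique" & mem$stress == "Pi"]
  expect_equal(length(intersect(uni, uni_pi)), 10)
  # planted memory baselines honour the stated floor
  expect_true(all(study$truth$baseline[c(opp, uni)] >= 100))
})

test_that("generated genome and QTLs are mutually consistent", {
  cfg <- sim_config(n_genes = 400, tissues = "leaf", n_t1 = 10, n_t1rec = 0,
                    n_shared = 0, n_opposite = 5, n_unique = 10,
                    n_unique_common = 0, n_t2only = 5, n_qtl = 3,
                    qtl_genes = 15, seed = 161)
  gen <- generate_genome(cfg, sprintf("gene%05d", 1:400))
  # spans are valid and non-overlapping within chromosomes
  expect_true(all(gen$spans$start <= gen$spans$end))
  by_chrom <- split(gen$spans, gen$spans$chromosome)
  for (ch in by_chrom)
    expect_true(all(diff(ch$start) > 0) &&
                  all(ch$start[-1] > ch$end[-nrow(ch)]))
  # cross-module check: interval lookup recovers the planted membership
  intervals <- marker_interval(gen$markers)
  for (i in seq_len(nrow(intervals))) {
    lab <- intervals$qtl[i]
    got <- genes_in_interval(gen$spans, intervals[i, ])$gene_id
    expect_setequal(got, gen$qtl_truth[[lab]])
  }
})

test_that("a written study is read back losslessly by the io layer", {
  cfg <- sim_config(n_genes = 300, tissues = "leaf", n_t1 = 10, n_t1rec = 5,
                    n_shared = 5, n_opposite = 10, n_unique = 10,
                    n_unique_common = 5, n_t2only = 5, n_terms = 30,
                    tff_scale = 0.05, seed = 171)
  study <- generate_study(cfg)
  dir <- tempfile()
  write_study(study, dir)
  cm <- read_counts(file.path(dir, "counts.tsv"),
                    file.path(dir, "samples.tsv"))
  expect_equal(cm$counts, study$cm$counts)
  go <- read_annotations(file.path(dir, "go_annotations.tsv"), "GO")
  expect_equal(go$term_to_genes, study$annotations$go$term_to_genes)
  expect_equal(go$genome_size, study$annotations$go$genome_size)
  spans <- read_gene_positions(file.path(dir, "genes.gff3"))
  expect_equal(spans$start, study$genome$spans$start)
  markers <- read_markers(file.path(dir, "markers.tsv"))
  expect_equal(markers, study$genome$markers)
})
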