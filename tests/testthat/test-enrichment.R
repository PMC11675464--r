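test_that("binomial_two_sided reproduces worked enumeration values", {
  # pmf(8; 10, 0.5) = 45/1024; terms with pmf <= that: x in {0,1,2,8,9,10}
  # summing to (1 + 10 + 45 + 45 + 10 + 1)/1024 = 112/1024
  expect_equal(binomial_two_sided(8, 10, 0.5), 112 / 1024)
  # the mode always gives p = 1
  expect_equal(binomial_two_sided(5, 10, 0.5), 1)
  expect_equal(binomial_two_sided(9, 10, 0.9), 1)
  expect_equal(binomial_two_sided(0, 10, 0.9),
               oracle_binom_two_sided(0, 10, 0.9))
  expect_error(binomial_two_sided(3, 10, 0), "inside")
  expect_error(binomial_two_sided(3, 10, 1), "inside")
  expect_error(binomial_two_sided(11, 10, 0.5), "observed")
})

test_that("hypergeom_upper reproduces the direct combinatorial sum", {
  # C(10,3)C(40,2) + C(10,4)C(40,1) + C(10,5) over C(50,5)
  expect_equal(hypergeom_upper(3, 10, 40, 5), 102252 / 2118760)
  expect_equal(hypergeom_upper(0, 10, 40, 5), 1)   # P(X >= 0) = 1
  # degenerate population: every draw is a success
  expect_equal(hypergeom_upper(4, 20, 0, 4), 1)
  expect_error(hypergeom_upper(6, 10, 40, 5), "min")
})

test_that("exact tests match brute-force enumeration on a parameter sweep", {
  for (n in c(5, 17, 60)) {
    for (p in c(0.02, 0.3, 0.5, 0.77)) {
      for (obs in unique(round(c(0, n / 4, n / 2, n)))) {
        expect_equal(binomial_two_sided(obs, n, p),
                     oracle_binom_two_sided(obs, n, p), tolerance = 1e-12)
      }
    }
  }
  set.seed(3)
  for (i in 1:100) {
    m <- sample(1:60, 1); n_rest <- sample(1:60, 1)
    k <- sample(1:(m + n_rest), 1)
    q <- sample(0:min(m, k), 1)
    expect_equal(hypergeom_upper(q, m, n_rest, k),
                 oracle_hyper_upper(q, m, n_rest, k), tolerance = 1e-12)
  }
})

test_that("benjamini_hochberg applies the step-up rule and preserves order", {
  # by hand: p(i) * m / i = (.04, .04, .04, .04) after cumulative min
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(1)
  p <- sort(runif(100))
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj) >= 0))      # monotone on sorted input
  expect_true(all(adj >= p))            # never decreases
  expect_true(all(adj <= 1))
  shuffled <- sample(seq_along(p))
  expect_equal(benjamini_hochberg(p[shuffled]), adj[shuffled])
  expect_error(benjamini_hochberg(c(0.5, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("chromosome enrichment uses the size-proportional null with n x p
           expectations and BH across chromosomes", {
  asm <- genome_assembly(paste0("c", 1:10), c(1e6, rep(1e6, 9)))
  # chromosome occupying 10% of the genome holding exactly 10% of 1000 QTL:
  # expected equals observed, direction neutral, p = 1 (mode region)
  counts <- rep(100, 10)
  qtl <- rec(rep(paste0("c", 1:10), counts), 0, 10)
  res <- chromosome_enrichment(qtl, asm)
  expect_equal(res$expected, rep(100, 10))
  expect_equal(res$direction, rep("neutral", 10))
  expect_true(all(res$p_raw > 0.99))

  # 160 observed on a 10% chromosome: enriched, exact two-sided p
  qtl2 <- rec(rep(paste0("c", 1:10), c(160, rep(93, 9))), 0, 10)
  res2 <- chromosome_enrichment(qtl2, asm)
  expect_equal(res2$direction[1], "enriched")
  expect_equal(res2$p_raw[1],
               oracle_binom_two_sided(160, nrow(qtl2), 0.1),
               tolerance = 1e-10)

  # zero observed on a 10% chromosome with n = 50: depleted two-sided tail
  qtl3 <- rec(rep(paste0("c", 2:10), length.out = 50), 0, 10)
  res3 <- chromosome_enrichment(qtl3, asm)
  expect_equal(res3$direction[1], "depleted")
  expect_equal(res3$p_raw[1], oracle_binom_two_sided(0, 50, 0.1),
               tolerance = 1e-10)
  expect_equal(res3$p_adj, benjamini_hochberg(res3$p_raw))
})

test_that("window enrichment tests the gene-proportion null, skipping
           zero-gene and short windows", {
  asm <- genome_assembly("chr1", 4.2e6)
  g <- make_grid(asm, 1e6)
  g$gene_count <- c(10, 70, 0, 20, 0)
  g$qtl_count <- c(10, 70, 5, 15, 0)
  res <- window_enrichment(g)
  # zero-gene window with QTL: skipped with a reason, not pseudo-counted
  expect_false(res$tested[3])
  expect_equal(res$skip_reason[3], "zero_genes")
  # 200 kbp partial window: skipped as short
  expect_false(res$tested[5])
  expect_equal(res$skip_reason[5], "short_window")
  expect_equal(sum(res$tested), 3L)
  # window holding 10% of genes and 10% of the 100 QTL: p near 1
  expect_equal(res$expected[1], 100 * 0.1)
  expect_gt(res$p_raw[1], 0.99)
  expect_equal(res$p_raw[res$tested],
               vapply(which(res$tested), function(i) {
                 oracle_binom_two_sided(g$qtl_count[i], 100,
                                        g$gene_count[i] / 100)
               }, 0), tolerance = 1e-10)
  g$gene_count[] <- 0L
  expect_error(window_enrichment(g), "all zero")
})

test_that("trait window enrichment matches the hypergeometric closed form
           and emits only observed (window, label) pairs", {
  asm <- genome_assembly("chr1", 5e6)
  grid <- make_grid(asm, 1e6)
  # 20 QTL: window 1 holds 5 (3 of trait X), the rest spread; trait Y
  # appears once in window 2 (singleton closed form p = m/N)
  set.seed(8)
  start <- c(runif(5, 0, 0.9e6), runif(15, 1e6, 4.9e6))
  qtl <- rec("chr1", floor(start), floor(start) + 10,
             trait = c(rep("X", 3), rep("Z", 2), "Y", rep("Z", 14)))
  grid <- count_features(grid, qtl)
  res <- trait_window_enrichment(grid, qtl, level = "trait_name",
                                 bh_family = "per_label")
  # every emitted pair has q_obs >= 1
  expect_true(all(res$q_obs >= 1))
  x1 <- res[res$label == "X" & res$start == 0, ]
  expect_equal(x1$q_obs, 3)
  expect_equal(x1$m, 5)
  expect_equal(x1$k, 3)
  expect_equal(x1$p_raw, oracle_hyper_upper(3, 5, 15, 3), tolerance = 1e-12)
  # singleton label: P(X >= 1) = m / N
  y <- res[res$label == "Y", ]
  expect_equal(nrow(y), 1L)
  expect_equal(y$p_raw, y$m / 20, tolerance = 1e-12)
  # no test rows for labels absent from a window
  expect_false(any(res$label == "X" & res$start > 0))
  expect_error(trait_window_enrichment(grid, qtl, level = "trait_class"),
               "no labels")
})

test_that("per-label and global BH families differ as documented", {
  asm <- genome_assembly("chr1", 6e6)
  grid <- make_grid(asm, 1e6)
  set.seed(5)
  start <- floor(runif(60, 0, 5.9e6))
  qtl <- rec("chr1", start, start + 10,
             trait = sample(c("A", "B", "C"), 60, replace = TRUE))
  grid <- count_features(grid, qtl)
  per <- trait_window_enrichment(grid, qtl, "trait_name", "per_label")
  glob <- trait_window_enrichment(grid, qtl, "trait_name", "global")
  expect_equal(per$p_raw, glob$p_raw)
  expect_equal(glob$p_adj, benjamini_hochberg(glob$p_raw))
  for (lab in unique(per$label)) {
    sel <- per$label == lab
    expect_equal(per$p_adj[sel], benjamini_hochberg(per$p_raw[sel]))
  }
})

test_that("a planted hotspot window is recovered by window enrichment after
           BH adjustment", {
  hs <- data.frame(chrom = "chr1", start = 5e6, lambda = 5)
  cfg <- sim_config(seed = 21, chromosome_lengths = c(2e7, 2e7),
                    n_genes = 1000, n_qtl = 3000,
                    placement_mixture = c(uniform = 0, gene = 1, hotspot = 0),
                    hotspots = hs, snp_length_fraction = 1,
                    duplicate_rate = 0, anomaly_rate = 0,
                    overlength_rate = 0)
  b <- simulate_qtlome(cfg)
  grid <- count_features(make_grid(b$assembly, 1e6), b$records, b$genes)
  res <- window_enrichment(grid)
  hot <- res$chrom == "chr1" & res$start == 5e6
  expect_true(res$tested[hot])
  expect_lt(res$p_adj[hot], 0.05)
  expect_equal(res$direction[hot], "enriched")
})
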