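test_that("pearson_r matches hand-computed and textbook values", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand computation: sum((x-2.5)(y-2.5)) / sqrt(5 * 5) = 4/5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r agrees with the explicit product-moment formula on
           random vectors", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), manual, tolerance = 1e-12)
  }
})

test_that("permutation p-values are seeded, bounded and detect collinearity", {
  x <- 1:12
  y <- 2 * x
  p1 <- permutation_pvalue(x, y, n_perm = 1000, seed = 5)
  p2 <- permutation_pvalue(x, y, n_perm = 1000, seed = 5)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 1001)
  # different seeds cannot beat the lower bound
  for (s in 1:5) {
    expect_lte(permutation_pvalue(x, y, n_perm = 1000, seed = s), 5 / 1001)
  }
  expect_gte(permutation_pvalue(rnorm(10), rnorm(10), 100, 1), 1 / 101)
  expect_error(permutation_pvalue(x, y, n_perm = 0), "positive")
})

test_that("the permutation test is calibrated under independence", {
  # uniform p under the null: rejection rate at 0.05 within the binomial CI
  n_rep <- 500
  ps <- vapply(seq_len(n_rep), function(i) {
    permutation_pvalue(rnorm(15), rnorm(15), n_perm = 200, seed = i)
  }, 0)
  rate <- mean(ps < 0.05)
  half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), half + 1e-9)
})

test_that("genome-level correlations relate QTL, gene and size vectors and
           support leave-out analyses", {
  asm <- genome_assembly(paste0("c", 1:5), c(5e6, 4e6, 3e6, 2e6, 1e6))
  # counts proportional to length: perfect correlations
  qtl <- rec(rep(paste0("c", 1:5), times = c(50, 40, 30, 20, 10)), 0, 100)
  genes <- data.frame(chrom = rep(paste0("c", 1:5),
                                  times = c(25, 20, 15, 10, 5)),
                      start = 0, end = 10, gene_id = NA, symbol = "",
                      biotype = "")
  genes$gene_id <- sprintf("g%d", seq_len(nrow(genes)))
  res <- genome_level_correlations(qtl, genes, asm, n_perm = 200, seed = 1)
  expect_equal(res$r, c(1, 1, 1))
  expect_true(all(res$p_value <= 5 / 201))

  # one outlier chromosome with a 10x QTL excess drags r down; leaving it
  # out restores the correlation
  qtl2 <- rbind(qtl, rec(rep("c4", 180), 0, 100))
  r_with <- genome_level_correlations(qtl2, genes, asm, 50, 1)
  r_without <- genome_level_correlations(qtl2, genes, asm, 50, 1,
                                         exclude_chroms = "c4")
  expect_lt(r_with$r[1], r_without$r[1])
  expect_equal(r_without$r[1], 1)

  one <- genome_assembly("c1", 5e6)
  expect_error(genome_level_correlations(qtl, genes, one, 10, 1),
               "at least 3")
})

test_that("the window-level matrix excludes short chromosomes and constant
           vectors and averages only included cells", {
  asm <- genome_assembly(c("cBig", "cSmall", "cEmpty"),
                         c(20e6, 9e6, 15e6))
  cfg <- null_sim_config(seed = 3, n_qtl = 800, lengths = c(20e6, 9e6, 15e6))
  b <- simulate_qtlome(cfg)
  # remove everything from cEmpty = chr3 to force a constant (all-zero) row
  qtl <- b$records[b$records$chrom != "chr3", ]
  asm <- b$assembly
  grid <- count_features(make_grid(asm, 1e6), qtl, b$genes)
  mat <- window_level_matrix(list(grid), min_windows = 10, n_perm = 100,
                             seed = 1)
  expect_equal(nrow(mat), 3L)
  # 9 windows at 1 Mbp: excluded for too few windows
  expect_true(mat$excluded[mat$chrom == "chr2"])
  expect_equal(mat$reason[mat$chrom == "chr2"], "too_few_windows")
  # all-zero QTL vector: excluded as constant
  expect_true(mat$excluded[mat$chrom == "chr3"])
  expect_equal(mat$reason[mat$chrom == "chr3"], "constant_vector")
  rb <- rbar(mat)
  expect_equal(rb$n_included, 1L)
  expect_equal(rb$rbar, mat$r[mat$chrom == "chr1"])
})

test_that("rbar equals the mean of included cells across scales and
           increases with window size under gene-proportional placement", {
  cfg <- null_sim_config(seed = 17, n_qtl = 600, n_genes = 1000,
                         lengths = c(3e7, 3e7, 3e7))
  b <- simulate_qtlome(cfg)
  grids <- lapply(c(250e3, 1e6, 2.5e6), function(w) {
    count_features(make_grid(b$assembly, w), b$records, b$genes)
  })
  mat <- window_level_matrix(grids, n_perm = 50, seed = 2)
  rb <- rbar(mat)
  for (w in rb$window_size) {
    cells <- mat[mat$window_size == w & !mat$excluded, ]
    expect_equal(rb$rbar[rb$window_size == w], mean(cells$r))
  }
  # correlation strengthens with coarser windows (qualitative pattern)
  expect_true(all(rb$rbar > 0))
  expect_gt(rb$rbar[rb$window_size == 2.5e6],
            rb$rbar[rb$window_size == 250e3])
})

test_that("QTL vs study/trait correlations flag constant counters and
           recover identity cases", {
  asm <- genome_assembly("chr1", 4e6)
  # every QTL from a distinct study and 1/2/3/4 QTL per window:
  # study_count == qtl_count exactly, so r = 1
  start <- c(0, 1e6, 1.1e6, 2e6, 2.1e6, 2.2e6, 3e6, 3.1e6, 3.2e6, 3.3e6)
  qtl <- rec("chr1", start, start + 10,
             study = sprintf("S%02d", 1:10), trait = sprintf("T%02d", 1:10))
  g <- count_features(make_grid(asm, 1e6), qtl)
  res <- qtl_vs_study_trait_correlation(g, n_perm = 100, seed = 1)
  expect_equal(res$r, c(1, 1))

  # all QTL from one study: constant only if counts are constant too; use
  # a grid where qtl counts vary but study counts are all 1 except where 0
  qtl2 <- rec("chr1", c(0, 1e5, 2e5, 1.1e6), c(10, 10, 10, 10) + c(0, 1e5, 2e5, 1.1e6),
              study = "S1")
  g2 <- count_features(make_grid(asm, 1e6), qtl2)
  res2 <- qtl_vs_study_trait_correlation(g2, n_perm = 100, seed = 1)
  expect_false(any(res2$excluded))
  # truly constant counter vectors are excluded, not NaN
  g3 <- g2
  g3$study_count <- 1L
  g3$trait_count <- 1L
  res3 <- qtl_vs_study_trait_correlation(g3, n_perm = 100, seed = 1)
  expect_true(all(res3$excluded))
  expect_equal(res3$reason, rep("constant_vector", 2))
})
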