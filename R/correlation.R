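.check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit input validation: constant
#' vectors raise an undefined-correlation error (callers exclude the unit)
#' rather than propagating NaN.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_r <- function(x, y) {
  .check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Permutation p-value for a Pearson correlation
#'
#' Permutes `y` with a seeded generator and reports the two-sided
#' "at least as extreme" p-value with the +1 correction:
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`, which is bounded
#' below by `1/(n_perm + 1)` and reproducible bit-for-bit under a fixed
#' seed.
#'
#' @param x,y numeric vectors (see [pearson_r()]).
#' @param n_perm number of permutations (`>= 1`; default 1000).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000L, seed = 1L) {
  .check_cor_input(x, y)
  if (!is.numeric(n_perm) || n_perm < 1L) {
    stop("n_perm must be a positive integer")
  }
  r_obs <- stats::cor(x, y)
  n <- length(y)
  r_perm <- with_seed(seed, {
    perm <- matrix(0, nrow = n, ncol = n_perm)
    for (j in seq_len(n_perm)) perm[, j] <- sample(y)
    as.numeric(stats::cor(x, perm))
  })
  (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
}

.correlation_row <- function(label, x, y, n_perm, seed) {
  excluded <- length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0
  if (excluded) {
    return(data.frame(label = label, r = NA_real_, n_points = length(x),
                      p_value = NA_real_, n_permutations = n_perm,
                      seed = seed, excluded = TRUE,
                      reason = if (length(x) < 3L) "too_few_points"
                               else "constant_vector",
                      stringsAsFactors = FALSE))
  }
  data.frame(label = label, r = pearson_r(x, y), n_points = length(x),
             p_value = permutation_pvalue(x, y, n_perm, seed),
             n_permutations = n_perm, seed = seed, excluded = FALSE,
             reason = "", stringsAsFactors = FALSE)
}

#' Genome-level correlations of QTL count, gene count and chromosome size
#'
#' Per-chromosome totals are correlated across chromosomes: QTL count vs
#' gene count (`r_qtl_genes`), QTL count vs chromosome length
#' (`r_qtl_chr_size`) and gene count vs length (`r_genes_chr_size`), each
#' with a permutation p-value. `exclude_chroms` supports leave-out analyses
#' of outlier chromosomes.
#'
#' @param qtl QC-passed QTL record data.frame.
#' @param genes gene data.frame.
#' @param assembly [genome_assembly()] with at least 3 chromosomes (after
#'   exclusions).
#' @param n_perm permutations per test.
#' @param seed master seed; per-test seeds are derived by label.
#' @param exclude_chroms chromosome names to leave out.
#' @return data.frame of correlation results (one row per label).
#' @export
genome_level_correlations <- function(qtl, genes, assembly,
                                      n_perm = 1000L, seed = 1L,
                                      exclude_chroms = NULL) {
  chroms <- setdiff(assembly$chromosomes$name, exclude_chroms)
  if (length(chroms) < 3L) stop("need at least 3 chromosomes")
  qtl_n <- as.numeric(table(factor(qtl$chrom, levels = chroms)))
  gene_n <- as.numeric(table(factor(genes$chrom, levels = chroms)))
  size <- chrom_lengths(assembly)[chroms]
  rbind(
    .correlation_row("r_qtl_genes", qtl_n, gene_n, n_perm,
                     derive_seed(seed, "r_qtl_genes")),
    .correlation_row("r_qtl_chr_size", qtl_n, size, n_perm,
                     derive_seed(seed, "r_qtl_chr_size")),
    .correlation_row("r_genes_chr_size", gene_n, size, n_perm,
                     derive_seed(seed, "r_genes_chr_size"))
  )
}

#' Chromosome x scale matrix of window-level density correlations
#'
#' For every chromosome and every window scale, the Pearson correlation
#' between two per-window counters (QTL vs gene counts by default) over that
#' chromosome's windows. Chromosomes with fewer than `min_windows` windows
#' at a scale, or with a constant counter vector, are excluded from that
#' cell and from the scale's mean correlation `rbar` (excluding rather than
#' scoring 0 keeps undefined correlations from biasing `rbar`).
#'
#' @param grids list of counted grids (typically one per scale).
#' @param x,y counter column names to correlate.
#' @param min_windows minimum windows per chromosome (default 10).
#' @param n_perm permutations per cell.
#' @param seed master seed.
#' @return data.frame with one row per (scale, chromosome) and attribute
#'   `rbar` (data.frame `window_size`, `rbar`, `n_included`), also available
#'   via [rbar()].
#' @export
window_level_matrix <- function(grids, x = "qtl_count", y = "gene_count",
                                min_windows = 10L, n_perm = 1000L,
                                seed = 1L) {
  if (inherits(grids, "window_grid")) grids <- list(grids)
  rows <- list()
  for (grid in grids) {
    w <- attr(grid, "window_size")
    for (chrom in unique(grid$chrom)) {
      sel <- grid$chrom == chrom
      xv <- grid[[x]][sel]
      yv <- grid[[y]][sel]
      label <- sprintf("r%s@%s", format(w / 1e6), chrom)
      if (sum(sel) < min_windows) {
        row <- data.frame(label = label, r = NA_real_, n_points = sum(sel),
                          p_value = NA_real_, n_permutations = n_perm,
                          seed = NA_integer_, excluded = TRUE,
                          reason = "too_few_windows", stringsAsFactors = FALSE)
      } else {
        row <- .correlation_row(label, xv, yv, n_perm,
                                derive_seed(seed, label))
      }
      row$window_size <- w
      row$chrom <- chrom
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  inc <- !out$excluded
  rbar <- do.call(rbind, lapply(split(seq_len(nrow(out)), out$window_size),
                                function(i) {
    data.frame(window_size = out$window_size[i[1]],
               rbar = if (any(inc[i])) mean(out$r[i][inc[i]]) else NA_real_,
               n_included = sum(inc[i]))
  }))
  rownames(rbar) <- NULL
  attr(out, "rbar") <- rbar
  out
}

#' Mean chromosomal correlation per scale
#'
#' @param matrix_result output of [window_level_matrix()].
#' @return the `rbar` data.frame.
#' @export
rbar <- function(matrix_result) {
  attr(matrix_result, "rbar")
}

#' Correlation of window QTL counts with study and trait counts
#'
#' Per-window QTL counts correlated against the number of distinct studies
#' and the number of distinct traits per window — high values indicate that
#' dense windows are dense because many studies/phenotypes hit them
#' (pleiotropic regions), not a single large study.
#'
#' @param grid a counted grid (with `study_count`/`trait_count`).
#' @param n_perm permutations.
#' @param seed master seed.
#' @return data.frame with rows `r_qtl_studies` and `r_qtl_traits`.
#' @export
qtl_vs_study_trait_correlation <- function(grid, n_perm = 1000L, seed = 1L) {
  rbind(
    .correlation_row("r_qtl_studies", grid$qtl_count, grid$study_count,
                     n_perm, derive_seed(seed, "r_qtl_studies")),
    .correlation_row("r_qtl_traits", grid$qtl_count, grid$trait_count,
                     n_perm, derive_seed(seed, "r_qtl_traits"))
  )
}
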