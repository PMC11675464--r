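#' Exact two-sided binomial test p-value
#'
#' The two-tailed exact binomial p-value as computed by
#' `stats::binom.test()`: the sum of all probabilities
#' `P(X = x) <= P(X = observed) * (1 + 1e-7)` under `X ~ Binom(n_total,
#' p_null)`. Equals 1 when the observed count is the distribution's mode.
#'
#' @param observed observed count, `0 <= observed <= n_total`.
#' @param n_total number of trials (total QTL).
#' @param p_null null success probability, strictly inside `(0, 1)`.
#' @return two-sided p-value.
#' @export
#' @examples
#' binomial_two_sided(8, 10, 0.5)  # 112/1024
binomial_two_sided <- function(observed, n_total, p_null) {
  stopifnot(length(observed) == 1L, length(n_total) == 1L,
            length(p_null) == 1L)
  if (is.na(p_null) || p_null <= 0 || p_null >= 1) {
    stop("p_null must be strictly inside (0, 1)")
  }
  if (observed < 0 || observed > n_total) {
    stop("observed must lie in [0, n_total]")
  }
  p <- stats::binom.test(round(observed), round(n_total), p_null,
                         alternative = "two.sided")$p.value
  # guard against underflow to exactly 0 for extreme observations
  max(p, .Machine$double.xmin)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= q_obs)` for `X` hypergeometric with `m` successes, `n_rest`
#' failures and `k` draws — evaluated as the survival function at
#' `q_obs - 1` (`stats::phyper(q_obs - 1, ..., lower.tail = FALSE)`). In the
#' trait enrichment test, `m` is the window's QTL count, `n_rest` the rest
#' of the database, `k` the trait's database-wide QTL count and `q_obs` the
#' trait's count inside the window.
#'
#' @param q_obs observed overlap count, `0 <= q_obs <= min(m, k)`.
#' @param m successes in the population.
#' @param n_rest failures in the population.
#' @param k number of draws.
#' @return upper-tail p-value.
#' @export
#' @examples
#' hypergeom_upper(3, 10, 40, 5)  # 102252/2118760
hypergeom_upper <- function(q_obs, m, n_rest, k) {
  stopifnot(length(q_obs) == 1L)
  if (any(c(q_obs, m, n_rest, k) < 0)) stop("counts must be non-negative")
  if (k > m + n_rest) stop("k cannot exceed the population size")
  if (q_obs > min(m, k)) stop("q_obs cannot exceed min(m, k)")
  p <- stats::phyper(q_obs - 1, m, n_rest, k, lower.tail = FALSE)
  # a true p-value is never exactly 0; values below double-precision
  # underflow are reported as the smallest positive double
  max(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wrapper around `stats::p.adjust(method = "BH")` with input validation:
#' p-values must lie in `(0, 1]`. Adjusted values never fall below the raw
#' values, never exceed 1, and input order is preserved.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

.direction <- function(observed, expected) {
  ifelse(observed > expected, "enriched",
         ifelse(observed < expected, "depleted", "neutral"))
}

#' Chromosome-level QTL enrichment (exact binomial)
#'
#' For each chromosome, the observed QTL count is compared with the
#' expectation `n x p` under a size-proportional null: `n` is the
#' genome-wide QTL count and `p` the proportion of the genome occupied by
#' the chromosome (chromosome size / genome size). Two-tailed exact test;
#' BH adjustment across the chromosomes of the assembly.
#'
#' @param qtl QC-passed QTL record data.frame (all on assembly
#'   chromosomes).
#' @param assembly [genome_assembly()].
#' @return data.frame with one row per chromosome: `chrom`, `length`,
#'   `p_null`, `n_total`, `observed`, `expected`, `direction`, `p_raw`,
#'   `p_adj`.
#' @export
chromosome_enrichment <- function(qtl, assembly) {
  chroms <- assembly$chromosomes
  if (!all(qtl$chrom %in% chroms$name)) {
    stop("QTL on a chromosome absent from the assembly")
  }
  observed <- as.numeric(table(factor(qtl$chrom, levels = chroms$name)))
  n_total <- nrow(qtl)
  p_null <- chroms$length / assembly$total_length
  p_raw <- vapply(seq_along(observed), function(i) {
    binomial_two_sided(observed[i], n_total, p_null[i])
  }, 0)
  data.frame(
    chrom = chroms$name, length = chroms$length, p_null = p_null,
    n_total = n_total, observed = observed, expected = n_total * p_null,
    direction = .direction(observed, n_total * p_null),
    p_raw = p_raw, p_adj = benjamini_hochberg(p_raw),
    stringsAsFactors = FALSE
  )
}

#' Window-level QTL enrichment (exact binomial, gene-proportion null)
#'
#' For each window, the observed QTL count is tested against the
#' expectation under a gene-proportional null: `p` is the window's share of
#' all genes. Windows with zero genes are skipped (their null probability is
#' undefined; no pseudo-count is invented) and reported with a skip reason,
#' as are partial windows shorter than `min_window_fraction` of the window
#' size. BH adjustment spans all tested windows.
#'
#' @param grid a counted grid (QTL and gene counts filled).
#' @param min_window_fraction partial windows shorter than this fraction of
#'   the window size are skipped (default 0.5; set 0 to keep all).
#' @return data.frame with one row per window: coordinates, counts,
#'   `tested`, `skip_reason`, `p_null`, `expected`, `direction`, `p_raw`,
#'   `p_adj`.
#' @export
window_enrichment <- function(grid, min_window_fraction = 0.5) {
  total_genes <- sum(grid$gene_count)
  if (total_genes == 0) stop("gene counts are all zero; count genes first")
  n_total <- sum(grid$qtl_count)
  w <- attr(grid, "window_size")
  short <- (grid$end - grid$start) < min_window_fraction * w
  zero <- grid$gene_count == 0
  tested <- !short & !zero
  skip_reason <- rep("", nrow(grid))
  skip_reason[zero] <- "zero_genes"
  skip_reason[short] <- "short_window"
  p_null <- ifelse(tested, grid$gene_count / total_genes, NA_real_)
  p_raw <- rep(NA_real_, nrow(grid))
  p_raw[tested] <- vapply(which(tested), function(i) {
    binomial_two_sided(grid$qtl_count[i], n_total, p_null[i])
  }, 0)
  p_adj <- rep(NA_real_, nrow(grid))
  p_adj[tested] <- benjamini_hochberg(p_raw[tested])
  out <- data.frame(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    index = grid$index, qtl_count = grid$qtl_count,
    gene_count = grid$gene_count, tested = tested,
    skip_reason = skip_reason, p_null = p_null, n_total = n_total,
    expected = n_total * p_null,
    direction = ifelse(tested, .direction(grid$qtl_count, n_total * p_null),
                       NA_character_),
    p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE
  )
  out
}

#' Trait-specific window enrichment (hypergeometric)
#'
#' For each phenotypic label at the requested hierarchy level (class, type
#' or trait) and each window holding at least one QTL for that label, the
#' upper-tail hypergeometric test of [hypergeom_upper()] asks whether the
#' label's QTL concentrate in the window beyond what drawing the label's
#' `k` database QTL at random from the `N` database QTL would give. BH
#' adjustment is applied within each label across windows by default
#' (`bh_family = "per_label"`), or across all tests (`"global"`).
#'
#' @param grid a counted grid.
#' @param qtl QC-passed QTL record data.frame with trait labels.
#' @param level `"trait_class"`, `"trait_type"` or `"trait_name"`.
#' @param bh_family `"per_label"` or `"global"`.
#' @param min_window_fraction as in [window_enrichment()].
#' @return data.frame with one row per (window, label) pair with
#'   `q_obs >= 1`: window coordinates, `level`, `label`, `q_obs`, `m`,
#'   `n_rest`, `k`, `expected`, `p_raw`, `p_adj`.
#' @export
trait_window_enrichment <- function(grid, qtl,
                                    level = c("trait_name", "trait_type",
                                              "trait_class"),
                                    bh_family = c("per_label", "global"),
                                    min_window_fraction = 0.5) {
  level <- match.arg(level)
  bh_family <- match.arg(bh_family)
  labels <- qtl[[level]]
  if (all(labels == "")) stop("no labels present at level ", level)
  idx <- assign_windows(grid, qtl$chrom,
                        interval_midpoint(qtl$start, qtl$end))
  n_db <- nrow(qtl)
  m_win <- tabulate(idx, nbins = nrow(grid))
  k_lab <- table(labels)
  w <- attr(grid, "window_size")
  keep_win <- (grid$end - grid$start) >= min_window_fraction * w
  pair <- stats::aggregate(list(q_obs = rep(1L, n_db)),
                           by = list(index = idx, label = labels), FUN = sum)
  pair <- pair[keep_win[pair$index] & pair$label != "", , drop = FALSE]
  if (nrow(pair) == 0L) stop("no (window, label) pair to test")
  pair$m <- m_win[pair$index]
  pair$n_rest <- n_db - pair$m
  pair$k <- as.integer(k_lab[pair$label])
  pair$expected <- pair$k * pair$m / n_db
  pair$p_raw <- vapply(seq_len(nrow(pair)), function(i) {
    hypergeom_upper(pair$q_obs[i], pair$m[i], pair$n_rest[i], pair$k[i])
  }, 0)
  if (bh_family == "per_label") {
    pair$p_adj <- NA_real_
    for (lab in unique(pair$label)) {
      sel <- pair$label == lab
      pair$p_adj[sel] <- benjamini_hochberg(pair$p_raw[sel])
    }
  } else {
    pair$p_adj <- benjamini_hochberg(pair$p_raw)
  }
  out <- cbind(
    data.frame(chrom = grid$chrom[pair$index],
               start = grid$start[pair$index],
               end = grid$end[pair$index],
               level = level, stringsAsFactors = FALSE),
    pair[, c("index", "label", "q_obs", "m", "n_rest", "k", "expected",
             "p_raw", "p_adj")]
  )
  out <- out[order(out$index, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
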