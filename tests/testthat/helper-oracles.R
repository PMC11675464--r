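# Independent brute-force oracles used to validate the package's
# statistical and interval machinery. These deliberately avoid the code
# paths (and where possible the base functions) they check.

# exact binomial pmf from first principles (log-space for stability)
oracle_binom_pmf <- function(x, n, p) {
  exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p))
}

# two-sided exact binomial p: sum of all pmf values not exceeding the
# observed one (with the conventional 1e-7 relative tolerance)
oracle_binom_two_sided <- function(obs, n, p) {
  pmf <- oracle_binom_pmf(0:n, n, p)
  min(1, sum(pmf[pmf <= pmf[obs + 1] * (1 + 1e-7)]))
}

# upper-tail hypergeometric p by direct combinatorial summation
oracle_hyper_upper <- function(q, m, n_rest, k) {
  if (q <= 0) return(1)
  x <- q:min(m, k)
  sum(choose(m, x) * choose(n_rest, k - x)) / choose(m + n_rest, k)
}

# O(n^2) connected components of the overlap/gap graph: intervals chain
# when they overlap by >= 1 bp or are separated by < gap (strict)
oracle_components <- function(start, end, gap) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        linked <- start[j] < end[i] + gap & start[i] < end[j] + gap
        if (linked && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# per-base bitmap union length on a toy single-chromosome genome
oracle_coverage_bitmap <- function(start, end, genome_len) {
  hit <- logical(genome_len)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) hit[(start[i] + 1):end[i]] <- TRUE
  }
  sum(hit)
}

# short-hand record builder for QC tests
rec <- function(chrom, start, end, trait = "T", study = "S", ...) {
  qtl_records(chrom = chrom, start = start, end = end, trait_name = trait,
              study_id = study, ...)
}

toy_assembly <- function(lengths = c(chr1 = 1e7, chr2 = 5e6),
                         label = "toy") {
  genome_assembly(names(lengths), unname(lengths), label)
}

# small null-structured simulation: gene-proportional placement, no
# hotspots, no corruption; used by calibration-style tests
null_sim_config <- function(seed, n_qtl = 2000L, n_genes = 400L,
                            lengths = c(1e7, 1e7), ...) {
  sim_config(seed = seed, chromosome_lengths = lengths,
             n_genes = n_genes, n_qtl = n_qtl,
             placement_mixture = c(uniform = 0, gene = 1, hotspot = 0),
             snp_length_fraction = 1,
             duplicate_rate = 0, anomaly_rate = 0, overlength_rate = 0, ...)
}

# exact rejection-region mass of the two-sided exact binomial test at the
# given null, computed analytically (sorted-pmf cumulative sums)
attained_size <- function(n, p, alpha = 0.05) {
  d <- dbinom(0:n, n, p)
  ds <- sort(d)
  cs <- cumsum(ds)
  pv <- cs[findInterval(d * (1 + 1e-7), ds)]
  sum(d[pv < alpha])
}
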