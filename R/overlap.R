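#' Midpoint-centered unique QTL intervals
#'
#' For the resampling overlap test only unique QTL are used, each replaced
#' by a fixed-width interval (default 250 kbp) centered on its midpoint.
#' Intervals running past a chromosome end are shifted inward with their
#' length preserved; a chromosome shorter than the width clamps the
#' interval to the chromosome.
#'
#' @param records QC-passed QTL record data.frame.
#' @param assembly [genome_assembly()].
#' @param width interval width in bp (default 250,000).
#' @param key duplicate definition passed to [deduplicate()].
#' @return data.frame with columns `chrom`, `start`, `end`, `qtl_id`.
#' @export
prepare_unique_qtl <- function(records, assembly, width = 250e3,
                               key = "position_trait") {
  uni <- deduplicate(records, key)$kept
  if (nrow(uni) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), qtl_id = character()))
  }
  lens <- chrom_lengths(assembly)
  clen <- lens[uni$chrom]
  if (anyNA(clen)) stop("record chromosome absent from assembly")
  mid <- interval_midpoint(uni$start, uni$end)
  start <- mid - width %/% 2
  end <- start + width
  shift <- pmax(0, -start)
  start <- start + shift
  end <- end + shift
  shift <- pmax(0, end - clen)
  start <- pmax(0, start - shift)
  end <- pmin(clen, end - shift)
  data.frame(chrom = uni$chrom, start = unname(start), end = unname(end),
             qtl_id = uni$qtl_id, stringsAsFactors = FALSE)
}

#' Count query intervals overlapping a subject set
#'
#' Number of `query` intervals overlapping at least 1 bp of any `subject`
#' interval; each query interval is counted at most once no matter how many
#' subjects it touches.
#'
#' @param query,subject interval data.frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return integer count.
#' @export
count_qtl_overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) return(0L)
  q <- records_granges(query$chrom, query$start, query$end)
  s <- records_granges(subject$chrom, subject$start, subject$end)
  sum(GenomicRanges::countOverlaps(q, s, minoverlap = 1L) > 0L)
}

#' Resampling overlap-enrichment test
#'
#' Counts overlaps between (midpoint-centered unique) QTL intervals and a
#' gene set of interest, and compares the count against a null built by
#' resampling: either random gene sets of the same size drawn without
#' replacement from the gene universe (`"random_genes"`), or length-matched
#' segments placed uniformly on the assembly with redraws for placements
#' that would run past a chromosome end (`"random_segments"`). The
#' enrichment alternative is one-tailed upper; `alternative = "less"` tests
#' depletion. `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param qtl_intervals intervals from [prepare_unique_qtl()].
#' @param set a [gene_set()] of interest.
#' @param universe gene data.frame to resample from (must contain at least
#'   as many genes as the set; required for `"random_genes"`).
#' @param assembly [genome_assembly()] (required for `"random_segments"`).
#' @param n_perm number of permutations (default 1000).
#' @param null_mode `"random_genes"` or `"random_segments"`.
#' @param seed integer seed; results are bit-for-bit reproducible.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return object of class `perm_test_result`: list with
#'   `gene_set_label`, `observed_overlaps`, `null_overlaps`, `n_perm`,
#'   `p_value`, `z_score`, `null_mode`, `alternative`, `seed`.
#' @export
permutation_overlap_test <- function(qtl_intervals, set, universe = NULL,
                                     assembly = NULL, n_perm = 1000L,
                                     null_mode = c("random_genes",
                                                   "random_segments"),
                                     seed = 1L,
                                     alternative = c("greater", "less")) {
  null_mode <- match.arg(null_mode)
  alternative <- match.arg(alternative)
  if (!inherits(set, "gene_set")) set <- gene_set(set)
  members <- set$members
  if (nrow(members) == 0L) stop("empty gene set")
  observed <- count_qtl_overlaps(qtl_intervals, members)
  q <- records_granges(qtl_intervals$chrom, qtl_intervals$start,
                       qtl_intervals$end)
  null_counts <- if (null_mode == "random_genes") {
    if (is.null(universe)) stop("random_genes null needs a gene universe")
    if (nrow(members) > nrow(universe)) {
      stop("gene set larger than the universe")
    }
    u <- records_granges(universe$chrom, universe$start, universe$end)
    hits <- GenomicRanges::findOverlaps(q, u, minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    g <- nrow(members)
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sel <- sample.int(nrow(universe), g)
      length(unique(qh[sh %in% sel]))
    }, 0L))
  } else {
    if (is.null(assembly)) stop("random_segments null needs an assembly")
    seg_len <- members$end - members$start
    lens <- chrom_lengths(assembly)
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      chrom <- sample(names(lens), length(seg_len), replace = TRUE,
                      prob = lens)
      pos <- floor(stats::runif(length(seg_len), 0, lens[chrom]))
      # redraw placements that would extend past the chromosome end
      for (tries in 1:100) {
        bad <- pos + seg_len > lens[chrom]
        if (!any(bad)) break
        chrom[bad] <- sample(names(lens), sum(bad), replace = TRUE,
                             prob = lens)
        pos[bad] <- floor(stats::runif(sum(bad), 0, lens[chrom[bad]]))
      }
      rnd <- data.frame(chrom = chrom, start = pos, end = pos + seg_len)
      count_qtl_overlaps(qtl_intervals, rnd)
    }, 0L))
  }
  n_ge <- sum(null_counts >= observed)
  n_le <- sum(null_counts <= observed)
  p <- if (alternative == "greater") (1 + n_ge) / (n_perm + 1) else
    (1 + n_le) / (n_perm + 1)
  s <- stats::sd(null_counts)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mean(null_counts)) / s
  structure(list(gene_set_label = set$label, observed_overlaps = observed,
                 null_overlaps = null_counts, n_perm = as.integer(n_perm),
                 p_value = p, z_score = z, null_mode = null_mode,
                 alternative = alternative, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "<perm_test_result> %s [%s, %s]: observed %d, null %.2f +/- %.2f, p = %.4g\n",
    x$gene_set_label, x$null_mode, x$alternative, x$observed_overlaps,
    mean(x$null_overlaps), stats::sd(x$null_overlaps), x$p_value))
  invisible(x)
}

#' Rank candidate genes by number of QTL reports
#'
#' Counts records per non-empty associated gene symbol and returns the most
#' reported symbols (ties broken alphabetically), mirroring how "top
#' candidate gene" lists are assembled from QTL databases.
#'
#' @param records QTL record data.frame.
#' @param top_n number of symbols to return (default 30).
#' @return data.frame with columns `symbol`, `n_reports`, ranked.
#' @export
rank_candidate_genes <- function(records, top_n = 30L) {
  sym <- records$gene_symbol[!is.na(records$gene_symbol) &
                               records$gene_symbol != ""]
  if (length(sym) == 0L) {
    warning("no gene symbols present in the records")
    return(data.frame(symbol = character(), n_reports = integer()))
  }
  tab <- table(sym)
  out <- data.frame(symbol = names(tab),
                    n_reports = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_reports, out$symbol), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
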