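#' Tile an assembly into fixed-width windows
#'
#' Windows tile each chromosome without gaps or overlaps; every window
#' except possibly the last of a chromosome has length `window_size`, and a
#' final partial window is kept and flagged (`is_partial`). The standard
#' analysis scales are 0.25, 1, 2.5 and 5 Mbp.
#'
#' @param assembly [genome_assembly()].
#' @param window_size window width in bp (`> 0`).
#' @return a `window_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `index`, `is_partial` and zeroed counter columns `qtl_count`,
#'   `gene_count`, `snp_count`, `study_count`, `trait_count`; attributes
#'   `window_size` and `assembly`.
#' @export
#' @examples
#' asm <- genome_assembly("chr1", 2.5e6)
#' make_grid(asm, 1e6)
make_grid <- function(assembly, window_size) {
  stopifnot(inherits(assembly, "genome_assembly"),
            is.numeric(window_size), length(window_size) == 1L,
            window_size > 0)
  chroms <- assembly$chromosomes
  pieces <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    n <- ceiling(len / window_size)
    start <- window_size * (seq_len(n) - 1)
    data.frame(chrom = chroms$name[i], start = start,
               end = pmin(start + window_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid)) {
    grid <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  }
  grid$index <- seq_len(nrow(grid))
  grid$is_partial <- (grid$end - grid$start) < window_size
  for (col in c("qtl_count", "gene_count", "snp_count", "study_count",
                "trait_count")) {
    grid[[col]] <- 0L
  }
  structure(grid, window_size = window_size, assembly = assembly,
            class = c("window_grid", "data.frame"))
}

# Map feature midpoints to global window indices. Errors on chromosomes
# absent from the grid's assembly: QC is responsible for removing those.
assign_windows <- function(grid, chrom, mid) {
  assembly <- attr(grid, "assembly")
  w <- attr(grid, "window_size")
  lens <- chrom_lengths(assembly)
  if (!all(chrom %in% names(lens))) {
    stop("feature on a chromosome absent from the grid's assembly")
  }
  if (any(mid < 0 | mid >= lens[chrom])) {
    stop("feature midpoint outside its chromosome")
  }
  n_win <- ceiling(lens / w)
  offset <- stats::setNames(c(0, cumsum(n_win))[seq_along(n_win)],
                            names(n_win))
  as.integer(offset[chrom] + mid %/% w + 1)
}

#' Count features per window
#'
#' Each feature is assigned to exactly ONE window: the window containing its
#' midpoint (for SNPs, the position). This keeps per-window counts summing
#' to the input totals, which the finite-population hypergeometric test
#' requires. `study_count` and `trait_count` are the numbers of distinct
#' study ids and trait names among the window's assigned QTL.
#'
#' @param grid a [make_grid()] grid.
#' @param qtl QTL record data.frame (QC-passed).
#' @param genes optional gene data.frame ([read_genes()]).
#' @param snps optional SNP position data.frame (`chrom`, `pos`).
#' @return the grid with counter columns filled.
#' @export
count_features <- function(grid, qtl = NULL, genes = NULL, snps = NULL) {
  nw <- nrow(grid)
  if (!is.null(qtl) && nrow(qtl)) {
    idx <- assign_windows(grid, qtl$chrom,
                          interval_midpoint(qtl$start, qtl$end))
    grid$qtl_count <- tabulate(idx, nbins = nw)
    n_distinct <- function(values) {
      out <- integer(nw)
      agg <- tapply(values, idx, function(v) length(unique(v)))
      out[as.integer(names(agg))] <- as.integer(agg)
      out
    }
    grid$study_count <- n_distinct(qtl$study_id)
    grid$trait_count <- n_distinct(qtl$trait_name)
  }
  if (!is.null(genes) && nrow(genes)) {
    gidx <- assign_windows(grid, genes$chrom,
                           interval_midpoint(genes$start, genes$end))
    grid$gene_count <- tabulate(gidx, nbins = nw)
  }
  if (!is.null(snps) && nrow(snps)) {
    sidx <- assign_windows(grid, snps$chrom, snps$pos)
    grid$snp_count <- tabulate(sidx, nbins = nw)
  }
  grid
}

#' Per-chromosome summary of window QTL density
#'
#' Median and quartiles of the per-window QTL count for each chromosome.
#' With 1 Mbp windows the window count is the QTL density per Mbp. The
#' median uses the conventional mean-of-central-pair rule for even window
#' counts; quartiles are `stats::quantile()` type 7.
#'
#' @param grid a counted [window_grid][make_grid()].
#' @return data.frame with columns `chrom`, `n_windows`, `q1`, `median`,
#'   `q3`, `mean`.
#' @export
chromosome_density_summary <- function(grid) {
  res <- lapply(split(grid$qtl_count, grid$chrom), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n_windows = length(x), q1 = q[1], median = q[2], q3 = q[3],
               mean = mean(x))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(chrom = names(res), stringsAsFactors = FALSE), out)
  ord <- match(attr(grid, "assembly")$chromosomes$name, out$chrom)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of the genome covered by QTL
#'
#' Covered bp is the total length of the union of all QTL intervals,
#' computed with `GenomicRanges::reduce()`.
#'
#' @param qtl QC-passed QTL record data.frame.
#' @param assembly [genome_assembly()].
#' @return object of class `coverage_summary`: list with `species_label`,
#'   `covered_bp`, `total_bp`, `fraction`.
#' @export
genome_coverage <- function(qtl, assembly) {
  if (nrow(qtl) == 0L) {
    covered <- 0
  } else {
    gr <- records_granges(qtl$chrom, qtl$start, qtl$end, assembly)
    covered <- sum(as.numeric(
      GenomicRanges::width(GenomicRanges::reduce(gr))))
  }
  structure(list(species_label = assembly$species_label,
                 covered_bp = covered,
                 total_bp = assembly$total_length,
                 fraction = covered / assembly$total_length),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %s: %.0f / %.0f bp (%.2f%%)\n",
              x$species_label, x$covered_bp, x$total_bp, 100 * x$fraction))
  invisible(x)
}

#' Export window counts as a BED-compatible TSV
#'
#' @param grid a counted grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_counts <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
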