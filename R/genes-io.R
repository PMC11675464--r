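#' Read gene annotations from GFF3 or BED
#'
#' Thin wrapper around `rtracklayer::import()` that converts to the internal
#' 0-based half-open convention and keeps only the configured feature type
#' (GFF3 only; BED rows are taken as-is). Gene identifiers come from
#' `ID`/`gene_id` (GFF3) or the name column (BED); symbols from `Name`.
#'
#' @param path annotation file.
#' @param assembly optional [genome_assembly()] used to flag unresolvable
#'   records (dropped with a warning).
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param feature_type GFF3 feature type to retain (default `"gene"`). An
#'   input with no features of this type yields an empty table with a
#'   warning.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `symbol`, `biotype`.
#' @export
read_genes <- function(path, assembly = NULL,
                       format = c("auto", "gff3", "bed"),
                       feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    keep <- !is.na(mc$type) & as.character(mc$type) == feature_type
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    if (length(gr) == 0L) {
      warning("no '", feature_type, "' features in ", path)
    }
  }
  get_col <- function(nm) {
    if (nm %in% names(mc)) {
      v <- as.character(mc[[nm]])
      v[is.na(v)] <- ""
      v
    } else rep("", length(gr))
  }
  gene_id <- get_col("ID")
  alt_id <- get_col("gene_id")
  gene_id[gene_id == ""] <- alt_id[gene_id == ""]
  if (format == "bed") gene_id <- get_col("name")
  gene_id[gene_id == ""] <- sprintf("gene%06d", which(gene_id == ""))
  symbol <- if (format == "bed") get_col("name") else get_col("Name")
  genes <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    gene_id = gene_id,
    symbol = symbol,
    biotype = get_col("biotype"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_id values are not unique in ", path)
  }
  if (!is.null(assembly)) {
    bad <- !(genes$chrom %in% assembly$chromosomes$name)
    if (any(bad)) {
      warning(sum(bad), " gene(s) on chromosomes absent from the assembly ",
              "were dropped")
      genes <- genes[!bad, , drop = FALSE]
      rownames(genes) <- NULL
    }
  }
  genes
}

#' Write gene annotations as GFF3
#'
#' @param genes gene data.frame as returned by [read_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "qtlome", "gene",
                   format(genes$start + 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   ".", "+", ".",
                   paste0("ID=", genes$gene_id, ";Name=", genes$symbol,
                          ";biotype=", genes$biotype),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Define a gene set of interest
#'
#' @param members gene data.frame (subset of a gene annotation).
#' @param label set label, e.g. `"major"` or `"candidate"`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(members, label = "genes_of_interest") {
  if (!is.data.frame(members) || nrow(members) == 0L) {
    stop("gene set must contain at least one member")
  }
  structure(list(label = as.character(label), members = members),
            class = "gene_set")
}

#' Read a gene set from a symbol list or BED file
#'
#' A plain-text file of gene symbols (one per line, or first TSV column) is
#' resolved against a gene annotation; a BED file is taken as intervals
#' directly. Unresolved symbols are reported with a warning.
#'
#' @param path symbol list (TSV/TXT) or BED file.
#' @param genes gene annotation data.frame used to resolve symbols.
#' @param label set label.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, genes, label = basename(path)) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    members <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      gene_id = as.character(S4Vectors::mcols(gr)$name %||%
                               sprintf("set%04d", seq_along(gr))),
      symbol = as.character(S4Vectors::mcols(gr)$name %||% ""),
      biotype = "",
      stringsAsFactors = FALSE
    )
    return(gene_set(members, label))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  symbols <- unique(vapply(strsplit(lines, "\t"), `[[`, "", 1L))
  hit <- genes$symbol %in% symbols
  missing <- setdiff(symbols, genes$symbol)
  if (length(missing)) {
    warning(length(missing), " symbol(s) not found in the gene annotation: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!any(hit)) stop("no gene-set symbol resolved against the annotation")
  gene_set(genes[hit, , drop = FALSE], label)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$label, nrow(x$members)))
  invisible(x)
}

#' Read SNP positions from a simple TSV/BED position table
#'
#' Accepts two-column `chrom<TAB>position` tables (0-based positions) or
#' BED3; returns point positions.
#'
#' @param path input file.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_snp_positions <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    return(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      pos = GenomicRanges::start(gr) - 1,
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos"),
                          colClasses = c("character", "numeric"))
  df
}
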