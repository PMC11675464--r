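QTL_COLUMNS <- c("chrom", "start", "end", "qtl_id", "trait_name",
                 "trait_type", "trait_class", "study_id", "gene_symbol",
                 "source_line", "extra_attrs", "merged_from")

#' Build a QTL record table
#'
#' Internal coordinates are 0-based half-open everywhere in the package, so
#' interval length is always `end - start` and BED interoperability is
#' direct; GFF input/output converts at the boundary.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates (NA allowed: QC flags,
#'   rather than drops, records lacking coordinates).
#' @param qtl_id annotation identifiers (generated if missing).
#' @param trait_name,trait_type,trait_class phenotype labels; the class >
#'   type > trait hierarchy mirrors AnimalQTLdb's phenotypic categories.
#' @param study_id study identifier used for merge grouping (PubMed id in
#'   AnimalQTLdb files).
#' @param gene_symbol optional associated gene symbol.
#' @param source_line originating line number in the source file.
#' @param extra_attrs passthrough string of unmapped GFF attributes.
#' @param merged_from provenance: semicolon list of qtl_ids merged into the
#'   record by the QC cascade.
#' @return a data.frame with the canonical QTL columns.
#' @export
#' @examples
#' qtl_records("chr1", 0, 1000, trait_name = "Milk yield", study_id = "S1")
qtl_records <- function(chrom = character(), start = numeric(),
                        end = numeric(), qtl_id = NULL,
                        trait_name = "", trait_type = "", trait_class = "",
                        study_id = "", gene_symbol = "",
                        source_line = NA_integer_, extra_attrs = "",
                        merged_from = "") {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(qtl_id)) {
    qtl_id <- if (n) sprintf("QTL%06d", seq_len(n)) else character()
  }
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    qtl_id = rep_len(as.character(qtl_id), n),
    trait_name = rep_len(as.character(trait_name), n),
    trait_type = rep_len(as.character(trait_type), n),
    trait_class = rep_len(as.character(trait_class), n),
    study_id = rep_len(as.character(study_id), n),
    gene_symbol = rep_len(as.character(gene_symbol), n),
    source_line = rep_len(as.integer(source_line), n),
    extra_attrs = rep_len(as.character(extra_attrs), n),
    merged_from = rep_len(as.character(merged_from), n),
    stringsAsFactors = FALSE
  )
  df
}

#' Attribute-key map for the AnimalQTLdb GFF dialect
#'
#' Which GFF attribute keys carry the trait/study metadata is configurable
#' because the source dialect is not formally documented; unmapped keys are
#' preserved verbatim in the `extra_attrs` passthrough column.
#'
#' @param qtl_id,trait_name,trait_type,trait_class,study,gene GFF attribute
#'   keys holding each field.
#' @return named character vector used by [read_qtl_gff()] and
#'   [write_qtl_gff()].
#' @export
qtl_attr_map <- function(qtl_id = "QTL_ID", trait_name = "trait",
                         trait_type = "trait_type",
                         trait_class = "trait_class",
                         study = "PUBMED_ID", gene = "gene_ID") {
  c(qtl_id = qtl_id, trait_name = trait_name, trait_type = trait_type,
    trait_class = trait_class, study = study, gene = gene)
}

.parse_gff_attrs <- function(s) {
  s <- sub(";\\s*$", "", s)
  if (is.na(s) || s == "" || s == ".") return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  keys <- sub("=.*$", "", parts)
  vals <- ifelse(grepl("=", parts), sub("^[^=]*=", "", parts), "")
  stats::setNames(vals, keys)
}

#' Read QTL annotations from an AnimalQTLdb-dialect GFF file
#'
#' One QTL per data line; the 9th column carries trait and study metadata.
#' Coordinates are converted from GFF's 1-based inclusive convention to the
#' internal 0-based half-open convention. Records lacking coordinates (`.` in
#' the start/end columns) are kept with `NA` coordinates so the QC cascade
#' can count them; lines with fewer than 9 columns are counted as malformed
#' (attribute `n_malformed`) and reported with a warning, never fatal.
#'
#' @param path GFF file path.
#' @param assembly optional [genome_assembly()]; when given, a logical
#'   `resolvable` column marks records whose chromosome exists in it.
#' @param attr_map a [qtl_attr_map()].
#' @return QTL record data.frame (see [qtl_records()]) in file order, with
#'   attribute `n_malformed`.
#' @export
read_qtl_gff <- function(path, assembly = NULL, attr_map = qtl_attr_map()) {
  if (!file.exists(path)) stop("QTL gff not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  malformed <- nf < 9L
  if (any(malformed)) {
    warning(sum(malformed), " malformed gff line(s) skipped in ", path)
  }
  fields <- fields[!malformed]
  line_no <- line_no[!malformed]
  coord <- function(x) {
    x[x %in% c(".", "")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  start1 <- coord(vapply(fields, `[[`, "", 4L))
  end1 <- coord(vapply(fields, `[[`, "", 5L))
  attrs <- lapply(vapply(fields, `[[`, "", 9L), .parse_gff_attrs)
  pick <- function(key) {
    vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else "", "")
  }
  extra <- vapply(attrs, function(a) {
    rest <- a[!(names(a) %in% attr_map)]
    if (!length(rest)) "" else paste(names(rest), rest, sep = "=",
                                     collapse = ";")
  }, "")
  qtl_id <- pick(attr_map[["qtl_id"]])
  qtl_id[qtl_id == ""] <- sprintf("QTL_line%d", line_no[qtl_id == ""])
  rec <- qtl_records(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start1 - 1,
    end = end1,
    qtl_id = qtl_id,
    trait_name = pick(attr_map[["trait_name"]]),
    trait_type = pick(attr_map[["trait_type"]]),
    trait_class = pick(attr_map[["trait_class"]]),
    study_id = pick(attr_map[["study"]]),
    gene_symbol = pick(attr_map[["gene"]]),
    source_line = line_no,
    extra_attrs = extra
  )
  if (!is.null(assembly)) {
    rec$resolvable <- rec$chrom %in% assembly$chromosomes$name
  }
  attr(rec, "n_malformed") <- sum(malformed)
  rec
}

#' Write QTL records to an AnimalQTLdb-dialect GFF file
#'
#' Inverse of [read_qtl_gff()]: internal 0-based half-open coordinates are
#' exported 1-based inclusive; `NA` coordinates become `.`. Re-importing the
#' file reproduces the records (coordinate conversion is an involution).
#'
#' @param records QTL record data.frame.
#' @param path output path.
#' @param attr_map a [qtl_attr_map()].
#' @param source value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_qtl_gff <- function(records, path, attr_map = qtl_attr_map(),
                          source = "qtlome") {
  co <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                 trim = TRUE))
  attrs <- paste0(
    attr_map[["qtl_id"]], "=", records$qtl_id,
    ";", attr_map[["trait_name"]], "=", records$trait_name,
    ";", attr_map[["trait_type"]], "=", records$trait_type,
    ";", attr_map[["trait_class"]], "=", records$trait_class,
    ";", attr_map[["study"]], "=", records$study_id,
    ";", attr_map[["gene"]], "=", records$gene_symbol,
    ifelse(nzchar(records$extra_attrs), paste0(";", records$extra_attrs), "")
  )
  lines <- paste(records$chrom, source, "QTL",
                 co(records$start + 1), co(records$end),
                 ".", ".", ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read QTL records as the package's internal TSV
#'
#' Field-for-field round trip: `read_qtl_tsv(write_qtl_tsv(x, f))` is
#' identical to `x` for every canonical column.
#'
#' @param records QTL record data.frame.
#' @param path file path.
#' @return `write_qtl_tsv` returns `path` invisibly; `read_qtl_tsv` returns
#'   the record data.frame.
#' @export
write_qtl_tsv <- function(records, path) {
  utils::write.table(records[intersect(QTL_COLUMNS, names(records))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_qtl_tsv
#' @export
read_qtl_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                          quote = "", comment.char = "",
                          colClasses = c(
                            chrom = "character", start = "numeric",
                            end = "numeric", qtl_id = "character",
                            trait_name = "character",
                            trait_type = "character",
                            trait_class = "character",
                            study_id = "character",
                            gene_symbol = "character",
                            source_line = "integer",
                            extra_attrs = "character",
                            merged_from = "character"),
                          stringsAsFactors = FALSE)
  for (col in c("trait_name", "trait_type", "trait_class", "study_id",
                "gene_symbol", "extra_attrs", "merged_from")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
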