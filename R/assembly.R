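#' Construct a genome assembly
#'
#' A `genome_assembly` is the coordinate space of one species: an ordered set
#' of chromosome names and lengths. Chromosome proportions of the total
#' length are the null probabilities of the chromosome-level binomial
#' enrichment test.
#'
#' @param name character vector of chromosome names (unique).
#' @param length numeric vector of chromosome lengths in bp (all `> 0`).
#' @param species_label optional species tag carried into summaries.
#' @return an object of class `genome_assembly`: a list with elements
#'   `species_label`, `chromosomes` (data.frame `name`, `length`) and
#'   `total_length`.
#' @export
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
genome_assembly <- function(name, length, species_label = "unspecified") {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) == 0L) stop("assembly must contain at least one chromosome")
  if (length(name) != length(length)) stop("name/length lengths differ")
  if (anyDuplicated(name)) stop("duplicate chromosome name in assembly")
  if (anyNA(length) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(
    list(
      species_label = as.character(species_label),
      chromosomes = data.frame(name = name, length = length,
                               stringsAsFactors = FALSE),
      total_length = sum(length)
    ),
    class = "genome_assembly"
  )
}

#' Read a chromosome-size table
#'
#' Expects a two-column TSV (`name<TAB>length`), the conventional
#' "chrom.sizes" layout. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param species_label optional species tag.
#' @return a [genome_assembly()].
#' @export
read_assembly <- function(path, species_label = "unspecified") {
  if (!file.exists(path)) stop("assembly file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("assembly file is empty: ", path)
  parts <- strsplit(lines, "\t| +")
  if (any(vapply(parts, length, 0L) < 2L)) {
    stop("assembly lines must be 'name<TAB>length'")
  }
  name <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  genome_assembly(name, len, species_label)
}

#' Write a chromosome-size table
#'
#' @param assembly a [genome_assembly()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  utils::write.table(assembly$chromosomes, path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d chromosomes, %.0f bp total\n",
              x$species_label, nrow(x$chromosomes), x$total_length))
  invisible(x)
}

# length lookup vector (named) for internal use
chrom_lengths <- function(assembly) {
  stats::setNames(assembly$chromosomes$length, assembly$chromosomes$name)
}
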