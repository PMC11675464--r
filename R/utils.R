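#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic operations in the package draw their seed from a single
#' master seed plus the name of the operation, so independent analyses get
#' decorrelated streams while the whole pipeline stays reproducible from one
#' integer.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the consumer (e.g. `"r_qtl_genes"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "placement")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  h <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Interval midpoint under the 0-based half-open convention; floor keeps the
# result an integer base position strictly inside [start, end).
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

# Convert internal 0-based half-open records to GRanges (1-based inclusive).
records_granges <- function(chrom, start, end, assembly = NULL) {
  if (anyNA(start) || anyNA(end)) {
    stop("records with missing coordinates cannot be converted to ranges")
  }
  si <- NULL
  if (!is.null(assembly)) {
    si <- GenomeInfoDb::Seqinfo(
      seqnames = assembly$chromosomes$name,
      seqlengths = assembly$chromosomes$length
    )
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  if (!is.null(si)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
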