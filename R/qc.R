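#' Quality-control configuration
#'
#' Thresholds of the QC cascade. Defaults follow the standard curation rules
#' for AnimalQTLdb-style QTL annotations: drop intervals longer than 10 Mbp,
#' merge same-study/same-trait annotations that overlap by at least 1 bp or
#' are separated by less than 500 kbp, cap merged spans at 1 Mbp (falling
#' back to the densest 1 Mbp windows covering at least 30% of the span), and
#' standardize final sizes into the 250 kbp - 1 Mbp band.
#'
#' @param max_qtl_length maximum accepted QTL length in bp.
#' @param merge_gap same-key records closer than this many bp are chained.
#'   The rule is strict: a gap exactly equal to `merge_gap` does not merge.
#' @param merge_span_cap cluster spans at most this long collapse to a
#'   single record; longer spans trigger the densest-window fallback.
#' @param min_std_length,max_std_length size-standardization band in bp.
#' @param min_span_coverage fraction of a long cluster span that the
#'   selected densest windows must cover.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(max_qtl_length = 10e6, merge_gap = 500e3,
                      merge_span_cap = 1e6, min_std_length = 250e3,
                      max_std_length = 1e6, min_span_coverage = 0.30) {
  cfg <- list(max_qtl_length = max_qtl_length, merge_gap = merge_gap,
              merge_span_cap = merge_span_cap,
              min_std_length = min_std_length,
              max_std_length = max_std_length,
              min_span_coverage = min_span_coverage)
  if (!(0 < min_std_length && min_std_length <= max_std_length &&
        max_std_length <= max_qtl_length)) {
    stop("need 0 < min_std_length <= max_std_length <= max_qtl_length")
  }
  if (!(0 < min_span_coverage && min_span_coverage <= 1)) {
    stop("min_span_coverage must be in (0, 1]")
  }
  structure(cfg, class = "qc_config")
}

.empty_ledger <- function() {
  structure(list(input_total = 0L, output_total = 0L,
                 missing_coordinates = 0L, anomalous_position = 0L,
                 out_of_bounds = 0L, over_length = 0L,
                 duplicate = 0L, merged_away = 0L),
            class = "qc_ledger")
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat("<qc_ledger>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert a QC ledger to a data.frame (for TSV export)
#' @param ledger a `qc_ledger`.
#' @return two-column data.frame (`reason`, `count`).
#' @export
ledger_table <- function(ledger) {
  data.frame(reason = names(ledger), count = unlist(ledger, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Remove records with anomalous coordinates, out-of-bounds positions or
#' excessive length
#'
#' Removal rules are applied in a fixed order, and the first matching rule
#' wins, so ledger categories are disjoint:
#' 1. `missing_coordinates` (NA start/end) or `anomalous_position`
#'    (`start >= end` or `start < 0`);
#' 2. `out_of_bounds`: chromosome absent from the assembly, or the interval
#'    extends past the chromosome end;
#' 3. `over_length`: length greater than `max_qtl_length`.
#'
#' Filters never raise on record content: bad records are counted and
#' returned, not errors.
#'
#' @param records QTL record data.frame.
#' @param assembly [genome_assembly()].
#' @param cfg [qc_config()].
#' @return list with `kept` (records), `removed` (records plus a `reason`
#'   column) and `ledger` (partial [qc_config()] counts).
#' @export
filter_anomalies <- function(records, assembly, cfg = qc_config()) {
  lens <- chrom_lengths(assembly)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  miss <- is.na(records$start) | is.na(records$end)
  reason[miss] <- "missing_coordinates"
  anom <- !miss & (records$start >= records$end | records$start < 0)
  reason[anom] <- "anomalous_position"
  open <- is.na(reason)
  known <- records$chrom %in% names(lens)
  oob <- open & (!known |
                   records$end > ifelse(known, lens[records$chrom], -Inf))
  reason[oob] <- "out_of_bounds"
  open <- is.na(reason)
  over <- open & (records$end - records$start > cfg$max_qtl_length)
  reason[over] <- "over_length"
  ledger <- .empty_ledger()
  ledger$input_total <- n
  for (r in c("missing_coordinates", "anomalous_position", "out_of_bounds",
              "over_length")) {
    ledger[[r]] <- sum(reason == r, na.rm = TRUE)
  }
  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep]
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  ledger$output_total <- nrow(kept)
  list(kept = kept, removed = removed, ledger = ledger)
}

.dedup_key <- function(records, key = c("position_trait", "position")) {
  key <- match.arg(key)
  if (key == "position_trait") {
    paste(records$chrom, records$start, records$end, records$trait_name,
          records$study_id, sep = "\r")
  } else {
    paste(records$chrom, records$start, records$end, sep = "\r")
  }
}

#' Collapse repeated annotations
#'
#' Records sharing chromosome, coordinates, trait name and study id are
#' repeated annotations: only the first occurrence (input order) is kept.
#' The alternative `key = "position"` deduplicates on coordinates alone,
#' giving the looser "unique QTL" accounting.
#'
#' @param records QTL record data.frame (anomalies already removed).
#' @param key duplicate definition, `"position_trait"` (default) or
#'   `"position"`.
#' @return list with `kept` and `n_removed`.
#' @export
deduplicate <- function(records, key = c("position_trait", "position")) {
  k <- .dedup_key(records, match.arg(key))
  dup <- duplicated(k)
  kept <- records[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, n_removed = sum(dup))
}

#' Select the densest 1 Mbp windows of an over-long merge cluster
#'
#' Candidate windows are `max_std_length`-wide tiles anchored at the cluster
#' span start with a `merge_gap` step; each candidate is scored by the number
#' of member QTL whose midpoint falls in it. Windows are selected greedily by
#' descending score (ties: leftmost first), skipping candidates that overlap
#' an already-selected window, until the summed selected length reaches
#' `min_span_coverage` of the span length.
#'
#' @param member_start,member_end member interval coordinates (0-based
#'   half-open); at least one member required.
#' @param cfg [qc_config()]. The cluster span (min start to max end) must
#'   exceed `merge_span_cap`.
#' @return data.frame of selected windows (`start`, `end`), sorted by start.
#' @export
densest_windows <- function(member_start, member_end, cfg = qc_config()) {
  if (length(member_start) == 0L) stop("cluster has no members")
  span_start <- min(member_start)
  span_end <- max(member_end)
  span_len <- span_end - span_start
  if (span_len <= cfg$merge_span_cap) {
    stop("densest_windows requires a cluster span above merge_span_cap")
  }
  w <- cfg$max_std_length
  step <- cfg$merge_gap
  starts <- if (span_len >= w) {
    span_start + step * (0:floor((span_len - w) / step))
  } else {
    span_start
  }
  mids <- interval_midpoint(member_start, member_end)
  score <- vapply(starts, function(s) sum(mids >= s & mids < s + w), 0L)
  ord <- order(-score, starts)
  selected <- numeric(0)
  covered <- 0
  target <- cfg$min_span_coverage * span_len
  for (i in ord) {
    s <- starts[i]
    if (any(s < selected + w & s + w > selected)) next
    selected <- c(selected, s)
    covered <- covered + w
    if (covered >= target) break
  }
  selected <- sort(selected)
  data.frame(start = selected, end = selected + w)
}

#' Merge same-study, same-trait QTL clusters
#'
#' Within each (chromosome, study, trait) group, single-linkage chaining
#' joins records that overlap by at least 1 bp or are separated by less than
#' `merge_gap` (strict). Each cluster collapses to one record spanning
#' `[min start, max end)` when the span does not exceed `merge_span_cap`;
#' longer clusters are replaced by one record per [densest_windows()]
#' window. Merged records keep the metadata of the cluster's first member
#' (leftmost by start, then end, then qtl_id — so the result is independent
#' of input order) and list all merged ids in `merged_from`.
#'
#' @param records deduplicated QTL record data.frame.
#' @param cfg [qc_config()].
#' @return list with `merged` (records, sorted by chrom/start) and
#'   `n_merged_away` (input count minus output count).
#' @export
cluster_and_merge <- function(records, cfg = qc_config()) {
  if (nrow(records) == 0L) return(list(merged = records, n_merged_away = 0L))
  grp <- paste(records$chrom, records$study_id, records$trait_name,
               sep = "\r")
  out <- vector("list", length(unique(grp)))
  gi <- 0L
  for (g in split(seq_len(nrow(records)), grp)) {
    sub <- records[g, , drop = FALSE]
    ord <- order(sub$start, sub$end, sub$qtl_id)
    sub <- sub[ord, , drop = FALSE]
    # chain: start a new cluster when the gap to the running max end of the
    # records already chained is >= merge_gap (overlaps give non-positive
    # gaps and always chain)
    prev_max_end <- cummax(sub$end)
    new_cluster <- c(TRUE, sub$start[-1] -
                       prev_max_end[-nrow(sub)] >= cfg$merge_gap)
    cl_id <- cumsum(new_cluster)
    for (cl in split(seq_len(nrow(sub)), cl_id)) {
      m <- sub[cl, , drop = FALSE]
      gi <- gi + 1L
      if (nrow(m) == 1L) {
        out[[gi]] <- m
        next
      }
      span_start <- min(m$start)
      span_end <- max(m$end)
      prov <- paste(m$qtl_id, collapse = ";")
      base <- m[1L, , drop = FALSE]
      if (span_end - span_start <= cfg$merge_span_cap) {
        base$start <- span_start
        base$end <- span_end
        base$merged_from <- prov
        out[[gi]] <- base
      } else {
        win <- densest_windows(m$start, m$end, cfg)
        rep_base <- base[rep(1L, nrow(win)), , drop = FALSE]
        rep_base$start <- win$start
        rep_base$end <- win$end
        rep_base$qtl_id <- paste0(base$qtl_id, "_w", seq_len(nrow(win)))
        rep_base$merged_from <- prov
        out[[gi]] <- rep_base
      }
    }
  }
  merged <- do.call(rbind, out[seq_len(gi)])
  merged <- merged[order(merged$chrom, merged$start, merged$end,
                         merged$trait_name, merged$study_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, n_merged_away = nrow(records) - nrow(merged))
}

#' Standardize QTL sizes into the configured band
#'
#' Records shorter than `min_std_length` are expanded, and records longer
#' than `max_std_length` trimmed, to the band limit, always centered on the
#' record midpoint. Intervals that would extend past a chromosome boundary
#' are shifted inward with their length preserved; only when the chromosome
#' itself is shorter than the standard length is the record clamped to the
#' whole chromosome.
#'
#' @param records merged QTL record data.frame.
#' @param assembly [genome_assembly()].
#' @param cfg [qc_config()].
#' @return records with standardized coordinates.
#' @export
standardize_sizes <- function(records, assembly, cfg = qc_config()) {
  if (nrow(records) == 0L) return(records)
  lens <- chrom_lengths(assembly)
  clen <- lens[records$chrom]
  if (anyNA(clen)) stop("record chromosome absent from assembly")
  len <- records$end - records$start
  target <- ifelse(len < cfg$min_std_length, cfg$min_std_length,
                   ifelse(len > cfg$max_std_length, cfg$max_std_length, len))
  mid <- interval_midpoint(records$start, records$end)
  new_start <- mid - target %/% 2
  new_end <- new_start + target
  # shift inward at chromosome boundaries, length preserved
  shift_right <- pmax(0, -new_start)
  new_start <- new_start + shift_right
  new_end <- new_end + shift_right
  shift_left <- pmax(0, new_end - clen)
  new_start <- new_start - shift_left
  new_end <- new_end - shift_left
  # chromosome shorter than the standard length: clamp to the chromosome
  new_start <- pmax(new_start, 0)
  new_end <- pmin(new_end, clen)
  records$start <- unname(new_start)
  records$end <- unname(new_end)
  records
}

#' Run the full quality-control cascade
#'
#' Stages, in order: anomaly/bounds/length filters ([filter_anomalies()]),
#' duplicate removal ([deduplicate()]), then same-key merging
#' ([cluster_and_merge()]) and size standardization ([standardize_sizes()])
#' iterated to a fixed point. The iteration makes the cascade idempotent:
#' standardization can move same-key records back within merging distance,
#' so a single pass would not be stable under re-analysis.
#'
#' The returned ledger satisfies the conservation identity
#' `input_total = output_total + missing_coordinates + anomalous_position +
#' out_of_bounds + over_length + duplicate + merged_away`.
#'
#' @param records parsed QTL record data.frame.
#' @param assembly [genome_assembly()].
#' @param cfg [qc_config()].
#' @param dedup_key duplicate definition passed to [deduplicate()].
#' @param max_iterations safety cap on merge/standardize fixed-point
#'   iterations.
#' @return list with `records` (clean records), `removed` (records removed
#'   by the filters, with reasons) and `ledger` (a `qc_ledger`).
#' @export
qc_cascade <- function(records, assembly, cfg = qc_config(),
                       dedup_key = "position_trait", max_iterations = 25L) {
  flt <- filter_anomalies(records, assembly, cfg)
  ledger <- flt$ledger
  dd <- deduplicate(flt$kept, dedup_key)
  ledger$duplicate <- dd$n_removed
  cur <- dd$kept
  merged_away <- 0L
  for (it in seq_len(max_iterations)) {
    mg <- cluster_and_merge(cur, cfg)
    merged_away <- merged_away + mg$n_merged_away
    std <- standardize_sizes(mg$merged, assembly, cfg)
    if (identical_intervals(std, cur)) {
      cur <- std
      break
    }
    cur <- std
    if (it == max_iterations) {
      warning("QC merge/standardize did not reach a fixed point in ",
              max_iterations, " iterations")
    }
  }
  ledger$merged_away <- merged_away
  ledger$output_total <- nrow(cur)
  ledger$input_total <- nrow(records)
  list(records = cur, removed = flt$removed, ledger = ledger)
}

identical_intervals <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  key <- function(x) sort(paste(x$chrom, x$start, x$end, x$trait_name,
                                x$study_id, sep = "\r"))
  identical(key(a), key(b))
}
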