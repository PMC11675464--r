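asm10 <- genome_assembly("chr1", 1e7)

test_that("anomaly filters remove records in the documented order with
           disjoint ledger reasons", {
  asm <- toy_assembly()
  records <- rbind(
    rec("chr1", 0, 0),                 # zero-length: anomalous_position
    rec("chr1", NA, NA),               # missing coordinates
    rec("chr1", -5, 100),              # negative start: anomalous
    rec("chr1", 9.999e6, 1.0004e7),    # ends 5 kbp past chr1: out_of_bounds
    rec("chr9", 0, 100),               # unknown chromosome: out_of_bounds
    rec("chr1", 0, 12e6),              # 12 Mbp: over_length? no - oob first
    rec("chr2", 0, 12e5),              # clean
    rec("chr1", 1e6, 1e6 + 12e6)       # would be over_length AND oob
  )
  res <- filter_anomalies(records, asm, qc_config())
  led <- res$ledger
  expect_equal(led$missing_coordinates, 1L)
  expect_equal(led$anomalous_position, 2L)
  # 12 Mbp records on chr1 (1e7 bp) exceed the chromosome: rule 2 wins
  expect_equal(led$out_of_bounds, 4L)
  expect_equal(led$over_length, 0L)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(led$input_total,
               led$output_total + led$missing_coordinates +
                 led$anomalous_position + led$out_of_bounds +
                 led$over_length)
  expect_setequal(unique(res$removed$reason),
                  c("missing_coordinates", "anomalous_position",
                    "out_of_bounds"))

  # a 12 Mbp record on a 20 Mbp chromosome is over_length proper
  big <- genome_assembly("chr1", 2e7)
  res2 <- filter_anomalies(rec("chr1", 0, 12e6), big, qc_config())
  expect_equal(res2$ledger$over_length, 1L)
})

test_that("deduplication collapses repeats on the position+trait+study key", {
  two <- rbind(rec("chr1", 100, 200), rec("chr1", 100, 200))
  res <- deduplicate(two)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$n_removed, 1L)

  # same interval, different trait: both kept
  difft <- rbind(rec("chr1", 100, 200, trait = "A"),
                 rec("chr1", 100, 200, trait = "B"))
  expect_equal(deduplicate(difft)$n_removed, 0L)
  expect_equal(deduplicate(difft, key = "position")$n_removed, 1L)

  # n copies -> 1 kept, n - 1 removed
  five <- do.call(rbind, replicate(5, rec("chr1", 7, 9), simplify = FALSE))
  expect_equal(deduplicate(five)$n_removed, 4L)
})

test_that("cluster_and_merge joins same-key records across sub-threshold
           gaps and respects the strict gap and key rules", {
  cfg <- qc_config()
  # gap 450 kbp < 500 kbp: merged into one record spanning both
  pair <- rbind(rec("chr1", 100e3, 200e3), rec("chr1", 650e3, 700e3))
  m <- cluster_and_merge(pair, cfg)
  expect_equal(nrow(m$merged), 1L)
  expect_equal(m$merged$start, 100e3)
  expect_equal(m$merged$end, 700e3)
  expect_equal(m$n_merged_away, 1L)
  expect_match(m$merged$merged_from, ";")

  # gap exactly 500 kbp: NOT merged (strict inequality)
  pair2 <- rbind(rec("chr1", 100e3, 200e3), rec("chr1", 700e3, 750e3))
  expect_equal(nrow(cluster_and_merge(pair2, cfg)$merged), 2L)

  # overlapping but different studies: not merged
  pair3 <- rbind(rec("chr1", 0, 300e3, study = "S1"),
                 rec("chr1", 100e3, 400e3, study = "S2"))
  expect_equal(nrow(cluster_and_merge(pair3, cfg)$merged), 2L)
})

test_that("densest-window fallback scores midpoints over anchored tiles and
           selects greedily to the coverage floor", {
  cfg <- qc_config()
  # span 3 Mbp, all 10 midpoints in the first tile: that single tile
  # (1/3 >= 30%) is selected
  start <- seq(0, 90e3, length.out = 10)
  end <- start + 20e3
  end[10] <- 3e6                      # stretch the span to 3 Mbp
  win <- densest_windows(start, end, cfg)
  expect_equal(nrow(win), 1L)
  expect_equal(win$start, 0)
  expect_equal(win$end, 1e6)

  # span 10 Mbp, uniform members: greedy takes non-overlapping 1 Mbp tiles
  # until 3 Mbp (>= 30% of 10 Mbp) is covered
  start <- seq(0, 9.95e6, by = 50e3)
  end <- pmin(start + 50e3, 1e7)
  win <- densest_windows(start, end, cfg)
  expect_equal(nrow(win), 3L)
  expect_equal(sum(win$end - win$start), 3e6)
  expect_true(all(win$start == sort(win$start)))
  # selected windows never overlap
  expect_true(all(diff(win$start) >= 1e6))

  expect_error(densest_windows(numeric(), numeric(), cfg), "no members")
  expect_error(densest_windows(0, 5e5, cfg), "above merge_span_cap")
})

test_that("merged clusters above the span cap are replaced by densest
           windows", {
  cfg <- qc_config()
  # 10 records chained by < 500 kbp gaps spanning 2.55 Mbp, most mass in
  # the first Mbp: the fallback picks the single densest tile (score 6),
  # which already covers >= 30% of the span
  start <- c(0, 100e3, 150e3, 200e3, 280e3, 700e3, 1.15e6, 1.6e6, 2.05e6,
             2.5e6)
  records <- rec("chr1", start, start + 50e3)
  m <- cluster_and_merge(records, cfg)
  expect_equal(nrow(m$merged), 1L)
  expect_equal(c(m$merged$start, m$merged$end), c(0, 1e6))
  expect_gte(m$merged$end - m$merged$start, 0.3 * 2.55e6)
  expect_equal(m$n_merged_away, 9L)
})

test_that("size standardization centers on midpoints and shifts inward at
           chromosome boundaries", {
  cfg <- qc_config()
  # 1 bp record at 1,234,567: expanded to the 250 kbp interval around it
  r <- standardize_sizes(rec("chr1", 1234567, 1234568), asm10, cfg)
  expect_equal(r$start, 1109567)
  expect_equal(r$end, 1359567)

  # 5 Mbp record: trimmed to the central 1 Mbp
  r <- standardize_sizes(rec("chr1", 2e6, 7e6), asm10, cfg)
  expect_equal(r$end - r$start, 1e6)
  expect_equal((r$start + r$end) / 2, 4.5e6)

  # 300 kbp record already inside the band: unchanged
  r <- standardize_sizes(rec("chr1", 1e6, 1.3e6), asm10, cfg)
  expect_equal(c(r$start, r$end), c(1e6, 1.3e6))

  # record near the chromosome start is shifted, not truncated
  r <- standardize_sizes(rec("chr1", 10, 11), asm10, cfg)
  expect_equal(c(r$start, r$end), c(0, 250e3))

  # chromosome shorter than the standard length: clamped to the chromosome
  tiny <- genome_assembly("chrS", 100e3)
  r <- standardize_sizes(rec("chrS", 10, 20), tiny, cfg)
  expect_equal(c(r$start, r$end), c(0, 100e3))
})

test_that("the QC cascade conserves counts, is idempotent and is
           order-independent", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_qtl = 300L, n_genes = 200L,
                      chromosome_lengths = c(3e7, 2e7, 1.5e7),
                      duplicate_rate = 0.2, anomaly_rate = 0.1,
                      overlength_rate = 0.05)
    b <- simulate_qtlome(cfg)
    res <- qc_cascade(b$records, b$assembly)
    led <- res$ledger
    expect_equal(led$input_total,
                 led$output_total + led$missing_coordinates +
                   led$anomalous_position + led$out_of_bounds +
                   led$over_length + led$duplicate + led$merged_away)
    # idempotence: re-running the cascade on its output changes nothing
    res2 <- qc_cascade(res$records, b$assembly)
    expect_equal(res2$ledger$output_total, led$output_total)
    expect_equal(sort(paste(res2$records$chrom, res2$records$start,
                            res2$records$end)),
                 sort(paste(res$records$chrom, res$records$start,
                            res$records$end)))
    expect_equal(sum(unlist(res2$ledger[c(
      "missing_coordinates", "anomalous_position", "out_of_bounds",
      "over_length", "duplicate", "merged_away")])), 0L)

    # order independence: shuffled input gives the same clean interval set
    shuf <- b$records[sample.int(nrow(b$records)), , drop = FALSE]
    res3 <- qc_cascade(shuf, b$assembly)
    expect_equal(sort(paste(res3$records$chrom, res3$records$start,
                            res3$records$end, res3$records$trait_name,
                            res3$records$study_id)),
                 sort(paste(res$records$chrom, res$records$start,
                            res$records$end, res$records$trait_name,
                            res$records$study_id)))
    expect_equal(unclass(res3$ledger), unclass(led))
  }
})

test_that("merged spans match the brute-force connected-components oracle
           on random same-key groups", {
  cfg <- qc_config()
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    start <- sort(sample.int(5e6, n))
    end <- start + sample.int(8e5, n)
    comp <- oracle_components(start, end, cfg$merge_gap)
    spans <- vapply(split(seq_len(n), comp), function(ix) {
      c(min(start[ix]), max(end[ix]))
    }, numeric(2))
    m <- cluster_and_merge(rec("chr1", start, end), cfg)
    # every merged output lies inside one oracle component span, and every
    # component is represented
    got_spans <- unique(vapply(seq_len(nrow(m$merged)), function(i) {
      hit <- which(spans[1, ] <= m$merged$start[i] &
                     m$merged$end[i] <= spans[2, ])
      expect_length(hit, 1L)
      hit
    }, 0L))
    expect_setequal(got_spans, seq_len(ncol(spans)))
    # clusters whose span fits the cap collapse to exactly the span
    for (k in seq_len(ncol(spans))) {
      if (spans[2, k] - spans[1, k] <= cfg$merge_span_cap) {
        sel <- m$merged$start >= spans[1, k] & m$merged$end <= spans[2, k]
        expect_equal(sum(sel), 1L)
        expect_equal(c(m$merged$start[sel], m$merged$end[sel]),
                     unname(spans[, k]))
      }
    }
  }
})

test_that("standardized record lengths always land in the configured band", {
  cfg <- qc_config()
  set.seed(7)
  start <- sample.int(9e6, 200)
  end <- pmin(start + 10^runif(200, 0, 6.9), 1e7)
  out <- standardize_sizes(rec("chr1", start, floor(end)), asm10, cfg)
  len <- out$end - out$start
  expect_true(all(len >= cfg$min_std_length & len <= cfg$max_std_length))
  expect_true(all(out$start >= 0 & out$end <= 1e7))
})
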