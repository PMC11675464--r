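#' Configuration for the synthetic QTLome generator
#'
#' Defines a synthetic species: a multi-chromosome genome with non-uniform
#' gene density, a study and class > type > trait phenotype hierarchy, a QTL
#' placement law mixing uniform-by-length and gene-proportional components
#' with optional multiplicative window hotspots, and corruption rates for
#' the repeated annotations, coordinate anomalies and over-long intervals
#' that real QTL databases contain. Every planted quantity is recorded in a
#' truth object so downstream quality control and enrichment analyses can be
#' validated exactly.
#'
#' Defaults emulate a mid-sized livestock QTL database: six chromosomes
#' with log-normal lengths around 80 Mbp, about 7 genes per Mbp, 60 studies,
#' a 4-class / 10-type / 40-trait hierarchy, 5,000 QTL (60% of them 1 bp
#' SNP-type records), 15% injected duplicates and 5% coordinate anomalies.
#'
#' @param seed master seed; substreams (`genome`, `placement`, `labels`,
#'   `corruption`, `shuffle`) are derived from it by name.
#' @param n_chromosomes number of chromosomes (used when
#'   `chromosome_lengths` is NULL).
#' @param chromosome_lengths explicit lengths in bp, or NULL to sample
#'   log-normal(`length_meanlog`, `length_sdlog`).
#' @param length_meanlog,length_sdlog log-normal parameters of sampled
#'   chromosome lengths.
#' @param n_genes number of genes.
#' @param gene_density_segments segments per chromosome of the
#'   piecewise-constant gene intensity.
#' @param gene_density_sdlog log-normal spread of the per-segment intensity
#'   multipliers (0 gives uniform gene density).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths.
#' @param n_studies number of studies; study sizes are log-normal.
#' @param trait_hierarchy named integer vector `c(classes=, types=,
#'   traits=)`.
#' @param n_qtl number of clean QTL placed.
#' @param placement_mixture named fractions `c(uniform=, gene=, hotspot=)`
#'   summing to 1. The `hotspot` fraction places QTL directly inside
#'   hotspot windows; independent of it, each hotspot's `lambda`
#'   multiplies the uniform+gene base intensity inside its window.
#' @param hotspots NULL or data.frame with columns `chrom`, `start`
#'   (window start, width `hotspot_width`), `lambda` (> 1), and optionally
#'   `trait` (forced trait label for QTL landing in the window).
#' @param hotspot_width hotspot window width (default 1 Mbp, the regional
#'   analysis scale).
#' @param qtl_length_range log-uniform length range of non-SNP QTL, bp.
#' @param snp_length_fraction fraction of QTL emitted as 1 bp records.
#' @param duplicate_rate,anomaly_rate,overlength_rate corruption fractions
#'   of `n_qtl`, each in `[0, 1)`.
#' @param gene_symbol_rate fraction of gene-placed QTL that carry the
#'   source gene's symbol.
#' @param max_qtl_length length bound used when injecting over-long
#'   records; match the QC `max_qtl_length` when validating ledgers.
#' @param species_label species tag.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 6L,
                       chromosome_lengths = NULL,
                       length_meanlog = log(8e7), length_sdlog = 0.35,
                       n_genes = 3000L,
                       gene_density_segments = 8L,
                       gene_density_sdlog = 0.6,
                       gene_length_meanlog = log(2e4),
                       gene_length_sdlog = 0.8,
                       n_studies = 60L,
                       trait_hierarchy = c(classes = 4L, types = 10L,
                                           traits = 40L),
                       n_qtl = 5000L,
                       placement_mixture = c(uniform = 0.4, gene = 0.6,
                                             hotspot = 0),
                       hotspots = NULL,
                       hotspot_width = 1e6,
                       qtl_length_range = c(1e3, 5e6),
                       snp_length_fraction = 0.6,
                       duplicate_rate = 0.15,
                       anomaly_rate = 0.05,
                       overlength_rate = 0.02,
                       gene_symbol_rate = 0.3,
                       max_qtl_length = 10e6,
                       species_label = "synthetic") {
  cfg <- as.list(environment())
  mix <- placement_mixture
  if (!all(c("uniform", "gene", "hotspot") %in% names(mix)) ||
      abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop("placement_mixture must be non-negative fractions ",
         "(uniform, gene, hotspot) summing to 1")
  }
  if (!is.null(hotspots)) {
    if (!all(c("chrom", "start", "lambda") %in% names(hotspots))) {
      stop("hotspots need columns chrom, start, lambda")
    }
    if (any(hotspots$lambda <= 1)) stop("hotspot lambda must exceed 1")
  }
  if (mix[["hotspot"]] > 0 && is.null(hotspots)) {
    stop("hotspot mixture mass requires a hotspots table")
  }
  rates <- c(duplicate_rate, anomaly_rate, overlength_rate)
  if (any(rates < 0 | rates >= 1)) stop("corruption rates must be in [0, 1)")
  if (qtl_length_range[2] > max_qtl_length) {
    stop("qtl_length_range must stay within max_qtl_length")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome assembly and gene annotation
#'
#' Chromosome lengths are taken verbatim or sampled log-normal; genes are
#' placed by a piecewise-constant inhomogeneous intensity (per-chromosome
#' segments with log-normal multipliers), so gene density varies along and
#' between chromosomes as in real annotations. Deterministic under the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `assembly` ([genome_assembly()]), `genes` (data.frame)
#'   and `gene_density` (segment table with multipliers).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "genome"), {
    lens <- cfg$chromosome_lengths
    if (is.null(lens)) {
      lens <- round(stats::rlnorm(cfg$n_chromosomes, cfg$length_meanlog,
                                  cfg$length_sdlog))
    }
    lens <- pmax(round(lens), 2L)
    asm <- genome_assembly(sprintf("chr%d", seq_along(lens)), lens,
                           cfg$species_label)
    # piecewise-constant gene intensity
    segs <- do.call(rbind, lapply(seq_along(lens), function(i) {
      k <- max(1L, cfg$gene_density_segments)
      bounds <- round(seq(0, lens[i], length.out = k + 1))
      data.frame(chrom = asm$chromosomes$name[i],
                 start = bounds[-(k + 1)], end = bounds[-1],
                 multiplier = stats::rlnorm(k, 0, cfg$gene_density_sdlog),
                 stringsAsFactors = FALSE)
    }))
    segs <- segs[segs$end > segs$start, , drop = FALSE]
    weight <- (segs$end - segs$start) * segs$multiplier
    if (cfg$n_genes > sum(lens)) stop("more genes than representable")
    seg_idx <- sample.int(nrow(segs), cfg$n_genes, replace = TRUE,
                          prob = weight)
    pos <- floor(stats::runif(cfg$n_genes, segs$start[seg_idx],
                              segs$end[seg_idx]))
    glen <- pmax(1, round(stats::rlnorm(cfg$n_genes, cfg$gene_length_meanlog,
                                        cfg$gene_length_sdlog)))
    chrom <- segs$chrom[seg_idx]
    end <- pmin(pos + glen, chrom_lengths(asm)[chrom])
    genes <- data.frame(chrom = chrom, start = pos, end = unname(end),
                        stringsAsFactors = FALSE)
    genes <- genes[order(match(genes$chrom, asm$chromosomes$name),
                         genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    genes$symbol <- sprintf("GENE%04d", seq_len(nrow(genes)))
    genes$biotype <- "protein_coding"
    rownames(genes) <- NULL
    list(assembly = asm, genes = genes, gene_density = segs)
  })
}

# lambda multiplier at given midpoints (1 outside hotspot windows)
.hotspot_lambda <- function(cfg, chrom, mid) {
  lam <- rep(1, length(mid))
  hs <- cfg$hotspots
  if (is.null(hs)) return(lam)
  for (i in seq_len(nrow(hs))) {
    inside <- chrom == hs$chrom[i] & mid >= hs$start[i] &
      mid < hs$start[i] + cfg$hotspot_width
    lam[inside] <- pmax(lam[inside], hs$lambda[i])
  }
  lam
}

.hotspot_trait <- function(cfg, chrom, mid) {
  out <- rep(NA_character_, length(mid))
  hs <- cfg$hotspots
  if (is.null(hs) || is.null(hs$trait)) return(out)
  for (i in seq_len(nrow(hs))) {
    if (is.na(hs$trait[i]) || hs$trait[i] == "") next
    inside <- chrom == hs$chrom[i] & mid >= hs$start[i] &
      mid < hs$start[i] + cfg$hotspot_width
    out[inside] <- hs$trait[i]
  }
  out
}

# draw n midpoints from the base mixture, then accept/reject so the final
# intensity is the base multiplied by the hotspot lambdas
.draw_midpoints <- function(cfg, assembly, genes, n) {
  lens <- chrom_lengths(assembly)
  hs <- cfg$hotspots
  lam_max <- if (is.null(hs)) 1 else max(hs$lambda)
  mix <- cfg$placement_mixture
  chrom <- character(0)
  mid <- numeric(0)
  while (length(mid) < n) {
    todo <- max(64L, ceiling((n - length(mid)) * 1.5))
    comp <- sample(c("uniform", "gene", "hotspot"), todo, replace = TRUE,
                   prob = mix[c("uniform", "gene", "hotspot")])
    c_new <- character(todo)
    m_new <- numeric(todo)
    nu <- sum(comp == "uniform")
    if (nu) {
      cs <- sample(names(lens), nu, replace = TRUE, prob = lens)
      c_new[comp == "uniform"] <- cs
      m_new[comp == "uniform"] <- floor(stats::runif(nu, 0, lens[cs]))
    }
    ng <- sum(comp == "gene")
    if (ng) {
      gi <- sample.int(nrow(genes), ng, replace = TRUE)
      c_new[comp == "gene"] <- genes$chrom[gi]
      m_new[comp == "gene"] <- floor(stats::runif(ng, genes$start[gi],
                                                  genes$end[gi]))
    }
    nh <- sum(comp == "hotspot")
    if (nh) {
      hi <- sample.int(nrow(hs), nh, replace = TRUE,
                       prob = hs$lambda * cfg$hotspot_width)
      c_new[comp == "hotspot"] <- hs$chrom[hi]
      m_new[comp == "hotspot"] <- floor(stats::runif(
        nh, hs$start[hi], pmin(hs$start[hi] + cfg$hotspot_width,
                               lens[hs$chrom[hi]])))
    }
    if (lam_max > 1) {
      accept <- stats::runif(todo) <
        .hotspot_lambda(cfg, c_new, m_new) / lam_max
      # hotspot-component draws are direct placements, always kept
      accept <- accept | comp == "hotspot"
      c_new <- c_new[accept]
      m_new <- m_new[accept]
    }
    chrom <- c(chrom, c_new)
    mid <- c(mid, m_new)
  }
  list(chrom = chrom[seq_len(n)], mid = mid[seq_len(n)])
}

#' Simulate a QTL database with planted structure and known truth
#'
#' Places `n_qtl` clean QTL by the configured placement mixture (with
#' hotspot windows multiplying the base intensity by their `lambda`),
#' assigns studies and hierarchical trait labels (hotspots may force a
#' trait, enabling trait-enrichment validation), draws lengths from a
#' mixture of 1 bp SNP-type records and log-uniform intervals, then injects
#' duplicates, coordinate anomalies (missing coordinates, `start >= end` or
#' negative starts, out-of-bounds/off-chromosome positions) and over-long
#' records at the configured rates. Clean records are guaranteed unique on
#' the (chrom, start, end, trait, study) key, so a QC ledger computed from
#' the emitted records recovers the planted counts exactly.
#'
#' @param cfg a [sim_config()].
#' @param assembly,genes output of [simulate_genome()].
#' @return list with `records` (shuffled clean + corrupted records) and
#'   `truth` (class `synthetic_truth`): planted hotspot table, per-reason
#'   corruption counts, the clean record table, and study/trait assignment
#'   tables.
#' @export
simulate_qtl <- function(cfg, assembly, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- chrom_lengths(assembly)
  if (!is.null(cfg$hotspots)) {
    bad <- !(cfg$hotspots$chrom %in% names(lens)) |
      cfg$hotspots$start < 0 |
      cfg$hotspots$start >= lens[cfg$hotspots$chrom]
    if (any(bad)) stop("hotspot window outside the assembly")
  }
  n <- cfg$n_qtl
  placed <- with_seed(derive_seed(cfg$seed, "placement"), {
    pts <- .draw_midpoints(cfg, assembly, genes, n)
    is_snp <- stats::runif(n) < cfg$snp_length_fraction
    len <- ifelse(is_snp, 1,
                  round(10^stats::runif(n, log10(cfg$qtl_length_range[1]),
                                        log10(cfg$qtl_length_range[2]))))
    start <- pts$mid - len %/% 2
    end <- start + len
    shift <- pmax(0, -start)
    start <- start + shift; end <- end + shift
    shift <- pmax(0, end - lens[pts$chrom])
    start <- pmax(0, start - shift); end <- pmin(lens[pts$chrom], end - shift)
    list(chrom = pts$chrom, start = unname(start), end = unname(end),
         mid = pts$mid, is_snp = is_snp)
  })
  labels <- with_seed(derive_seed(cfg$seed, "labels"), {
    th <- cfg$trait_hierarchy
    traits <- data.frame(
      trait = sprintf("Trait_%02d", seq_len(th[["traits"]])),
      type = sprintf("Type_%02d",
                     sample.int(th[["types"]], th[["traits"]],
                                replace = TRUE)),
      stringsAsFactors = FALSE
    )
    type_class <- sprintf("Class_%d",
                          sample.int(th[["classes"]], th[["types"]],
                                     replace = TRUE))
    traits$class <- type_class[as.integer(sub("Type_", "", traits$type))]
    trait_w <- stats::rlnorm(nrow(traits), 0, 1)
    study_w <- stats::rlnorm(cfg$n_studies, 0, 1)
    ti <- sample.int(nrow(traits), n, replace = TRUE, prob = trait_w)
    si <- sample.int(cfg$n_studies, n, replace = TRUE, prob = study_w)
    forced <- .hotspot_trait(cfg, placed$chrom, placed$mid)
    trait_name <- ifelse(is.na(forced), traits$trait[ti], forced)
    fi <- match(trait_name, traits$trait)
    fi[is.na(fi)] <- ti[is.na(fi)]  # forced labels outside the table
    sym <- rep("", n)
    give <- stats::runif(n) < cfg$gene_symbol_rate
    near <- vapply(seq_len(n), function(i) {
      if (!give[i]) return(NA_integer_)
      on_chrom <- which(genes$chrom == placed$chrom[i])
      if (!length(on_chrom)) return(NA_integer_)
      gm <- interval_midpoint(genes$start[on_chrom], genes$end[on_chrom])
      on_chrom[which.min(abs(gm - placed$mid[i]))]
    }, 0L)
    sym[!is.na(near)] <- genes$symbol[near[!is.na(near)]]
    list(trait_name = trait_name,
         trait_type = traits$type[fi],
         trait_class = traits$class[fi],
         study_id = sprintf("STUDY%04d", si),
         gene_symbol = sym,
         trait_table = traits)
  })
  clean <- qtl_records(
    chrom = placed$chrom, start = placed$start, end = placed$end,
    qtl_id = sprintf("QTL%06d", seq_len(n)),
    trait_name = labels$trait_name, trait_type = labels$trait_type,
    trait_class = labels$trait_class, study_id = labels$study_id,
    gene_symbol = labels$gene_symbol
  )
  # enforce key uniqueness so injected duplicates are the only duplicates
  clean <- with_seed(derive_seed(cfg$seed, "uniqueness"), {
    for (tries in 1:50) {
      key <- .dedup_key(clean)
      dup <- which(duplicated(key))
      if (!length(dup)) break
      wiggle <- sample(1:1000, length(dup), replace = TRUE)
      room_right <- unname(lens[clean$chrom[dup]] - clean$end[dup])
      shift <- pmin(wiggle, room_right)
      # no room rightward: nudge left instead (length preserved)
      shift[shift < 1] <- -pmin(wiggle, clean$start[dup])[shift < 1]
      clean$start[dup] <- clean$start[dup] + shift
      clean$end[dup] <- clean$end[dup] + shift
    }
    clean
  })
  corrupted <- with_seed(derive_seed(cfg$seed, "corruption"), {
    n_dup <- round(cfg$duplicate_rate * n)
    n_anom <- round(cfg$anomaly_rate * n)
    n_missing <- ceiling(n_anom / 3)
    n_anom_pos <- ceiling((n_anom - n_missing) / 2)
    n_oob <- n_anom - n_missing - n_anom_pos
    n_over <- round(cfg$overlength_rate * n)
    next_id <- n
    new_ids <- function(k) {
      ids <- sprintf("QTL%06d", next_id + seq_len(k))
      next_id <<- next_id + k
      ids
    }
    take <- function(k) clean[sample.int(n, k, replace = TRUE), ,
                              drop = FALSE]
    out <- list()
    if (n_dup) {
      dup <- take(n_dup)
      dup$qtl_id <- new_ids(n_dup)
      out$dup <- dup
    }
    if (n_missing) {
      m <- take(n_missing)
      m$start <- NA_real_; m$end <- NA_real_
      m$qtl_id <- new_ids(n_missing)
      out$missing <- m
    }
    if (n_anom_pos) {
      a <- take(n_anom_pos)
      zero_len <- seq_len(n_anom_pos) %% 2 == 0
      a$end[zero_len] <- a$start[zero_len]          # start >= end
      a$start[!zero_len] <- -abs(a$start[!zero_len]) - 1  # negative start
      a$qtl_id <- new_ids(n_anom_pos)
      out$anom <- a
    }
    if (n_oob) {
      o <- take(n_oob)
      off <- seq_len(n_oob) %% 2 == 0
      o$chrom[off] <- "chrUn"                        # unknown chromosome
      beyond <- !off
      o$end[beyond] <- lens[o$chrom[beyond]] +
        sample(1e3:1e5, sum(beyond), replace = TRUE)
      o$start[beyond] <- o$end[beyond] - sample(1e3:1e4, sum(beyond),
                                                replace = TRUE)
      o$qtl_id <- new_ids(n_oob)
      out$oob <- o
    }
    if (n_over) {
      host <- names(lens)[lens > 1.2 * cfg$max_qtl_length]
      if (!length(host)) {
        stop("no chromosome long enough to host over-length records; ",
             "lower max_qtl_length or lengthen chromosomes")
      }
      ov <- take(n_over)
      ov$chrom <- sample(host, n_over, replace = TRUE)
      olen <- round(cfg$max_qtl_length *
                      stats::runif(n_over, 1.05, 1.15))
      olen <- pmin(olen, lens[ov$chrom] - 1)
      ov$start <- floor(stats::runif(n_over, 0, lens[ov$chrom] - olen))
      ov$end <- ov$start + olen
      ov$qtl_id <- new_ids(n_over)
      out$over <- ov
    }
    list(records = if (length(out)) do.call(rbind, out) else clean[0, ],
         counts = list(duplicate = n_dup, missing_coordinates = n_missing,
                       anomalous_position = n_anom_pos,
                       out_of_bounds = n_oob, over_length = n_over))
  })
  all_rec <- rbind(clean, corrupted$records)
  all_rec <- with_seed(derive_seed(cfg$seed, "shuffle"),
                       all_rec[sample.int(nrow(all_rec)), , drop = FALSE])
  all_rec$source_line <- seq_len(nrow(all_rec))
  rownames(all_rec) <- NULL
  truth <- structure(
    c(corrupted$counts,
      list(n_clean = n, hotspots = cfg$hotspots,
           clean_records = clean, trait_table = labels$trait_table,
           study_table = as.data.frame(table(study_id = clean$study_id),
                                       stringsAsFactors = FALSE))),
    class = "synthetic_truth")
  list(records = all_rec, truth = truth)
}

#' Simulate a complete synthetic QTLome bundle
#'
#' Convenience wrapper: [simulate_genome()] then [simulate_qtl()].
#'
#' @param cfg a [sim_config()].
#' @return list with `assembly`, `genes`, `gene_density`, `records`,
#'   `truth`.
#' @export
simulate_qtlome <- function(cfg = sim_config()) {
  g <- simulate_genome(cfg)
  q <- simulate_qtl(cfg, g$assembly, g$genes)
  c(g, q)
}

#' Write a synthetic bundle to disk
#'
#' Emits the file formats the pipeline consumes: `assembly.tsv`
#' (chromosome sizes), `genes.gff3`, `qtl.gff` (AnimalQTLdb dialect) and
#' truth tables (`truth_counts.tsv`, `hotspots.tsv` when present).
#'
#' @param bundle output of [simulate_qtlome()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(assembly = file.path(dir, "assembly.tsv"),
             genes = file.path(dir, "genes.gff3"),
             qtl = file.path(dir, "qtl.gff"),
             truth_counts = file.path(dir, "truth_counts.tsv"))
  write_assembly(bundle$assembly, paths[["assembly"]])
  write_genes_gff3(bundle$genes, paths[["genes"]])
  write_qtl_gff(bundle$records, paths[["qtl"]])
  tc <- bundle$truth[c("duplicate", "missing_coordinates",
                       "anomalous_position", "out_of_bounds", "over_length",
                       "n_clean")]
  utils::write.table(
    data.frame(quantity = names(tc), count = unlist(tc, use.names = FALSE)),
    paths[["truth_counts"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth$hotspots)) {
    paths[["hotspots"]] <- file.path(dir, "hotspots.tsv")
    utils::write.table(bundle$truth$hotspots, paths[["hotspots"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}
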