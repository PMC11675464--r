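#' Build a pipeline run configuration
#'
#' Collects paths, QC thresholds, window scales, permutation settings and
#' the master seed for an end-to-end run. Can also be loaded from a YAML
#' file with [read_run_config()].
#'
#' @param assembly_path chromosome-size TSV.
#' @param qtl_path AnimalQTLdb-dialect QTL GFF.
#' @param genes_path gene annotation (GFF3 or BED).
#' @param out_dir output directory.
#' @param species_label species tag.
#' @param snp_path optional SNP position table.
#' @param gene_set_paths optional named character vector of gene-set files
#'   (symbol lists or BED).
#' @param qc list of [qc_config()] overrides.
#' @param window_scales window widths in bp.
#' @param trait_levels trait-hierarchy levels to test.
#' @param n_permutations permutations for correlation and overlap tests.
#' @param seed master seed.
#' @param bh_family BH family mode for the trait tests.
#' @param overlap_null null mode for the overlap test.
#' @param unique_width width of midpoint-centered unique QTL intervals.
#' @param dedup_key duplicate definition.
#' @param attr_map a [qtl_attr_map()].
#' @return object of class `run_config`.
#' @export
run_config <- function(assembly_path, qtl_path, genes_path, out_dir,
                       species_label = "unspecified",
                       snp_path = NULL, gene_set_paths = NULL,
                       qc = list(),
                       window_scales = c(250e3, 1e6, 2.5e6, 5e6),
                       trait_levels = c("trait_class", "trait_type",
                                        "trait_name"),
                       n_permutations = 1000L, seed = 1L,
                       bh_family = "per_label",
                       overlap_null = "random_genes",
                       unique_width = 250e3,
                       dedup_key = "position_trait",
                       attr_map = qtl_attr_map()) {
  cfg <- as.list(environment())
  cfg$qc <- do.call(qc_config, qc)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gene_set_paths)) y$gene_set_paths <- unlist(y$gene_set_paths)
  if (!is.null(y$window_scales)) y$window_scales <- as.numeric(y$window_scales)
  do.call(run_config, y)
}

.log_stage <- function(stage, t0) {
  message(sprintf("[qtlome] %-12s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full QTLome analysis pipeline
#'
#' Executes, in order: input parsing, the QC cascade, window counting at
#' every configured scale, genome- and window-level correlations,
#' chromosome / window / trait enrichment tests, and (when gene sets are
#' supplied) the resampling overlap tests, writing one TSV per result plus
#' a machine-readable JSON manifest with input/output checksums, the seed
#' and the QC ledger. Rerunning with an identical configuration and inputs
#' is byte-identical. Any stage error aborts with the stage name.
#'
#' @param cfg a [run_config()] or the path of its YAML file.
#' @return invisible named character vector: the output manifest (paths).
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  emit <- function(name, df) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    .write_tsv(df, path)
    out[[name]] <<- path
  }
  t0 <- as.numeric(Sys.time())

  inputs <- stop_stage("io", {
    assembly <- read_assembly(cfg$assembly_path, cfg$species_label)
    qtl_raw <- read_qtl_gff(cfg$qtl_path, assembly, cfg$attr_map)
    list(assembly = assembly, qtl_raw = qtl_raw)
  })
  .log_stage("io", t0)

  qc <- stop_stage("qc", {
    res <- qc_cascade(inputs$qtl_raw, inputs$assembly, cfg$qc,
                      dedup_key = cfg$dedup_key)
    emit("qc_ledger", ledger_table(res$ledger))
    if (nrow(res$removed)) emit("qc_removed", res$removed)
    write_qtl_tsv(res$records, file.path(cfg$out_dir, "qtl_clean.tsv"))
    out[["qtl_clean"]] <- file.path(cfg$out_dir, "qtl_clean.tsv")
    res
  })
  .log_stage("qc", t0)

  win <- stop_stage("windowing", {
    genes <- read_genes(cfg$genes_path, inputs$assembly)
    snps <- if (!is.null(cfg$snp_path)) read_snp_positions(cfg$snp_path)
    grids <- lapply(cfg$window_scales, function(w) {
      g <- count_features(make_grid(inputs$assembly, w), qc$records, genes,
                          snps)
      emit(sprintf("window_counts_%sbp",
                   format(w, scientific = FALSE, trim = TRUE)),
           as.data.frame(g))
      g
    })
    names(grids) <- format(cfg$window_scales, scientific = FALSE,
                           trim = TRUE)
    emit("chromosome_density",
         chromosome_density_summary(grids[[which.min(abs(
           cfg$window_scales - 1e6))]]))
    cov <- genome_coverage(qc$records, inputs$assembly)
    emit("genome_coverage",
         data.frame(species = cov$species_label, covered_bp = cov$covered_bp,
                    total_bp = cov$total_bp, fraction = cov$fraction))
    list(genes = genes, grids = grids, coverage = cov)
  })
  .log_stage("windowing", t0)

  stop_stage("correlate", {
    emit("correlations_genome",
         genome_level_correlations(qc$records, win$genes, inputs$assembly,
                                   cfg$n_permutations, cfg$seed))
    mat <- window_level_matrix(win$grids, n_perm = cfg$n_permutations,
                               seed = cfg$seed)
    emit("correlations_windows", mat)
    emit("correlations_windows_rbar", rbar(mat))
    grid1 <- win$grids[[which.min(abs(cfg$window_scales - 1e6))]]
    emit("correlations_study_trait",
         qtl_vs_study_trait_correlation(grid1, cfg$n_permutations, cfg$seed))
  })
  .log_stage("correlate", t0)

  stop_stage("enrich", {
    emit("chromosome_enrichment",
         chromosome_enrichment(qc$records, inputs$assembly))
    grid1 <- win$grids[[which.min(abs(cfg$window_scales - 1e6))]]
    emit("window_enrichment", window_enrichment(grid1))
    for (level in cfg$trait_levels) {
      emit(paste0("trait_enrichment_", level),
           trait_window_enrichment(grid1, qc$records, level,
                                   bh_family = cfg$bh_family))
    }
  })
  .log_stage("enrich", t0)

  if (!is.null(cfg$gene_set_paths)) {
    stop_stage("overlap", {
      uq <- prepare_unique_qtl(qc$records, inputs$assembly,
                               cfg$unique_width, cfg$dedup_key)
      rows <- lapply(names(cfg$gene_set_paths), function(nm) {
        gs <- read_gene_set(cfg$gene_set_paths[[nm]], win$genes, nm)
        pt <- permutation_overlap_test(
          uq, gs, universe = win$genes, assembly = inputs$assembly,
          n_perm = cfg$n_permutations, null_mode = cfg$overlap_null,
          seed = derive_seed(cfg$seed, paste0("overlap:", nm)))
        data.frame(gene_set = nm, n_genes = nrow(gs$members),
                   observed = pt$observed_overlaps,
                   null_mean = mean(pt$null_overlaps),
                   null_sd = stats::sd(pt$null_overlaps),
                   z_score = pt$z_score, p_value = pt$p_value,
                   null_mode = pt$null_mode, stringsAsFactors = FALSE)
      })
      emit("overlap_tests", do.call(rbind, rows))
    })
    .log_stage("overlap", t0)
  }

  stop_stage("report", {
    ranked <- rank_candidate_genes(qc$records)
    if (nrow(ranked)) emit("candidate_genes", ranked)
    manifest <- list(
      package_version = as.character(utils::packageVersion("qtlome")),
      seed = cfg$seed,
      species_label = cfg$species_label,
      inputs = as.list(tools::md5sum(c(cfg$assembly_path, cfg$qtl_path,
                                       cfg$genes_path))),
      ledger = unclass(qc$ledger),
      outputs = as.list(tools::md5sum(unlist(out)))
    )
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out[["manifest"]] <- manifest_path
  })
  .log_stage("report", t0)
  invisible(unlist(out))
}
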