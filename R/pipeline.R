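#' Pipeline configuration
#'
#' Bundles the analysis thresholds (all defaults as used throughout the
#' package), the simulation scenario, and output paths.
#'
#' @param outdir Output directory for report files.
#' @param n_fragments Fragments per simulated sample.
#' @param n_replicates Replicates per tissue x protocol condition.
#' @param tissues Tissues to simulate.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param min_overlap Minimum exonic overlap for gene assignment (bp).
#' @param expressed_rpkm Detection threshold (RPKM, strict `>`).
#' @param corr_filter_rpkm Low-expression filter for correlations.
#' @param intron_rate_min_rpkm Expression filter for the intron-rate
#'   statistic.
#' @param fc_threshold,alpha,de_rpkm_floor Differential-expression criteria.
#' @param fc_flag Concordance large-discrepancy flag on |log2FC|.
#' @param library_size `"counted"` or `"mapped"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("prepcompare_run_"),
                       n_fragments = 5e4, n_replicates = 2,
                       tissues = c("blood", "colon"), seed = 1L,
                       min_overlap = 25L, expressed_rpkm = 0.1,
                       corr_filter_rpkm = 0.5, intron_rate_min_rpkm = 1,
                       fc_threshold = 2, alpha = 0.05, de_rpkm_floor = 0.5,
                       fc_flag = 4, library_size = "counted") {
  stopifnot(min_overlap > 0, expressed_rpkm > 0, corr_filter_rpkm > 0,
            intron_rate_min_rpkm > 0, fc_threshold > 0, alpha > 0,
            de_rpkm_floor > 0, fc_flag > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic protocol-comparison pipeline
#'
#' Simulates the configured tissue x protocol x replicate grid, counts every
#' sample, computes all summary metrics (read categories, detection classes,
#' biotype breakdowns, usable-read fractions and extra depth, correlations,
#' per-biotype concordance, intron rates) and the differential-expression
#' comparison per tissue, and writes TSV/JSON reports plus a run manifest to
#' `config$outdir`. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @param annotation Optional pre-built [generate_annotation()] result.
#' @return Invisibly, a list with all in-memory results and `files`, the
#'   vector of written report paths.
#' @export
run_pipeline <- function(config = run_config(), annotation = NULL) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  annotation <- annotation %||% generate_annotation()
  models <- annotation$models

  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      protocol = c("polyA", "riboZ"),
                      tissue = config$tissues,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%d",
                            ifelse(grid$tissue == "blood", "B", "C"),
                            ifelse(grid$protocol == "polyA", "M", "T"),
                            grid$replicate)
  grid$seed <- config$seed * 1000L + seq_len(nrow(grid))

  sims <- list(); per_sample <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- protocol_sim_config(protocol = grid$protocol[i],
                              tissue = grid$tissue[i],
                              n_fragments = config$n_fragments,
                              seed = grid$seed[i])
    sims[[grid$sample_id[i]]] <- simulate_fragments(annotation, sc)
    per_sample[[grid$sample_id[i]]] <- count_sample(
      sims[[grid$sample_id[i]]]$fragments, models,
      sample_id = grid$sample_id[i], min_overlap = config$min_overlap)
  }
  ct <- build_count_table(per_sample, samples = grid)
  expr <- expression_matrix(ct, models, library_size = config$library_size)

  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # per-sample QC metrics and read categories
  qc <- cbind(grid[, c("sample_id", "tissue", "protocol", "replicate")],
              ct$categories[match(grid$sample_id, ct$categories$sample_id),
                            -1, drop = FALSE],
              counted_library_size = ct$counted_library_size[grid$sample_id],
              usable_fraction = usable_fraction(
                ct$counted_library_size[grid$sample_id],
                ct$total_sequenced_reads[grid$sample_id]))
  emit(qc, "table1_metrics.tsv")
  catlong <- ct$categories
  catlong[c("exonic", "intronic", "intergenic")] <-
    catlong[c("exonic", "intronic", "intergenic")] / catlong$n_unique_fragments
  emit(catlong[, c("sample_id", "exonic", "intronic", "intergenic")],
       "fig2a_categories.tsv")

  # merged per tissue x protocol; detection classes and biotype breakdowns
  group <- paste(grid$tissue, grid$protocol, sep = "_")
  merged <- merge_replicates(ct$exonic[, grid$sample_id, drop = FALSE], group,
                             ct$counted_library_size[grid$sample_id])
  len <- models$genes$exonic_length[match(rownames(merged$counts),
                                          models$genes$gene_id)]
  merged_rpkm <- compute_rpkm(merged$counts, len, merged$library_size)
  merged_cpm <- compute_cpm(merged$counts, merged$library_size)

  det <- list(); fig3 <- NULL; usable <- NULL
  for (tis in config$tissues) {
    cls <- detection_classes(merged_rpkm[, paste0(tis, "_polyA")],
                             merged_rpkm[, paste0(tis, "_riboZ")],
                             threshold = config$expressed_rpkm)
    det[[tis]] <- cls
    for (lv in levels(cls)) {
      ids <- rownames(merged_rpkm)[cls == lv]
      bb <- biotype_breakdown(models, gene_ids = ids)
      fig3 <- rbind(fig3, cbind(tissue = tis, class = lv, bb))
    }
  }
  emit(fig3, "fig3_detection_biotype.tsv")

  reads_bb <- NULL
  for (s in grid$sample_id) {
    bb <- biotype_breakdown(models, counts = setNames(ct$exonic[, s],
                                                      rownames(ct$exonic)))
    reads_bb <- rbind(reads_bb, cbind(sample_id = s, bb))
  }
  emit(reads_bb, "fig3e_read_biotype.tsv")

  uf <- tapply(qc$usable_fraction, group, mean)
  usable <- data.frame(group = names(uf), usable_fraction = as.numeric(uf))
  extra <- do.call(rbind, lapply(config$tissues, function(tis) {
    ed <- extra_depth_required(uf[[paste0(tis, "_polyA")]],
                               uf[[paste0(tis, "_riboZ")]])
    data.frame(tissue = tis, extra_depth_raw_pct = ed$raw,
               extra_depth_pct = ed$rounded)
  }))
  emit(usable, "fig3f_usable.tsv")
  emit(extra, "extra_depth.tsv")

  cm <- correlation_matrix(expr, rpkm_filter = config$corr_filter_rpkm)
  emit(cbind(sample_id = rownames(cm), as.data.frame(cm)),
       "fig2b_correlation.tsv")

  conc <- NULL
  for (tis in config$tissues) {
    cc <- concordance_by_biotype(merged_cpm[, paste0(tis, "_polyA")],
                                 merged_cpm[, paste0(tis, "_riboZ")],
                                 models, fc_flag = config$fc_flag)
    conc <- rbind(conc, cbind(tissue = tis, cc$by_category))
  }
  emit(conc, "fig4_concordance.tsv")

  ira <- intron_rate_analysis(ct, models, expr$rpkm,
                              min_rpkm = config$intron_rate_min_rpkm)
  emit(ira$medians, "fig6_intron_rate.tsv")

  de_all <- NULL; fig5b <- NULL; fig5c <- NULL
  for (tis in config$tissues) {
    ga <- grid$sample_id[grid$tissue == tis & grid$protocol == "polyA"]
    gb <- grid$sample_id[grid$tissue == tis & grid$protocol == "riboZ"]
    universe <- rownames(merged_rpkm)[det[[tis]] != "None"]
    de <- de_analysis(ct, models, ga, gb, expressed_genes = universe,
                      fc_threshold = config$fc_threshold,
                      alpha = config$alpha, rpkm_floor = config$de_rpkm_floor)
    ds <- de_summary_by_biotype(de, models, expressed_genes = universe)
    de_all <- rbind(de_all, cbind(tissue = tis, de))
    fig5b <- rbind(fig5b, cbind(tissue = tis, ds$table_b))
    fig5c <- rbind(fig5c, cbind(tissue = tis, ds$table_c))
  }
  emit(de_all, "de_results.tsv")
  emit(fig5b, "fig5b.tsv")
  emit(fig5c, "fig5c.tsv")

  manifest <- list(
    package_version = as.character(packageVersion("prepcompare")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    n_genes = nrow(models$genes),
    samples = grid[, c("sample_id", "tissue", "protocol", "replicate", "seed")],
    file_md5 = as.list(setNames(tools::md5sum(files), basename(files)))
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, manifest_path)

  invisible(list(annotation = annotation, count_table = ct, expr = expr,
                 detection = det, merged_rpkm = merged_rpkm,
                 merged_cpm = merged_cpm, usable = usable, extra_depth = extra,
                 correlation = cm, concordance = conc, intron_rate = ira,
                 de = de_all, fig5b = fig5b, fig5c = fig5c,
                 files = files, grid = grid))
}
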