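#!/usr/bin/env Rscript
# Step 3: all protocol-comparison summaries from the counts of step 2 —
# detection classes, biotype breakdowns of genes and reads, usable-read
# fractions with the extra-depth arithmetic, sample correlations, per-biotype
# concordance, and the per-gene intron-rate analysis.

library(prepcompare)

simdir <- "results/sim"
cntdir <- "results/counts"
outdir <- "results/metrics"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

models <- build_gene_models(parse_gtf(file.path(simdir, "annotation.gtf")))
samples <- read.delim(file.path(simdir, "samples.tsv"))
read_mat <- function(f) {
  d <- read.delim(file.path(cntdir, f), check.names = FALSE)
  as.matrix(`rownames<-`(d[, -1, drop = FALSE], d$gene_id))
}
exonic <- read_mat("exonic_counts.tsv")
intronic <- read_mat("intronic_counts.tsv")
qc <- read.delim(file.path(cntdir, "read_categories.tsv"))
ct <- build_count_table(lapply(qc$sample_id, function(s) {
  list(gene_counts = data.frame(gene_id = rownames(exonic),
                                exonic = exonic[, s], intronic = intronic[, s]),
       categories = unlist(qc[qc$sample_id == s,
                              c("exonic", "intronic", "intergenic")]),
       counted_library_size = qc$counted_library_size[qc$sample_id == s],
       n_unique_fragments = qc$n_unique_fragments[qc$sample_id == s],
       exonic_pct = qc$exonic_pct[qc$sample_id == s],
       n_ambiguous = qc$n_ambiguous[qc$sample_id == s],
       sample_id = s,
       total_sequenced_reads = qc$total_sequenced_reads[qc$sample_id == s])
}), samples = samples)

expr <- expression_matrix(ct, models)

# usable reads and the extra-depth requirement
usable <- usable_fraction(ct$counted_library_size, ct$total_sequenced_reads)
group <- paste(samples$tissue, samples$protocol, sep = "_")[
  match(names(usable), samples$sample_id)]
uf <- tapply(usable, group, mean)
extra <- do.call(rbind, lapply(c("blood", "colon"), function(tis) {
  ed <- extra_depth_required(uf[[paste0(tis, "_polyA")]],
                             uf[[paste0(tis, "_riboZ")]])
  data.frame(tissue = tis, usable_polya = uf[[paste0(tis, "_polyA")]],
             usable_riboz = uf[[paste0(tis, "_riboZ")]],
             extra_depth_raw_pct = ed$raw, extra_depth_pct = ed$rounded)
}))
write.table(extra, file.path(outdir, "extra_depth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("usable-read fractions and extra depth needed by rRNA depletion:\n")
print(extra, row.names = FALSE)

# merged per-condition expression, detection classes, biotype breakdowns
merged <- merge_replicates(ct$exonic, group, ct$counted_library_size)
len <- models$genes$exonic_length[match(rownames(merged$counts),
                                        models$genes$gene_id)]
mrpkm <- compute_rpkm(merged$counts, len, merged$library_size)
mcpm <- compute_cpm(merged$counts, merged$library_size)

det_bio <- NULL
for (tis in c("blood", "colon")) {
  cls <- detection_classes(mrpkm[, paste0(tis, "_polyA")],
                           mrpkm[, paste0(tis, "_riboZ")])
  cat(sprintf("%s detection classes: %s\n", tis,
              paste(names(table(cls)), table(cls), sep = "=", collapse = " ")))
  for (lv in levels(cls)) {
    bb <- biotype_breakdown(models,
                            gene_ids = rownames(mrpkm)[cls == lv])
    det_bio <- rbind(det_bio, cbind(tissue = tis, class = lv, bb))
  }
}
write.table(det_bio, file.path(outdir, "detection_biotype.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

reads_bio <- do.call(rbind, lapply(colnames(ct$exonic), function(s) {
  cbind(sample_id = s,
        biotype_breakdown(models, counts = setNames(ct$exonic[, s],
                                                    rownames(ct$exonic))))
}))
write.table(reads_bio, file.path(outdir, "read_biotype.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# correlations and per-biotype concordance
cm <- correlation_matrix(expr)
write.table(cbind(sample_id = rownames(cm), as.data.frame(cm)),
            file.path(outdir, "sample_correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
conc <- do.call(rbind, lapply(c("blood", "colon"), function(tis) {
  cc <- concordance_by_biotype(mcpm[, paste0(tis, "_polyA")],
                               mcpm[, paste0(tis, "_riboZ")], models)
  cat(sprintf("%s: %d genes flagged at |log2FC| > 4\n", tis, nrow(cc$flagged)))
  cbind(tissue = tis, cc$by_category)
}))
write.table(conc, file.path(outdir, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# intron rates
ira <- intron_rate_analysis(ct, models, expr$rpkm)
write.table(ira$records, file.path(outdir, "intron_rate_records.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ira$medians, file.path(outdir, "intron_rate_medians.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ira$by_intron_length,
            file.path(outdir, "intron_rate_by_length.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("median intron rate by sample x category:\n")
print(ira$medians, row.names = FALSE)
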