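#!/usr/bin/env Rscript
# Step 4: differential expression between protocols per tissue (exact pooled
# count test, BH adjustment, FC>2 / adj p<0.05 / mean RPKM>0.5 criteria) and
# the biotype x direction summaries.

library(prepcompare)

simdir <- "results/sim"
cntdir <- "results/counts"
outdir <- "results/diffexp"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

models <- build_gene_models(parse_gtf(file.path(simdir, "annotation.gtf")))
samples <- read.delim(file.path(simdir, "samples.tsv"))
read_mat <- function(f) {
  d <- read.delim(file.path(cntdir, f), check.names = FALSE)
  as.matrix(`rownames<-`(d[, -1, drop = FALSE], d$gene_id))
}
exonic <- read_mat("exonic_counts.tsv")
qc <- read.delim(file.path(cntdir, "read_categories.tsv"))
ct <- build_count_table(lapply(qc$sample_id, function(s) {
  list(gene_counts = data.frame(gene_id = rownames(exonic),
                                exonic = exonic[, s],
                                intronic = 0L),
       categories = unlist(qc[qc$sample_id == s,
                              c("exonic", "intronic", "intergenic")]),
       counted_library_size = qc$counted_library_size[qc$sample_id == s],
       n_unique_fragments = qc$n_unique_fragments[qc$sample_id == s],
       exonic_pct = qc$exonic_pct[qc$sample_id == s],
       n_ambiguous = qc$n_ambiguous[qc$sample_id == s],
       sample_id = s,
       total_sequenced_reads = qc$total_sequenced_reads[qc$sample_id == s])
}), samples = samples)

group <- paste(samples$tissue, samples$protocol, sep = "_")
merged <- merge_replicates(ct$exonic[, samples$sample_id], group,
                           ct$counted_library_size[samples$sample_id])
len <- models$genes$exonic_length[match(rownames(merged$counts),
                                        models$genes$gene_id)]
mrpkm <- compute_rpkm(merged$counts, len, merged$library_size)

all_de <- NULL
for (tis in c("blood", "colon")) {
  ga <- samples$sample_id[samples$tissue == tis & samples$protocol == "polyA"]
  gb <- samples$sample_id[samples$tissue == tis & samples$protocol == "riboZ"]
  cls <- detection_classes(mrpkm[, paste0(tis, "_polyA")],
                           mrpkm[, paste0(tis, "_riboZ")])
  universe <- rownames(mrpkm)[cls != "None"]
  de <- de_analysis(ct, models, ga, gb, expressed_genes = universe)
  s <- de_summary_by_biotype(de, models, expressed_genes = universe)
  cat(sprintf("%s: %d of %d expressed genes differentially captured (%d up in rRNA depletion)\n",
              tis, sum(de$is_de), length(universe),
              sum(de$direction == "up_in_riboz")))
  all_de <- rbind(all_de, cbind(tissue = tis, de))
  write.table(s$table_b, file.path(outdir, sprintf("%s_de_by_biotype.tsv", tis)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(s$table_c, file.path(outdir, sprintf("%s_de_direction.tsv", tis)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(s$table_b, row.names = FALSE)
}
write.table(all_de, file.path(outdir, "de_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
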