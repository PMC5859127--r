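#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (exonic_length/1000) / (library_size/1e6)`. The library
#' size is by default the per-sample counted reads (sum of exonic assigned
#' counts); see [expression_matrix()] for the alternative.
#'
#' @param counts Numeric vector or gene-by-sample matrix of counts.
#' @param exonic_length Per-gene union-exon length in bp (recycled across
#'   samples for a matrix).
#' @param library_size Per-sample library size (scalar for a vector, one per
#'   column for a matrix).
#' @export
compute_rpkm <- function(counts, exonic_length, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(exonic_length <= 0)) stop("exonic_length must be positive")
  if (is.matrix(counts)) {
    sweep(counts / (exonic_length / 1000), 2, library_size / 1e6, "/")
  } else {
    counts / (exonic_length / 1000) / (library_size / 1e6)
  }
}

#' Counts per million
#'
#' @inheritParams compute_rpkm
#' @export
compute_cpm <- function(counts, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (is.matrix(counts)) {
    sweep(counts, 2, library_size / 1e6, "/")
  } else {
    counts / (library_size / 1e6)
  }
}

#' RPKM and CPM matrices from a count table
#'
#' @param count_table A `count_table` from [build_count_table()].
#' @param models The matching `gene_models`.
#' @param library_size Either `"counted"` (sum of exonic assigned counts,
#'   the default) or `"mapped"` (number of uniquely mapped fragments). The
#'   choice is recorded in the result's `provenance`.
#' @return list with matrices `rpkm`, `cpm`, vector `library_size`, and
#'   `provenance` string.
#' @export
expression_matrix <- function(count_table, models,
                              library_size = c("counted", "mapped")) {
  library_size <- match.arg(library_size)
  lib <- switch(library_size,
                counted = count_table$counted_library_size,
                mapped = setNames(count_table$categories$n_unique_fragments,
                                  count_table$categories$sample_id))
  len <- models$genes$exonic_length[match(rownames(count_table$exonic),
                                          models$genes$gene_id)]
  list(rpkm = compute_rpkm(count_table$exonic, len, lib),
       cpm = compute_cpm(count_table$exonic, lib),
       library_size = lib,
       provenance = library_size)
}

#' Merge replicate counts into per-condition totals
#'
#' Counts are summed across the replicates of each group; library sizes sum
#' accordingly, so merged RPKM equals the RPKM of the pooled fragments.
#'
#' @param counts Gene-by-sample matrix.
#' @param groups Character vector, one group label per column.
#' @param library_size Optional per-sample library sizes to merge alongside.
#' @return list with `counts` (gene by group) and `library_size` when given.
#' @export
merge_replicates <- function(counts, groups, library_size = NULL) {
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  if (any(table(groups) == 0)) stop("empty group")
  glev <- unique(groups)
  merged <- vapply(glev, function(g) {
    rowSums(counts[, groups == g, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(merged) <- list(rownames(counts), glev)
  out <- list(counts = merged)
  if (!is.null(library_size)) {
    out$library_size <- vapply(glev, function(g) sum(library_size[groups == g]), 0)
  }
  out
}

#' Detection classes from merged per-protocol expression
#'
#' A gene is expressed under a protocol if its RPKM is strictly greater than
#' the threshold; the four classes Both / PolyA / RiboZ / None partition the
#' annotated gene universe.
#'
#' @param rpkm_polya,rpkm_riboz Per-gene merged RPKM vectors over the same
#'   gene universe.
#' @param threshold Expression threshold (default 0.1 RPKM, strict `>`).
#' @return Factor over levels Both, PolyA, RiboZ, None.
#' @export
detection_classes <- function(rpkm_polya, rpkm_riboz, threshold = 0.1) {
  if (length(rpkm_polya) != length(rpkm_riboz)) stop("gene universes differ")
  a <- rpkm_polya > threshold
  b <- rpkm_riboz > threshold
  cls <- ifelse(a & b, "Both", ifelse(a, "PolyA", ifelse(b, "RiboZ", "None")))
  factor(cls, levels = c("Both", "PolyA", "RiboZ", "None"))
}

#' Biotype breakdowns of genes and of counted reads
#'
#' Gene fractions: of a gene set (e.g. the genes expressed in one sample, or
#' one detection class), the share in each of the five biotype categories.
#' Read fractions: the share of a sample's counted reads assigned to genes
#' of each category. Genes in the "other" bucket are excluded from the
#' five-way fractions.
#'
#' @param gene_ids Character vector of genes (for gene fractions), or `NULL`.
#' @param counts Named per-gene count vector (for read fractions), or `NULL`.
#' @param models A `gene_models` object.
#' @return data.frame with `category`, and `gene_fraction` and/or
#'   `read_fraction` columns; fractions sum to 1 over the five categories.
#' @export
biotype_breakdown <- function(models, gene_ids = NULL, counts = NULL) {
  cats <- biotype_categories()
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  gcat <- setNames(models$genes$category, models$genes$gene_id)
  if (!is.null(gene_ids)) {
    cc <- gcat[gene_ids]
    cc <- cc[cc %in% cats]
    tab <- table(factor(cc, cats))
    out$n_genes <- as.integer(tab)
    out$gene_fraction <- if (sum(tab) > 0) as.numeric(tab / sum(tab)) else NA_real_
  }
  if (!is.null(counts)) {
    cc <- gcat[names(counts)]
    keep <- cc %in% cats
    sums <- tapply(counts[keep], factor(cc[keep], cats), sum, default = 0)
    out$n_reads <- as.numeric(sums)
    out$read_fraction <- if (sum(sums) > 0) as.numeric(sums / sum(sums)) else NA_real_
  }
  out
}

#' Fraction of sequenced reads usable for gene quantification
#'
#' Counted (exonic assigned) reads normalized by the total number of
#' sequenced reads.
#'
#' @param counted_library_size Reads assigned to genes.
#' @param total_sequenced_reads Declared sequencing depth (> 0).
#' @export
usable_fraction <- function(counted_library_size, total_sequenced_reads) {
  if (any(total_sequenced_reads <= 0)) stop("total_sequenced_reads must be positive")
  if (any(counted_library_size > total_sequenced_reads)) {
    stop("counted reads exceed total sequenced reads")
  }
  counted_library_size / total_sequenced_reads
}

#' Extra sequencing depth required to match polyA+ exonic coverage
#'
#' How many more reads an rRNA-depleted library must sequence to deliver the
#' same number of usable (exonic) reads as a polyA+ library:
#' `(frac_polya / frac_riboz - 1) * 100` percent, reported rounded to the
#' nearest `round_to` percent with the raw value alongside.
#'
#' @param frac_polya,frac_riboz Usable-read fractions in (0, 1].
#' @param round_to Rounding grain in percent (default 10).
#' @return list with `raw` and `rounded` percent values.
#' @export
extra_depth_required <- function(frac_polya, frac_riboz, round_to = 10) {
  if (any(frac_riboz <= 0)) stop("frac_riboz must be positive (infinite depth otherwise)")
  if (any(frac_polya <= 0 | frac_polya > 1) || any(frac_riboz > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  raw <- (frac_polya / frac_riboz - 1) * 100
  list(raw = raw, rounded = round(raw / round_to) * round_to)
}

#' Sample-sample correlation of log2(CPM+1) over expressed genes
#'
#' Genes with RPKM below `rpkm_filter` in every sample are removed, then the
#' pairwise correlation of `log2(CPM + 1)` is computed across samples.
#'
#' @param expr An [expression_matrix()] result.
#' @param rpkm_filter Low-expression filter (default 0.5; a gene is dropped
#'   iff RPKM < 0.5 in all samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric sample-by-sample correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, rpkm_filter = 0.5, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(expr$cpm) < 2) stop("need at least 2 samples")
  keep <- apply(expr$rpkm >= rpkm_filter, 1, any)
  if (sum(keep) < 2) stop("fewer than 2 genes survive the RPKM filter")
  cor(log2(expr$cpm[keep, , drop = FALSE] + 1), method = method)
}

#' Per-biotype concordance between the two protocols
#'
#' For each biotype category, the Pearson correlation of `log2(CPM + 1)`
#' between merged polyA+ and merged rRNA-depletion expression, plus the
#' genes whose absolute `log2((cpm_riboz + 1)/(cpm_polya + 1))` exceeds
#' `fc_flag` (large-discrepancy flags).
#'
#' @param cpm_polya,cpm_riboz Named per-gene merged CPM vectors.
#' @param models A `gene_models` object.
#' @param fc_flag Flag threshold on |log2 fold change| (default 4).
#' @return list with `by_category` data.frame (`category`, `n`, `r`) and
#'   `flagged` data.frame (`gene_id`, `category`, `log2fc`).
#' @export
concordance_by_biotype <- function(cpm_polya, cpm_riboz, models, fc_flag = 4) {
  stopifnot(length(cpm_polya) == length(cpm_riboz))
  ids <- names(cpm_polya)
  cat <- models$genes$category[match(ids, models$genes$gene_id)]
  lf <- log2((cpm_riboz + 1) / (cpm_polya + 1))
  by_cat <- do.call(rbind, lapply(biotype_categories(), function(cc) {
    sel <- which(cat == cc)
    r <- if (length(sel) >= 2 &&
             stats::sd(cpm_polya[sel]) > 0 && stats::sd(cpm_riboz[sel]) > 0) {
      cor(log2(cpm_polya[sel] + 1), log2(cpm_riboz[sel] + 1))
    } else NA_real_
    data.frame(category = cc, n = length(sel), r = r, stringsAsFactors = FALSE)
  }))
  flagged <- data.frame(gene_id = ids, category = cat, log2fc = lf,
                        stringsAsFactors = FALSE)
  flagged <- flagged[abs(flagged$log2fc) > fc_flag, , drop = FALSE]
  rownames(flagged) <- NULL
  list(by_category = by_cat, flagged = flagged)
}

#' Per-gene intron rates with structural filters
#'
#' The intron rate of a gene in a sample is its intronic read count divided
#' by intronic + exonic counts. Genes are excluded from the statistic if they
#' overlap any other gene, have no introns, or fall below `min_rpkm` in any
#' sample; genes with zero intronic + exonic reads after filtering are also
#' dropped. Summaries: per sample-by-category medians, and binned trends of
#' rate versus total intron length (half-decade log10 bins) and versus the
#' number of introns (bins 1, 2-5, 6-10, 11-20, >20).
#'
#' @param count_table A `count_table`.
#' @param models The matching `gene_models`.
#' @param rpkm Gene-by-sample RPKM matrix for the expression filter.
#' @param min_rpkm Expression filter (default 1; a gene must reach it in
#'   every sample).
#' @return list with `records` (long data.frame gene x sample with
#'   `intron_rate` and structure columns), `filters` (per-gene filter
#'   outcome), `medians` (sample x category median rates), `by_intron_length`
#'   and `by_n_introns` (binned medians).
#' @export
intron_rate_analysis <- function(count_table, models, rpkm, min_rpkm = 1) {
  g <- models$genes
  expressed <- apply(rpkm >= min_rpkm, 1, all)
  filters <- data.frame(
    gene_id = g$gene_id,
    overlaps_other_gene = g$overlaps_other_gene,
    no_introns = g$n_introns == 0,
    below_min_rpkm = !expressed[g$gene_id],
    stringsAsFactors = FALSE
  )
  filters$filter_pass <- !(filters$overlaps_other_gene | filters$no_introns |
                             filters$below_min_rpkm)
  keep <- filters$gene_id[filters$filter_pass]

  recs <- NULL
  for (s in colnames(count_table$exonic)) {
    exo <- count_table$exonic[keep, s]
    intr <- count_table$intronic[keep, s]
    tot <- exo + intr
    ok <- tot > 0
    if (!any(ok)) next
    recs <- rbind(recs, data.frame(
      gene_id = keep[ok], sample_id = s,
      category = g$category[match(keep[ok], g$gene_id)],
      intron_rate = intr[ok] / tot[ok],
      exonic = exo[ok], intronic = intr[ok],
      intron_length = g$intron_length[match(keep[ok], g$gene_id)],
      n_introns = g$n_introns[match(keep[ok], g$gene_id)],
      stringsAsFactors = FALSE))
  }
  if (is.null(recs)) {
    recs <- data.frame(gene_id = character(0), sample_id = character(0),
                       category = character(0), intron_rate = numeric(0),
                       exonic = numeric(0), intronic = numeric(0),
                       intron_length = integer(0), n_introns = integer(0))
  }
  rownames(recs) <- NULL

  medians <- if (!is.null(recs) && nrow(recs) > 0) {
    stats::aggregate(intron_rate ~ sample_id + category, recs, median)
  } else {
    data.frame(sample_id = character(0), category = character(0),
               intron_rate = numeric(0))
  }

  bin_len <- function(x) {
    lo <- floor(log10(pmax(x, 1)) * 2) / 2
    sprintf("1e%.1f-1e%.1f", lo, lo + 0.5)
  }
  bin_n <- function(n) cut(n, c(0, 1, 5, 10, 20, Inf),
                           labels = c("1", "2-5", "6-10", "11-20", ">20"))
  by_len <- by_n <- NULL
  if (!is.null(recs) && nrow(recs) > 0) {
    recs$intron_length_bin <- bin_len(recs$intron_length)
    recs$n_introns_bin <- bin_n(recs$n_introns)
    by_len <- stats::aggregate(intron_rate ~ sample_id + intron_length_bin,
                               recs, median)
    by_n <- stats::aggregate(intron_rate ~ sample_id + n_introns_bin, recs, median)
  }
  list(records = recs, filters = filters, medians = medians,
       by_intron_length = by_len, by_n_introns = by_n)
}
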