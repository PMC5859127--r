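#' Exact two-group count test on pooled counts
#'
#' A deliberately simple substitute for a negative-binomial GLM: for each
#' gene the replicate counts of each group are pooled, and conditional on
#' the pooled total `n = xA + xB` the split is tested against
#' `Binomial(n, LA/(LA+LB))` where `LA`, `LB` are the pooled library sizes.
#' The two-sided p-value doubles the smaller tail (capped at 1). Genes with
#' zero pooled total get p = 1. A hook for externally computed per-gene
#' p-values exists in [de_analysis()].
#'
#' @param counts_a,counts_b Gene-by-replicate count matrices (or vectors).
#' @param lib_a,lib_b Per-replicate library sizes.
#' @return Per-gene two-sided p-value vector.
#' @export
two_group_count_test <- function(counts_a, counts_b, lib_a, lib_b) {
  if (any(c(lib_a, lib_b) <= 0)) stop("library sizes must be positive")
  xa <- if (is.matrix(counts_a)) rowSums(counts_a) else counts_a
  xb <- if (is.matrix(counts_b)) rowSums(counts_b) else counts_b
  la <- sum(lib_a); lb <- sum(lib_b)
  pr <- la / (la + lb)
  n <- xa + xb
  p <- rep(1, length(xa))
  pos <- n > 0
  lower <- pbinom(xa[pos], n[pos], pr)
  upper <- pbinom(xa[pos] - 1, n[pos], pr, lower.tail = FALSE)
  p[pos] <- pmin(1, 2 * pmin(lower, upper))
  names(p) <- names(xa) %||% rownames(counts_a)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Literal step-up: sort p ascending, `adj_(i) = min_{j >= i} (m/j) p_(j)`,
#' capped at 1, returned in the original order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev((m / seq_len(m)) * p[o]))))
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(p)
  out
}

#' Apply the differential-expression criteria
#'
#' A gene is differentially expressed iff its fold change exceeds
#' `fc_threshold` (i.e. |log2FC| > log2(fc_threshold)), its BH-adjusted
#' p-value is below `alpha`, and its mean expression exceeds `rpkm_floor`
#' RPKM — all strict inequalities. Direction is relative to the
#' rRNA-depletion group: up means higher in rRNA depletion than in polyA+.
#'
#' @param log2fc Per-gene log2 fold change (riboZ over polyA).
#' @param adj_p BH-adjusted p-values.
#' @param mean_rpkm Mean RPKM over all samples of both groups.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param rpkm_floor Expression floor (default 0.5 RPKM).
#' @return data.frame with `gene_id`, `log2fc`, `adj_p`, `mean_rpkm`,
#'   `is_de`, `direction` in `{up_in_riboz, down_in_riboz, none}`.
#' @export
apply_de_criteria <- function(log2fc, adj_p, mean_rpkm, fc_threshold = 2,
                              alpha = 0.05, rpkm_floor = 0.5) {
  stopifnot(length(log2fc) == length(adj_p), length(adj_p) == length(mean_rpkm))
  is_de <- abs(log2fc) > log2(fc_threshold) & adj_p < alpha & mean_rpkm > rpkm_floor
  direction <- ifelse(!is_de, "none",
                      ifelse(log2fc > 0, "up_in_riboz", "down_in_riboz"))
  data.frame(gene_id = names(log2fc) %||% seq_along(log2fc),
             log2fc = log2fc, adj_p = adj_p, mean_rpkm = mean_rpkm,
             is_de = is_de, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression between protocols
#'
#' Runs the pooled-count exact test (or accepts externally computed per-gene
#' p-values), BH adjustment, and the threshold criteria. log2FC is computed
#' on group-mean CPM with a pseudo-count of 0.5 added to each mean; mean
#' RPKM averages over all samples of both groups.
#'
#' @param count_table A `count_table`.
#' @param models The matching `gene_models`.
#' @param group_polya,group_riboz Sample ids of the two groups.
#' @param pvalues Optional externally computed per-gene p-values (named);
#'   replaces the internal test.
#' @param expressed_genes Optional gene universe restriction (e.g. genes
#'   expressed under either protocol); defaults to all genes.
#' @param pseudo_count Pseudo-count added to mean CPM (default 0.5).
#' @inheritParams apply_de_criteria
#' @return data.frame as from [apply_de_criteria()] with `pvalue` added.
#' @export
de_analysis <- function(count_table, models, group_polya, group_riboz,
                        pvalues = NULL, expressed_genes = NULL,
                        fc_threshold = 2, alpha = 0.05, rpkm_floor = 0.5,
                        pseudo_count = 0.5) {
  exo <- count_table$exonic
  lib <- count_table$counted_library_size
  genes <- expressed_genes %||% rownames(exo)
  exo <- exo[genes, , drop = FALSE]

  cpm <- compute_cpm(exo, lib)
  len <- models$genes$exonic_length[match(genes, models$genes$gene_id)]
  rpkm <- compute_rpkm(exo, len, lib)
  mean_a <- rowMeans(cpm[, group_polya, drop = FALSE])
  mean_b <- rowMeans(cpm[, group_riboz, drop = FALSE])
  log2fc <- setNames(log2((mean_b + pseudo_count) / (mean_a + pseudo_count)), genes)
  mean_rpkm <- rowMeans(rpkm[, c(group_polya, group_riboz), drop = FALSE])

  p <- if (is.null(pvalues)) {
    two_group_count_test(exo[, group_polya, drop = FALSE],
                         exo[, group_riboz, drop = FALSE],
                         lib[group_polya], lib[group_riboz])
  } else {
    pvalues[genes]
  }
  adj <- bh_adjust(p)
  out <- apply_de_criteria(log2fc, adj, mean_rpkm, fc_threshold, alpha, rpkm_floor)
  out$pvalue <- unname(p)
  out
}

#' Summarize DE genes by biotype and direction
#'
#' Table B: per category, the number of up- and down-regulated DE genes over
#' the number of expressed genes in that category. Table C: within each
#' category, the up and down shares of that category's DE genes (categories
#' with zero DE genes are reported as missing).
#'
#' @param de A [de_analysis()] result.
#' @param models A `gene_models` object.
#' @param expressed_genes Gene ids of the expressed universe (denominator of
#'   table B); defaults to all genes in `de`.
#' @return list of data.frames `table_b` and `table_c`.
#' @export
de_summary_by_biotype <- function(de, models, expressed_genes = NULL) {
  expressed_genes <- expressed_genes %||% de$gene_id
  gcat <- setNames(models$genes$category, models$genes$gene_id)
  cats <- biotype_categories()
  tab <- lapply(cats, function(cc) {
    expr_n <- sum(gcat[expressed_genes] == cc, na.rm = TRUE)
    sel <- de[de$is_de & gcat[de$gene_id] == cc & !is.na(gcat[de$gene_id]), ]
    up <- sum(sel$direction == "up_in_riboz")
    down <- sum(sel$direction == "down_in_riboz")
    list(b = data.frame(category = cc, n_expressed = expr_n, n_up = up,
                        n_down = down,
                        pct_up = if (expr_n > 0) 100 * up / expr_n else NA_real_,
                        pct_down = if (expr_n > 0) 100 * down / expr_n else NA_real_,
                        stringsAsFactors = FALSE),
         c = data.frame(category = cc, n_de = up + down,
                        frac_up = if (up + down > 0) up / (up + down) else NA_real_,
                        frac_down = if (up + down > 0) down / (up + down) else NA_real_,
                        stringsAsFactors = FALSE))
  })
  list(table_b = do.call(rbind, lapply(tab, `[[`, "b")),
       table_c = do.call(rbind, lapply(tab, `[[`, "c")))
}
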