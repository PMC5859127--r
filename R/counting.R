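#' Validate a fragment table
#'
#' Fragments are spliced, deduplicated read pairs represented as one row per
#' alignment block: `fragment_id`, `chrom`, `start`, `end` (0-based
#' half-open), `strand`, `is_unique`. Blocks of a fragment must be disjoint,
#' sorted and on one chromosome.
#'
#' @param fragments Fragment block data.frame.
#' @return The validated data.frame (invisibly re-ordered by id, start).
#' @export
validate_fragments <- function(fragments) {
  need <- c("fragment_id", "chrom", "start", "end", "strand", "is_unique")
  miss <- setdiff(need, names(fragments))
  if (length(miss) > 0) stop("fragment table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (any(fragments$end <= fragments$start)) stop("fragment block with end <= start")
  fragments <- fragments[order(fragments$fragment_id, fragments$start), , drop = FALSE]
  # adjacent rows of one fragment must share chrom and must not overlap
  same <- fragments$fragment_id[-1] == fragments$fragment_id[-nrow(fragments)]
  if (any(same & fragments$chrom[-1] != fragments$chrom[-nrow(fragments)])) {
    stop("fragment with blocks on multiple chromosomes")
  }
  if (any(same & fragments$start[-1] < fragments$end[-nrow(fragments)])) {
    stop("fragment with overlapping blocks")
  }
  rownames(fragments) <- NULL
  fragments
}

# Per-(fragment, gene) total overlap widths of blocks against a set of
# per-gene intervals. `frag_idx` is an integer fragment index per block;
# returns data.table(frag = integer index, gene = integer gene index, w).
overlap_by_gene <- function(blocks_gr, frag_idx, ivl_df, gene_levels) {
  if (nrow(ivl_df) == 0) {
    return(data.table::data.table(frag = integer(0), gene = integer(0),
                                  w = integer(0)))
  }
  ivl_gr <- GenomicRanges::GRanges(ivl_df$chrom, to_iranges(ivl_df$start, ivl_df$end))
  hits <- GenomicRanges::findOverlaps(blocks_gr, ivl_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(blocks_gr)[q], GenomicRanges::ranges(ivl_gr)[s]))
  dt <- data.table::data.table(frag = frag_idx[q],
                               gene = match(ivl_df$gene_id[s], gene_levels),
                               w = w)
  dt[, list(w = sum(w)), by = c("frag", "gene")]
}

#' Classify fragments into exonic / intronic / intergenic regions
#'
#' Region classification as used for library-level read-category summaries:
#' a fragment is exonic if any block overlaps any gene's union exon by at
#' least 1 bp; otherwise intronic if any block overlaps any intron; otherwise
#' intergenic. Strand-blind. Only uniquely mapped fragments should be passed.
#'
#' @param fragments Fragment block data.frame (see [validate_fragments()]).
#' @param models A `gene_models` object.
#' @return data.frame with `fragment_id` and `region` in
#'   `{exonic, intronic, intergenic}`, one row per fragment.
#' @export
classify_read_region <- function(fragments, models) {
  fragments <- validate_fragments(fragments)
  ids <- unique(fragments$fragment_id)
  fi <- match(fragments$fragment_id, ids)
  blocks_gr <- to_granges(fragments)
  hit_ex <- IRanges::overlapsAny(blocks_gr, to_granges(models$exons),
                                 ignore.strand = TRUE)
  hit_in <- if (nrow(models$introns) > 0) {
    IRanges::overlapsAny(blocks_gr, to_granges(models$introns),
                         ignore.strand = TRUE)
  } else rep(FALSE, length(blocks_gr))
  region <- rep("intergenic", length(ids))
  region[unique(fi[hit_in])] <- "intronic"
  region[unique(fi[hit_ex])] <- "exonic"
  data.frame(fragment_id = ids, region = region, stringsAsFactors = FALSE)
}

#' Assign fragments to genes under the minimum-overlap counting rules
#'
#' Exonic assignment to a gene requires total block overlap with that gene's
#' union exons of at least `min_overlap` bp, no overlap with a multi-gene
#' exonic region, and no second gene reaching `min_overlap` (otherwise the
#' fragment is ambiguous and counted for no gene). Fragments that reach
#' `min_overlap` on no gene but overlap at least one gene's introns are
#' tallied as intronic for the gene with the longest intronic overlap (ties
#' broken by lexicographic gene id) — these feed the per-gene intron rate.
#' Non-unique fragments are dropped. Assignment is deterministic and
#' independent of input order.
#'
#' @param fragments Fragment block data.frame.
#' @param models A `gene_models` object.
#' @param min_overlap Minimum exonic overlap in bp (default 25, the
#'   featureCounts `--minOverlap` setting used throughout).
#' @return data.frame with one row per unique fragment: `fragment_id`,
#'   `status` in `{exonic_assigned, ambiguous, excluded_overlap,
#'   unassigned_exonic, intronic, intergenic}`, and `gene_id` (`NA` unless
#'   exonic_assigned or intronic).
#' @export
assign_fragments <- function(fragments, models, min_overlap = 25L) {
  if (min_overlap <= 0) stop("min_overlap must be a positive number of bases")
  fragments <- validate_fragments(fragments)
  fragments <- fragments[fragments$is_unique, , drop = FALSE]
  ids <- unique(fragments$fragment_id)
  if (length(ids) == 0) {
    return(data.frame(fragment_id = integer(0), status = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  fi <- match(fragments$fragment_id, ids)
  blocks_gr <- to_granges(fragments)
  glev <- models$genes$gene_id

  ex <- overlap_by_gene(blocks_gr, fi, models$exons, glev)
  inn <- overlap_by_gene(blocks_gr, fi, models$introns, glev)

  in_multi <- logical(length(ids))
  if (!is.null(models$multi_exonic) && nrow(models$multi_exonic) > 0) {
    multi_gr <- to_granges(models$multi_exonic)
    hit <- IRanges::overlapsAny(blocks_gr, multi_gr, ignore.strand = TRUE)
    in_multi[unique(fi[hit])] <- TRUE
  }

  cand <- ex[ex$w >= min_overlap]
  n_cand <- tabulate(cand$frag, nbins = length(ids))

  status <- rep("intergenic", length(ids))
  gene <- rep(NA_integer_, length(ids))

  status[unique(ex$frag)] <- "unassigned_exonic"

  one <- cand[n_cand[cand$frag] == 1L]
  status[one$frag] <- "exonic_assigned"
  gene[one$frag] <- one$gene
  status[n_cand > 1L] <- "ambiguous"
  gene[n_cand > 1L] <- NA_integer_

  # multi-gene exonic region exclusion overrides any assignment
  excl <- in_multi & n_cand >= 1L
  status[excl] <- "excluded_overlap"
  gene[excl] <- NA_integer_

  # intronic tally: no gene reached min_overlap anywhere
  itr <- inn[n_cand[inn$frag] == 0L]
  if (nrow(itr) > 0) {
    data.table::setorder(itr, frag, -w, gene)
    best <- itr[!duplicated(itr$frag)]
    status[best$frag] <- "intronic"
    gene[best$frag] <- best$gene
  }

  out <- data.frame(fragment_id = ids, status = status,
                    gene_id = glev[gene], stringsAsFactors = FALSE)
  out[order(out$fragment_id), , drop = FALSE]
}

#' Count one sample: per-gene exonic/intronic counts and category totals
#'
#' Combines [classify_read_region()] (1-bp-overlap region categories, as in
#' library QC summaries) with [assign_fragments()] (min-overlap gene
#' assignment). The exonic percentage is the exonic category total over the
#' declared total sequenced reads; the counted library size is the sum of
#' exonic assigned counts and is the default library size for CPM/RPKM.
#'
#' @param fragments Fragment block data.frame.
#' @param models A `gene_models` object.
#' @param sample_id Sample identifier.
#' @param total_sequenced_reads Declared sequencing depth; must be at least
#'   the number of unique fragments supplied. Defaults to the number of
#'   unique fragments.
#' @param min_overlap Passed to [assign_fragments()].
#' @return list with `gene_counts` (gene_id, exonic, intronic), `categories`
#'   (named counts exonic/intronic/intergenic over unique fragments),
#'   `counted_library_size`, `n_unique_fragments`, `exonic_pct`,
#'   `n_ambiguous`, `sample_id`, `total_sequenced_reads`.
#' @export
count_sample <- function(fragments, models, sample_id = "sample",
                         total_sequenced_reads = NULL, min_overlap = 25L) {
  fragments <- validate_fragments(fragments)
  fragments <- fragments[fragments$is_unique, , drop = FALSE]
  n_frag <- length(unique(fragments$fragment_id))
  if (n_frag == 0) warning("count_sample: empty fragment set for ", sample_id)
  total_sequenced_reads <- total_sequenced_reads %||% n_frag
  if (total_sequenced_reads < n_frag) {
    stop("total_sequenced_reads (", total_sequenced_reads,
         ") smaller than number of fragments (", n_frag, ")")
  }

  reg <- classify_read_region(fragments, models)
  categories <- c(exonic = sum(reg$region == "exonic"),
                  intronic = sum(reg$region == "intronic"),
                  intergenic = sum(reg$region == "intergenic"))

  asg <- assign_fragments(fragments, models, min_overlap = min_overlap)
  gene_ids <- models$genes$gene_id
  exonic <- table(factor(asg$gene_id[asg$status == "exonic_assigned"], gene_ids))
  intronic <- table(factor(asg$gene_id[asg$status == "intronic"], gene_ids))
  gene_counts <- data.frame(gene_id = gene_ids,
                            exonic = as.integer(exonic),
                            intronic = as.integer(intronic),
                            stringsAsFactors = FALSE)

  list(gene_counts = gene_counts,
       categories = categories,
       counted_library_size = sum(gene_counts$exonic),
       n_unique_fragments = n_frag,
       exonic_pct = if (total_sequenced_reads > 0) {
         exonic_pct(categories[["exonic"]], total_sequenced_reads)
       } else NA_real_,
       n_ambiguous = sum(asg$status %in% c("ambiguous", "excluded_overlap")),
       sample_id = sample_id,
       total_sequenced_reads = total_sequenced_reads)
}

#' Exonic reads as a percentage of total sequenced reads
#'
#' The QC-table arithmetic: exonic reads / total reads x 100, reported to
#' two decimals.
#'
#' @param exonic_reads,total_reads Counts.
#' @param digits Decimals to round to (default 2, as printed in QC tables).
#' @export
exonic_pct <- function(exonic_reads, total_reads, digits = 2) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  round(exonic_reads / total_reads * 100, digits)
}

#' Build a multi-sample count table
#'
#' @param per_sample list of [count_sample()] results (one per sample).
#' @param samples Optional sample sheet data.frame with at least `sample_id`;
#'   `tissue`, `protocol`, `replicate`, `total_sequenced_reads` are carried
#'   through when present.
#' @return An object of class `count_table`: `exonic` and `intronic`
#'   gene-by-sample integer matrices, `categories` per-sample data.frame,
#'   `counted_library_size` and `total_sequenced_reads` named vectors, and
#'   the `samples` sheet.
#' @export
build_count_table <- function(per_sample, samples = NULL) {
  ids <- vapply(per_sample, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  genes <- per_sample[[1]]$gene_counts$gene_id
  exo <- vapply(per_sample, function(s) s$gene_counts$exonic, integer(length(genes)))
  intr <- vapply(per_sample, function(s) s$gene_counts$intronic, integer(length(genes)))
  dimnames(exo) <- dimnames(intr) <- list(genes, ids)
  cats <- do.call(rbind, lapply(per_sample, function(s) {
    data.frame(sample_id = s$sample_id, exonic = s$categories[["exonic"]],
               intronic = s$categories[["intronic"]],
               intergenic = s$categories[["intergenic"]],
               n_unique_fragments = s$n_unique_fragments,
               exonic_pct = s$exonic_pct, n_ambiguous = s$n_ambiguous,
               stringsAsFactors = FALSE)
  }))
  rownames(cats) <- NULL
  structure(list(
    exonic = exo, intronic = intr, categories = cats,
    counted_library_size = setNames(
      vapply(per_sample, `[[`, 0, "counted_library_size"), ids),
    total_sequenced_reads = setNames(
      vapply(per_sample, `[[`, 0, "total_sequenced_reads"), ids),
    samples = samples
  ), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$exonic), "genes x", ncol(x$exonic), "samples\n")
  print(x$categories)
  invisible(x)
}

#' Subsample fragments uniformly without replacement
#'
#' Reproducible for a fixed seed and independent of the input row order
#' (fragment ids are sorted before sampling).
#'
#' @param fragments Fragment block data.frame.
#' @param n Number of fragments to keep; must not exceed the number present.
#' @param seed Integer seed.
#' @return The subset of rows belonging to the sampled fragments.
#' @export
subsample_fragments <- function(fragments, n, seed) {
  ids <- sort(unique(fragments$fragment_id))
  if (n > length(ids)) stop("cannot subsample ", n, " of ", length(ids), " fragments")
  keep <- with_seed(seed, sample(ids, n))
  out <- fragments[fragments$fragment_id %in% keep, , drop = FALSE]
  out[order(out$fragment_id, out$start), , drop = FALSE]
}

#' Read fragments from a BED12 file
#'
#' Blocks are expanded from blockSizes/blockStarts; the score column is
#' interpreted as the unique-mapping flag (1 = unique) when present.
#'
#' @param path BED12 file path.
#' @return Fragment block data.frame.
#' @export
read_fragments_bed12 <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 12) stop("expected BED12, found ", ncol(bed), " columns")
  names(bed)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                        "thickStart", "thickEnd", "rgb", "blockCount",
                        "blockSizes", "blockStarts")
  sizes <- lapply(strsplit(bed$blockSizes, ","), as.integer)
  offs <- lapply(strsplit(bed$blockStarts, ","), as.integer)
  nb <- lengths(sizes)
  idx <- rep(seq_len(nrow(bed)), nb)
  data.frame(
    fragment_id = bed$name[idx],
    chrom = bed$chrom[idx],
    start = bed$start[idx] + unlist(offs),
    end = bed$start[idx] + unlist(offs) + unlist(sizes),
    strand = bed$strand[idx],
    is_unique = if (all(bed$score %in% c(0, 1))) bed$score[idx] == 1 else TRUE,
    stringsAsFactors = FALSE
  )
}

#' Write fragments as BED12
#'
#' @param fragments Fragment block data.frame.
#' @param path Output path.
#' @export
write_fragments_bed12 <- function(fragments, path) {
  fragments <- validate_fragments(fragments)
  dt <- data.table::as.data.table(fragments)
  bed <- dt[, list(chrom = chrom[1], start = min(start), end = max(end),
                   score = as.integer(is_unique[1]), strand = strand[1],
                   blockCount = .N,
                   blockSizes = paste0(paste(end - start, collapse = ","), ","),
                   blockStarts = paste0(paste(start - min(start), collapse = ","), ",")),
            by = "fragment_id"]
  out <- bed[, list(chrom, start, end, name = fragment_id, score, strand,
                    thickStart = start, thickEnd = end, rgb = "0",
                    blockCount, blockSizes, blockStarts)]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
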