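# Independent fixtures and brute-force oracles used across the suite.
# Everything here is deliberately plain base R (nested loops, per-base
# bitmaps) so it shares no code path with the package implementation.

# Raw gene records with random multi-transcript exon structure, possibly
# overlapping genes (to exercise ambiguity and multi-gene exclusion).
random_raw_records <- function(n_genes = 20, chrom_length = 60000, seed = 1,
                               types = c("protein_coding", "lincRNA", "miRNA",
                                         "processed_pseudogene", "TR_J_gene")) {
  set.seed(seed)
  exons <- NULL
  genes <- NULL
  for (i in seq_len(n_genes)) {
    id <- sprintf("G%03d", i)
    n_ex <- sample(1:4, 1)
    widths <- sample(40:400, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(50:2000, n_ex - 1, replace = TRUE) else integer(0)
    starts <- cumsum(c(0, widths[-n_ex] + gaps))
    span <- starts[n_ex] + widths[n_ex]
    off <- sample.int(max(chrom_length - span, 1), 1)
    strand <- sample(c("+", "-"), 1)
    # a second "transcript": a random subset of the exons, shifted inward
    keep2 <- sort(sample(seq_len(n_ex), max(1, n_ex - 1)))
    exons <- rbind(
      exons,
      data.frame(gene_id = id, chrom = "chrR", start = off + starts,
                 end = off + starts + widths, strand = strand),
      data.frame(gene_id = id, chrom = "chrR", start = off + starts[keep2],
                 end = off + starts[keep2] + pmax(widths[keep2] %/% 2, 1),
                 strand = strand)
    )
    genes <- rbind(genes, data.frame(gene_id = id,
                                     gene_type = sample(types, 1),
                                     chrom = "chrR", strand = strand))
  }
  list(genes = genes, exons = exons)
}

# Random fragment set over the toy chromosome: single- and two-block
# fragments of 30-100 bp, some flagged non-unique.
random_fragments <- function(n = 1000, chrom_length = 60000, seed = 1,
                             chrom = "chrR") {
  set.seed(seed)
  out <- vector("list", n)
  for (f in seq_len(n)) {
    len <- sample(30:100, 1)
    s <- sample.int(chrom_length - len - 3000, 1)
    if (runif(1) < 0.2) {   # spliced: two blocks with a gap
      l1 <- sample(10:(len - 10), 1)
      gap <- sample(20:2000, 1)
      out[[f]] <- data.frame(
        fragment_id = f, chrom = chrom,
        start = c(s, s + l1 + gap), end = c(s + l1, s + len + gap),
        strand = sample(c("+", "-"), 1), is_unique = runif(1) > 0.05)
    } else {
      out[[f]] <- data.frame(fragment_id = f, chrom = chrom,
                             start = s, end = s + len,
                             strand = sample(c("+", "-"), 1),
                             is_unique = runif(1) > 0.05)
    }
  }
  do.call(rbind, out)
}

# interval overlap width of one block against a set of intervals
.ov_width <- function(bs, be, is, ie) {
  sum(pmax(0, pmin(be, ie) - pmax(bs, is)))
}

# Brute-force reimplementation of the counting rules: O(fragments x genes)
# loops over data frames, no GenomicRanges.
oracle_count_sample <- function(fragments, models, min_overlap = 25) {
  fragments <- fragments[fragments$is_unique, , drop = FALSE]
  ids <- sort(unique(fragments$fragment_id))
  genes <- models$genes$gene_id
  exonic <- setNames(integer(length(genes)), genes)
  intronic <- setNames(integer(length(genes)), genes)
  categories <- c(exonic = 0L, intronic = 0L, intergenic = 0L)
  multi <- models$multi_exonic

  # per-gene interval lists, hoisted out of the fragment loop
  ex_by_gene <- split(models$exons, models$exons$gene_id)
  in_by_gene <- split(models$introns, models$introns$gene_id)
  frag_by_id <- split(fragments, fragments$fragment_id)

  for (f in ids) {
    bl <- frag_by_id[[as.character(f)]]
    ex_ov <- in_ov <- setNames(numeric(length(genes)), genes)
    for (g in genes) {
      ge <- ex_by_gene[[g]]
      gi <- in_by_gene[[g]]
      for (b in seq_len(nrow(bl))) {
        if (!is.null(ge) && nrow(ge) > 0 && ge$chrom[1] == bl$chrom[1])
          ex_ov[g] <- ex_ov[g] + .ov_width(bl$start[b], bl$end[b], ge$start, ge$end)
        if (!is.null(gi) && nrow(gi) > 0 && gi$chrom[1] == bl$chrom[1])
          in_ov[g] <- in_ov[g] + .ov_width(bl$start[b], bl$end[b], gi$start, gi$end)
      }
    }
    # region classification: 1 bp rule, exon beats intron
    if (any(ex_ov > 0)) {
      categories["exonic"] <- categories["exonic"] + 1L
    } else if (any(in_ov > 0)) {
      categories["intronic"] <- categories["intronic"] + 1L
    } else {
      categories["intergenic"] <- categories["intergenic"] + 1L
    }
    # gene assignment: min-overlap + multi-gene exclusion + uniqueness
    in_multi <- FALSE
    if (!is.null(multi) && nrow(multi) > 0) {
      for (b in seq_len(nrow(bl))) {
        m <- multi[multi$chrom == bl$chrom[b], , drop = FALSE]
        if (nrow(m) > 0 && .ov_width(bl$start[b], bl$end[b], m$start, m$end) > 0)
          in_multi <- TRUE
      }
    }
    cand <- names(ex_ov)[ex_ov >= min_overlap]
    if (length(cand) == 1 && !in_multi) {
      exonic[cand] <- exonic[cand] + 1L
    } else if (length(cand) == 0 && any(in_ov > 0)) {
      hit <- names(in_ov)[in_ov > 0]
      best <- hit[order(-in_ov[hit], hit)][1]
      intronic[best] <- intronic[best] + 1L
    }
  }
  list(gene_counts = data.frame(gene_id = genes,
                                exonic = as.integer(exonic),
                                intronic = as.integer(intronic),
                                stringsAsFactors = FALSE),
       categories = categories,
       counted_library_size = sum(exonic))
}

# write GTF lines to a temp file and return the path
write_gtf_tmp <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# small hand-written 3-gene GTF used in several annotation tests
toy_gtf_lines <- function() {
  a <- function(g, t, ty) sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";', g, t, ty)
  c(
    paste("chr1", "src", "gene", 101, 400, ".", "+", ".",
          sprintf('gene_id "GA"; gene_type "protein_coding";'), sep = "\t"),
    paste("chr1", "src", "transcript", 101, 400, ".", "+", ".", a("GA", "GA.1", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", a("GA", "GA.1", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", a("GA", "GA.1", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "transcript", 151, 400, ".", "+", ".", a("GA", "GA.2", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 151, 250, ".", "+", ".", a("GA", "GA.2", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", a("GA", "GA.2", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "gene", 1001, 1060, ".", "-", ".",
          sprintf('gene_id "GB"; gene_type "miRNA";'), sep = "\t"),
    paste("chr1", "src", "transcript", 1001, 1060, ".", "-", ".", a("GB", "GB.1", "miRNA"), sep = "\t"),
    paste("chr1", "src", "exon", 1001, 1060, ".", "-", ".", a("GB", "GB.1", "miRNA"), sep = "\t"),
    paste("chr2", "src", "gene", 501, 2000, ".", "+", ".",
          sprintf('gene_id "GC"; gene_type "lincRNA";'), sep = "\t"),
    paste("chr2", "src", "transcript", 501, 2000, ".", "+", ".", a("GC", "GC.1", "lincRNA"), sep = "\t"),
    paste("chr2", "src", "exon", 501, 700, ".", "+", ".", a("GC", "GC.1", "lincRNA"), sep = "\t"),
    paste("chr2", "src", "exon", 1801, 2000, ".", "+", ".", a("GC", "GC.1", "lincRNA"), sep = "\t"),
    paste("chr2", "src", "CDS", 501, 700, ".", "+", ".", a("GC", "GC.1", "lincRNA"), sep = "\t")
  )
}

# single-block fragment row constructor
frag <- function(id, start, end, chrom = "chrR", strand = "+", unique = TRUE) {
  data.frame(fragment_id = id, chrom = chrom, start = start, end = end,
             strand = strand, is_unique = unique, stringsAsFactors = FALSE)
}
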