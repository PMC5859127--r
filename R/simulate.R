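#' Configuration for the toy annotation
#'
#' The default layout emulates the structural scenarios that drive the
#' protocol comparison: intron-dominated multi-exon protein-coding genes
#' (human protein-coding genes are >90% intron by length), a compact
#' globin-like gene with short introns, a highly abundant unspliced
#' lncRNA, a polyA- intron-less histone-like gene, a spliced lncRNA, a
#' processed pseudogene, a dominant free-standing small RNA, a 60 bp small
#' RNA nested inside a host gene's intron, and a receptor constant gene
#' whose long intron contains several 60 bp J-segment genes (all shorter
#' than the 75 bp fragment length).
#'
#' @param n_protein_coding Number of generic protein-coding genes.
#' @param pc_exon_length,pc_intron_length,pc_n_exons Generic protein-coding
#'   gene structure (defaults: 6 exons of 250 bp separated by 5700 bp
#'   introns, i.e. a 30 kb span that is 95% intron).
#' @param gap Intergenic gap between consecutive genes in bp.
#' @param chrom,chrom_length Toy chromosome name and length.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(n_protein_coding = 6, pc_exon_length = 250,
                              pc_intron_length = 5700, pc_n_exons = 6,
                              gap = 5000, chrom = "chrT",
                              chrom_length = 350000L) {
  structure(list(n_protein_coding = n_protein_coding,
                 pc_exon_length = pc_exon_length,
                 pc_intron_length = pc_intron_length,
                 pc_n_exons = pc_n_exons, gap = gap, chrom = chrom,
                 chrom_length = chrom_length),
            class = "annotation_config")
}

# exon starts (0-based, gene-relative) for an alternating exon/intron layout
alt_layout <- function(n_exons, exon_len, intron_len) {
  starts <- (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  cbind(start = starts, end = starts + exon_len)
}

# gene-relative exon matrix from (start, end) pairs
ivl <- function(...) {
  m <- do.call(rbind, list(...))
  colnames(m) <- c("start", "end")
  m
}

#' Generate the toy genome annotation
#'
#' Emits Gencode-dialect GTF text (gene/transcript/exon features with
#' `gene_id`, `transcript_id`, `gene_type` attributes) together with the
#' `gene_models` the GTF is expected to parse back into. One gene carries
#' two transcripts with different exon subsets so that the union-exon
#' collapse is exercised by the round trip. Deterministic: the same config
#' and seed always produce identical output.
#'
#' @param config An [annotation_config()].
#' @param seed Unused randomness hook kept for interface symmetry; the
#'   default layout is fully deterministic.
#' @return list with `gtf` (character vector of GTF lines), `models`
#'   (`gene_models`), and `layout` (per-gene placement table).
#' @export
generate_annotation <- function(config = annotation_config(), seed = 1) {
  chrom <- config$chrom
  gap <- config$gap
  genes <- list()
  add_gene <- function(id, type, strand, exons, n_tx = 1) {
    genes[[length(genes) + 1]] <<- list(id = id, type = type, strand = strand,
                                        exons = exons, n_tx = n_tx)
  }

  for (i in seq_len(config$n_protein_coding)) {
    add_gene(sprintf("PC%d", i), "protein_coding", if (i %% 2) "+" else "-",
             alt_layout(config$pc_n_exons, config$pc_exon_length,
                        config$pc_intron_length),
             n_tx = if (i == 1) 2 else 1)
  }
  # compact globin-like gene: 3 x 200 bp exons, 150 bp introns
  add_gene("GLOBL1", "protein_coding", "+", alt_layout(3, 200, 150))
  # spliced lncRNA: 4 x 250 bp exons, 3667/3667/3666 bp introns
  add_gene("LNC2", "lincRNA", "-",
           ivl(c(0, 250), c(3917, 4167), c(7834, 8084), c(11750, 12000)))
  # dominant unspliced lncRNA (MALAT1-like): one 8 kb exon
  add_gene("MALATL1", "lincRNA", "+", cbind(start = 0, end = 8000))
  # polyA- intron-less histone-like gene
  add_gene("HISTN1", "protein_coding", "+", cbind(start = 0, end = 500))
  # host gene with a 60 bp small RNA nested mid-intron
  add_gene("ARLH1", "protein_coding", "+", ivl(c(0, 300), c(8300, 8600)))
  add_gene("SMR1", "miRNA", "+", cbind(start = 4270, end = 4330),
           )  # placed relative to ARLH1 below
  # receptor constant gene with four 60 bp J-like genes inside its intron
  add_gene("TCACL1", "TR_C_gene", "+", ivl(c(0, 400), c(20400, 20800)))
  for (j in 1:4) {
    add_gene(sprintf("TRAJL%d", j), "TR_J_gene", "+",
             cbind(start = 3000 + (j - 1) * 4000, end = 3060 + (j - 1) * 4000))
  }
  # processed pseudogene and a dominant free-standing small RNA
  add_gene("PSG1", "processed_pseudogene", "-", cbind(start = 0, end = 1000))
  add_gene("RN7SLL1", "misc_RNA", "+", cbind(start = 0, end = 300))

  # place genes left to right; nested genes share their host's offset
  host_of <- c(SMR1 = "ARLH1", TRAJL1 = "TCACL1", TRAJL2 = "TCACL1",
               TRAJL3 = "TCACL1", TRAJL4 = "TCACL1")
  offset <- gap
  placement <- list()
  for (g in genes) {
    if (g$id %in% names(host_of)) next
    placement[[g$id]] <- offset
    offset <- offset + max(g$exons[, "end"]) + gap
  }
  for (nested in names(host_of)) placement[[nested]] <- placement[[host_of[nested]]]
  if (offset > config$chrom_length) {
    stop("layout exceeds chromosome length (need ", offset, " bp, have ",
         config$chrom_length, ")")
  }

  layout <- do.call(rbind, lapply(genes, function(g) {
    off <- placement[[g$id]]
    data.frame(gene_id = g$id, gene_type = g$type, strand = g$strand,
               span_start = off + min(g$exons[, "start"]),
               span_end = off + max(g$exons[, "end"]),
               stringsAsFactors = FALSE)
  }))

  gtf <- character(0)
  attr_str <- function(gid, type, tid = NULL) {
    a <- sprintf('gene_id "%s"; gene_type "%s";', gid, type)
    if (!is.null(tid)) a <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                                    gid, tid, type)
    a
  }
  for (g in genes) {
    off <- placement[[g$id]]
    ex <- g$exons
    ex[, "start"] <- ex[, "start"] + off
    ex[, "end"] <- ex[, "end"] + off
    g1 <- min(ex[, "start"]) + 1L; g2 <- max(ex[, "end"])
    gtf <- c(gtf, paste(chrom, "toy", "gene", g1, g2, ".", g$strand, ".",
                        attr_str(g$id, g$type), sep = "\t"))
    for (t in seq_len(g$n_tx)) {
      tid <- sprintf("%s.t%d", g$id, t)
      # transcript 2 (when present) skips the second exon: union still spans all
      rows <- if (t == 2 && nrow(ex) > 2) setdiff(seq_len(nrow(ex)), 2L) else seq_len(nrow(ex))
      t1 <- min(ex[rows, "start"]) + 1L; t2 <- max(ex[rows, "end"])
      gtf <- c(gtf, paste(chrom, "toy", "transcript", t1, t2, ".", g$strand, ".",
                          attr_str(g$id, g$type, tid), sep = "\t"))
      for (r in rows) {
        gtf <- c(gtf, paste(chrom, "toy", "exon", ex[r, "start"] + 1L,
                            ex[r, "end"], ".", g$strand, ".",
                            attr_str(g$id, g$type, tid), sep = "\t"))
      }
    }
  }

  raw <- list(
    genes = unique(do.call(rbind, lapply(genes, function(g) {
      data.frame(gene_id = g$id, gene_type = g$type,
                 chrom = chrom, strand = g$strand, stringsAsFactors = FALSE)
    }))),
    exons = do.call(rbind, lapply(genes, function(g) {
      off <- placement[[g$id]]
      data.frame(gene_id = g$id, chrom = chrom,
                 start = g$exons[, "start"] + off, end = g$exons[, "end"] + off,
                 strand = g$strand, stringsAsFactors = FALSE)
    }))
  )
  raw$genes <- raw$genes[order(raw$genes$gene_id), , drop = FALSE]
  raw$exons <- raw$exons[order(raw$exons$gene_id, raw$exons$start), , drop = FALSE]
  rownames(raw$genes) <- rownames(raw$exons) <- NULL
  models <- build_gene_models(raw)
  list(gtf = gtf, models = models, layout = layout, chrom = chrom,
       chrom_length = config$chrom_length)
}

#' Default relative abundance of the toy genes
#'
#' Expected share of counted (exonic assigned) reads per gene under the
#' rRNA-depletion protocol. The MALAT1-like lncRNA is pinned at 0.027 of
#' counted reads and the free-standing small RNA at 0.02; the blood preset
#' gives the globin-like gene a large share, the colon preset a negligible
#' one, with the generic protein-coding genes absorbing the remainder.
#'
#' @param tissue `"blood"` or `"colon"`.
#' @param n_protein_coding Number of generic protein-coding genes.
#' @return Named numeric vector summing to 1.
#' @export
default_abundance <- function(tissue = c("blood", "colon"), n_protein_coding = 6) {
  tissue <- match.arg(tissue)
  extras <- c(MALATL1 = 0.027, RN7SLL1 = 0.02, ARLH1 = 0.03, TCACL1 = 0.01,
              LNC2 = 0.006, PSG1 = 0.004, SMR1 = 0.001, HISTN1 = 0.01,
              TRAJL1 = 0.00025, TRAJL2 = 0.00025, TRAJL3 = 0.00025,
              TRAJL4 = 0.00025,
              GLOBL1 = if (tissue == "blood") 0.15 else 0.002)
  pc <- rep((1 - sum(extras)) / n_protein_coding, n_protein_coding)
  names(pc) <- sprintf("PC%d", seq_len(n_protein_coding))
  c(pc, extras)
}

#' Default polyA+ capture probabilities of the toy genes
#'
#' Probability that a transcript of each gene is captured by oligo(dT)
#' selection. Small RNAs, J-segment genes and the histone-like gene are
#' polyA- (capture 0); the MALAT1-like lncRNA is mostly processed to a
#' non-polyadenylated mature form (capture 0.05); mRNAs are fully captured.
#'
#' @param gene_ids Gene ids to cover; unlisted genes default to 1.
#' @return Named numeric vector in \[0, 1\].
#' @export
default_polya_capture <- function(gene_ids) {
  cap <- setNames(rep(1, length(gene_ids)), gene_ids)
  special <- c(MALATL1 = 0.05, LNC2 = 0.7, PSG1 = 0.5, HISTN1 = 0,
               SMR1 = 0, RN7SLL1 = 0, TRAJL1 = 0, TRAJL2 = 0, TRAJL3 = 0,
               TRAJL4 = 0, TCACL1 = 1)
  hit <- intersect(names(special), gene_ids)
  cap[hit] <- special[hit]
  cap
}

#' Simulation configuration for one protocol
#'
#' @param protocol `"polyA"` or `"riboZ"`.
#' @param tissue `"blood"` or `"colon"`; presets differ in the
#'   rRNA-depletion nascent fraction (0.50 vs 0.34) and globin-like
#'   abundance.
#' @param n_fragments Number of fragments to draw.
#' @param nascent_fraction Probability that a fragment comes from an
#'   unspliced nascent transcript (uniform over the gene span). Defaults:
#'   0.06 for polyA+, 0.50 (blood) / 0.34 (colon) for rRNA depletion.
#' @param intergenic_fraction Probability of an intergenic fragment.
#' @param abundance Named per-gene expected share of counted reads; see
#'   [default_abundance()].
#' @param polya_capture Named per-gene capture probability (polyA+ protocol
#'   only); see [default_polya_capture()].
#' @param fragment_length Fragment length in bp (default 75, single- or
#'   two-block).
#' @param seed Integer seed.
#' @return list of class `protocol_sim_config`.
#' @export
protocol_sim_config <- function(protocol = c("polyA", "riboZ"),
                                tissue = c("blood", "colon"),
                                n_fragments = 2e5,
                                nascent_fraction = NULL,
                                intergenic_fraction = 0.02,
                                abundance = NULL, polya_capture = NULL,
                                fragment_length = 75L, seed = 1L) {
  protocol <- match.arg(protocol)
  tissue <- match.arg(tissue)
  nascent_fraction <- nascent_fraction %||%
    if (protocol == "polyA") 0.06 else if (tissue == "blood") 0.50 else 0.34
  stopifnot(nascent_fraction >= 0, nascent_fraction <= 1,
            intergenic_fraction >= 0, intergenic_fraction < 1)
  structure(list(protocol = protocol, tissue = tissue,
                 n_fragments = as.integer(n_fragments),
                 nascent_fraction = nascent_fraction,
                 intergenic_fraction = intergenic_fraction,
                 abundance = abundance, polya_capture = polya_capture,
                 fragment_length = as.integer(fragment_length),
                 seed = as.integer(seed)),
            class = "protocol_sim_config")
}

# Probability that a nascent (single-block, uniform-start) fragment from this
# gene is exonic-assigned to it under the min-overlap rule, computed exactly
# from per-base exon coverage over the gene span.
p_nascent_assigned <- function(models, gene_id, fragment_length, min_overlap = 25L) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  span <- g$span_end - g$span_start
  L <- min(fragment_length, span)
  mask <- integer(span + fragment_length)
  for (i in seq_len(nrow(ex))) {
    mask[(ex$start[i] - g$span_start + 1):(ex$end[i] - g$span_start)] <- 1L
  }
  cm <- c(0L, cumsum(mask))
  starts <- 0:(span - L)                   # fragment start offsets in span
  ov <- cm[pmin(starts + L, span) + 1] - cm[starts + 1]
  mean(ov >= min_overlap)
}

#' Simulate labeled fragments for one protocol
#'
#' Each fragment draws a source: intergenic (uniform over gene-free space),
#' or a gene weighted by the abundance profile corrected for per-gene
#' counting efficiency (so configured abundances are expected shares of
#' counted reads). Under the polyA+ protocol gene weights are additionally
#' multiplied by the polyA capture probability and renormalized. A gene
#' fragment is nascent with probability `nascent_fraction` (a single block
#' uniform over the unspliced gene span) and mature otherwise (uniform over
#' the spliced union-exon transcript, split into two blocks when it crosses
#' a junction; genes shorter than the fragment length yield the whole
#' transcript). Every fragment carries a truth label.
#'
#' @param annotation A [generate_annotation()] result.
#' @param config A [protocol_sim_config()].
#' @return list with `fragments` (block data.frame) and `truth`
#'   (`fragment_id`, `source_gene`, `provenance`, `category`).
#' @export
simulate_fragments <- function(annotation, config) {
  models <- annotation$models
  g <- models$genes
  L <- config$fragment_length
  abundance <- config$abundance %||% default_abundance(config$tissue)
  miss <- setdiff(names(abundance), g$gene_id)
  if (length(miss) > 0) stop("abundance names unknown genes: ",
                             paste(miss, collapse = ", "))

  # counting-efficiency correction: mature fragments always count, nascent
  # fragments count with the gene's geometric assignment probability
  p_nasc <- vapply(names(abundance), function(id)
    p_nascent_assigned(models, id, L), 0)
  p_counted <- (1 - config$nascent_fraction) +
    config$nascent_fraction * p_nasc
  w <- abundance / pmax(p_counted, 1e-9)

  if (config$protocol == "polyA") {
    cap <- config$polya_capture %||% default_polya_capture(names(abundance))
    w <- w * cap[names(abundance)]
    if (sum(w) <= 0) stop("no gene capturable under polyA+ with this config")
  }
  w <- w / sum(w)

  # gene-free gaps for intergenic draws
  span_gr <- GenomicRanges::GRanges(annotation$chrom,
                                    to_iranges(g$span_start, g$span_end))
  gaps_gr <- GenomicRanges::gaps(GenomicRanges::reduce(span_gr, ignore.strand = TRUE))
  gaps_gr <- gaps_gr[GenomicRanges::strand(gaps_gr) == "*"]
  gaps <- granges_to_df(gaps_gr)
  gaps$end <- pmin(gaps$end, annotation$chrom_length)
  gaps <- gaps[gaps$end - gaps$start >= L, , drop = FALSE]

  n <- config$n_fragments
  sim <- with_seed(config$seed, {
    is_intergenic <- runif(n) < config$intergenic_fraction
    gene <- rep(NA_character_, n)
    gene[!is_intergenic] <- sample(names(w), sum(!is_intergenic),
                                   replace = TRUE, prob = w)
    is_nascent <- !is_intergenic & runif(n) < config$nascent_fraction
    u_pos <- runif(n)
    u_gap <- sample.int(nrow(gaps), n, replace = TRUE,
                        prob = gaps$end - gaps$start - L + 1)
    list(is_intergenic = is_intergenic, gene = gene, is_nascent = is_nascent,
         u_pos = u_pos, u_gap = u_gap)
  })

  blocks <- vector("list", 4)
  truth_prov <- rep(NA_character_, n)

  # intergenic fragments
  ig <- which(sim$is_intergenic)
  if (length(ig) > 0) {
    gp <- gaps[sim$u_gap[ig], , drop = FALSE]
    s <- gp$start + floor(sim$u_pos[ig] * (gp$end - gp$start - L + 1))
    blocks[[1]] <- data.frame(fragment_id = ig, chrom = annotation$chrom,
                              start = s, end = s + L, strand = "+",
                              is_unique = TRUE, stringsAsFactors = FALSE)
    truth_prov[ig] <- "intergenic"
  }

  ex_by_gene <- split(models$exons, models$exons$gene_id)
  out_nascent <- out_mature <- list()
  for (id in unique(sim$gene[!is.na(sim$gene)])) {
    gi <- g[g$gene_id == id, ]
    idx_n <- which(!is.na(sim$gene) & sim$gene == id & sim$is_nascent)
    idx_m <- which(!is.na(sim$gene) & sim$gene == id & !sim$is_nascent)
    span <- gi$span_end - gi$span_start
    ex <- ex_by_gene[[id]]
    ex <- ex[order(ex$start), , drop = FALSE]

    if (length(idx_n) > 0) {
      Ln <- min(L, span)
      s <- gi$span_start + floor(sim$u_pos[idx_n] * (span - Ln + 1))
      out_nascent[[id]] <- data.frame(fragment_id = idx_n,
                                      chrom = annotation$chrom,
                                      start = s, end = s + Ln,
                                      strand = gi$strand, is_unique = TRUE,
                                      stringsAsFactors = FALSE)
      # nascent fragments touching an exon of the source gene are exonic
      touches <- rep(FALSE, length(idx_n))
      for (i in seq_len(nrow(ex))) {
        touches <- touches | (s < ex$end[i] & s + Ln > ex$start[i])
      }
      truth_prov[idx_n] <- ifelse(touches, "nascent_exonic", "nascent_intronic")
    }
    if (length(idx_m) > 0) {
      widths <- ex$end - ex$start
      coff <- cumsum(c(0, widths))          # transcript-coordinate offsets
      tlen <- sum(widths)
      Lm <- min(L, tlen)
      ts <- floor(sim$u_pos[idx_m] * (tlen - Lm + 1))
      te <- ts + Lm
      # map [ts, te) in transcript coords to genomic blocks
      for (i in seq_len(nrow(ex))) {
        lo <- pmax(ts, coff[i]); hi <- pmin(te, coff[i + 1])
        hit <- hi > lo
        if (any(hit)) {
          out_mature[[paste(id, i)]] <- data.frame(
            fragment_id = idx_m[hit], chrom = annotation$chrom,
            start = ex$start[i] + lo[hit] - coff[i],
            end = ex$start[i] + hi[hit] - coff[i],
            strand = gi$strand, is_unique = TRUE, stringsAsFactors = FALSE)
        }
      }
      truth_prov[idx_m] <- "mature_exonic"
    }
  }

  fragments <- rbind(blocks[[1]],
                     do.call(rbind, out_nascent),
                     do.call(rbind, out_mature))
  fragments <- fragments[order(fragments$fragment_id, fragments$start), ,
                         drop = FALSE]
  rownames(fragments) <- NULL

  truth <- data.frame(
    fragment_id = seq_len(n),
    source_gene = sim$gene,
    provenance = truth_prov,
    category = g$category[match(sim$gene, g$gene_id)],
    stringsAsFactors = FALSE
  )
  list(fragments = fragments, truth = truth, config = config)
}

# Overlap of fragment blocks against sorted disjoint intervals, base-R path
# (findInterval), independent of the GenomicRanges machinery used in counting.
.blocks_touch <- function(starts, ends, ivl_start, ivl_end) {
  if (length(ivl_start) == 0) return(rep(FALSE, length(starts)))
  o <- order(ivl_start)
  ss <- ivl_start[o]; ee <- ivl_end[o]
  idx <- findInterval(starts, ss)
  left <- idx >= 1 & ifelse(idx >= 1, ee[pmax(idx, 1)] > starts, FALSE)
  right <- idx < length(ss) & ss[pmin(idx + 1, length(ss))] < ends
  left | right
}

#' Exact truth tallies from simulation labels
#'
#' Computes, from the truth labels and the annotation geometry (via an
#' independent base-R interval check), the quantities used as recovery
#' targets: per-gene fragment and mature-fragment shares, the
#' geometry-adjusted intronic fraction (fragments overlapping no exon of any
#' gene but overlapping an intron — the quantity the library-level intronic
#' category measures), and the set of genes with nonzero mature
#' transcription.
#'
#' @param sim A [simulate_fragments()] result.
#' @param models The `gene_models` the simulation used.
#' @return list with `n_fragments`, `per_gene` (draw and mature shares),
#'   `label_intronic_fraction`, `geom_intronic_fraction`,
#'   `geom_exonic_fraction`, `true_present_genes`.
#' @export
truth_summaries <- function(sim, models) {
  truth <- sim$truth
  frag <- sim$fragments
  n <- nrow(truth)

  ex <- models$exons
  red_ex <- granges_to_df(GenomicRanges::reduce(to_granges(ex)))
  red_in <- if (nrow(models$introns) > 0) {
    granges_to_df(GenomicRanges::reduce(to_granges(models$introns)))
  } else data.frame(start = integer(0), end = integer(0))

  t_ex <- .blocks_touch(frag$start, frag$end, red_ex$start, red_ex$end)
  t_in <- .blocks_touch(frag$start, frag$end, red_in$start, red_in$end)
  any_ex <- tapply(t_ex, frag$fragment_id, any)
  any_in <- tapply(t_in, frag$fragment_id, any)
  ids <- as.integer(names(any_ex))
  geom_exonic <- sum(any_ex)
  geom_intronic <- sum(!any_ex & any_in)

  tg <- table(factor(truth$source_gene, models$genes$gene_id))
  tm <- table(factor(truth$source_gene[truth$provenance == "mature_exonic"],
                     models$genes$gene_id))
  per_gene <- data.frame(gene_id = models$genes$gene_id,
                         n_fragments = as.integer(tg),
                         n_mature = as.integer(tm),
                         draw_share = as.integer(tg) / n,
                         mature_share = as.integer(tm) / n,
                         stringsAsFactors = FALSE)
  list(n_fragments = n,
       per_gene = per_gene,
       label_intronic_fraction = mean(truth$provenance == "nascent_intronic"),
       geom_intronic_fraction = geom_intronic / n,
       geom_exonic_fraction = geom_exonic / n,
       true_present_genes = per_gene$gene_id[per_gene$n_mature > 0])
}
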