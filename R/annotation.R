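#' Parse a Gencode-dialect GTF into raw gene records
#'
#' Reads `gene`/`transcript`/`exon` features and groups the exon intervals by
#' `gene_id`. Coordinates are converted from the GTF's 1-based closed
#' convention to the package-internal 0-based half-open convention. Feature
#' types other than gene/transcript/exon are skipped. The result does not
#' depend on the order of lines in the file.
#'
#' @param path Path to a GTF file (uncompressed or gzip).
#' @return A list with elements:
#'   \describe{
#'     \item{genes}{data.frame with `gene_id`, `gene_type`, `chrom`, `strand`.}
#'     \item{exons}{data.frame of raw (pre-union) exon intervals with
#'       `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`.}
#'   }
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_lines(path)

  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$gene_id)) stop("GTF has no gene_id attribute")
  if (is.null(meta$gene_type)) stop("GTF has no gene_type attribute")

  keep <- meta$type %in% c("gene", "transcript", "exon")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("parse_gtf: skipped ", n_skipped, " non-gene/transcript/exon features")
  }
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)

  is_exon <- meta$type == "exon"
  if (!any(is_exon)) stop("GTF contains no exon features")
  ex <- gr[is_exon]
  exons <- data.frame(
    gene_id = S4Vectors::mcols(ex)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$gene_id, exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL

  # One row per gene; gene_type taken from the first record seen for the id.
  first <- !duplicated(meta$gene_id)
  genes <- data.frame(
    gene_id = meta$gene_id[first],
    gene_type = meta$gene_type[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  missing <- setdiff(exons$gene_id, genes$gene_id)
  if (length(missing) > 0) stop("exons reference unknown gene ids: ",
                                paste(missing, collapse = ", "))
  list(genes = genes, exons = exons)
}

# Cheap structural scan so malformed lines are reported with their number;
# rtracklayer's own errors do not carry line positions.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(body)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF line ", idx[which(nf < 9)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf < 9)[1]])
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    stop("malformed GTF line ", idx[bad], ": non-numeric coordinates")
  }
  if (any(ends < starts)) {
    bad <- which(ends < starts)[1]
    stop("invalid GTF line ", idx[bad], ": end < start")
  }
  has_attr <- grepl("gene_id\\s+\"[^\"]*\"", vapply(fields, `[[`, "", 9L))
  feat <- vapply(fields, `[[`, "", 3L)
  need <- feat %in% c("gene", "transcript", "exon")
  if (any(need & !has_attr)) {
    bad <- which(need & !has_attr)[1]
    stop("malformed attribute block at GTF line ", idx[bad], ": missing gene_id")
  }
  invisible(TRUE)
}

#' Default mapping from Gencode gene_type to the five biotype categories
#'
#' The five-way collapse used throughout: protein-coding, lncRNA, pseudogene,
#' small RNA, and TCR/BCR. Any `gene_type` containing "pseudogene" is a
#' pseudogene; `TR_*`/`IG_*` receptor segment types are TCR/BCR; the Gencode
#' long-noncoding set maps to lncRNA; common short noncoding classes map to
#' small RNA. Unknown strings fall through to "other".
#'
#' @return data.frame with columns `gene_type` and `category`.
#' @export
default_biotype_map <- function() {
  path <- system.file("extdata", "biotype_map.tsv", package = "prepcompare")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Collapse Gencode gene_type strings to the five biotype categories
#'
#' @param gene_type Character vector of Gencode `gene_type` strings.
#' @param map Mapping table as from [default_biotype_map()]; rule-based
#'   fallbacks (substring "pseudogene", prefixes `TR_`/`IG_`) apply to types
#'   absent from the table.
#' @return Character vector over
#'   `{protein-coding, lncRNA, pseudogene, small RNA, TCR/BCR, other}`.
#'   A warning lists types mapped to "other".
#' @export
classify_biotype <- function(gene_type, map = default_biotype_map()) {
  out <- map$category[match(gene_type, map$gene_type)]
  miss <- is.na(out)
  # rule fallbacks for the open-ended Gencode families
  out[miss & grepl("pseudogene", gene_type)] <- "pseudogene"
  miss <- is.na(out)
  out[miss & grepl("^(TR|IG)_", gene_type)] <- "TCR/BCR"
  miss <- is.na(out)
  if (any(miss)) {
    warning("unmapped gene_type(s) assigned to 'other': ",
            paste(unique(gene_type[miss]), collapse = ", "))
    out[miss] <- "other"
  }
  out
}

#' Category levels of the five-way biotype classification
#' @export
biotype_categories <- function() {
  c("protein-coding", "lncRNA", "pseudogene", "small RNA", "TCR/BCR")
}

#' Build union-exon gene models from raw GTF records
#'
#' Each gene's transcript exons are collapsed to their interval union; the
#' introns are the complementary intervals within the gene span, so union
#' exons and introns tile the span exactly. Single-exon genes get an empty
#' intron set. Gene-overlap flags mark genes whose span intersects another
#' gene's span (strand-blind by default), and exonic positions covered by
#' two or more distinct genes are collected as multi-gene regions, which the
#' counting stage excludes from gene assignment.
#'
#' @param raw A list as returned by [parse_gtf()].
#' @param biotype_map Mapping table for [classify_biotype()].
#' @param overlap_stranded If `TRUE`, span overlap between genes is only
#'   flagged for genes on the same strand. Default `FALSE` (strand-blind).
#' @return An object of class `gene_models`: list with `genes` (one row per
#'   gene: `gene_id`, `gene_type`, `category`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `exonic_length`, `n_introns`, `intron_length`,
#'   `overlaps_other_gene`), `exons` and `introns` (per-gene disjoint sorted
#'   intervals, 0-based half-open), and `multi_exonic` (multi-gene exonic
#'   regions).
#' @export
build_gene_models <- function(raw, biotype_map = default_biotype_map(),
                              overlap_stranded = FALSE) {
  genes <- raw$genes
  exons <- raw$exons
  if (nrow(exons) == 0) stop("no exons to build gene models from")
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon) > 0) {
    genes <- genes[!genes$gene_id %in% no_exon, , drop = FALSE]
  }

  # exons of a gene must agree on chromosome and strand
  chk <- data.table::as.data.table(exons)[
    , list(nchrom = data.table::uniqueN(chrom),
           nstrand = data.table::uniqueN(strand)), by = "gene_id"]
  bad <- chk$gene_id[chk$nchrom > 1 | chk$nstrand > 1]
  if (length(bad) > 0) {
    stop("gene(s) with exons on mixed chromosomes/strands: ",
         paste(bad, collapse = ", "))
  }
  if (any(exons$end <= exons$start)) stop("exon with non-positive width")

  gene_ids <- sort(unique(exons$gene_id))
  genes <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]

  ex_gr <- GenomicRanges::GRanges(exons$chrom, to_iranges(exons$start, exons$end))
  red <- unlist(range(GenomicRanges::split(ex_gr, factor(exons$gene_id, gene_ids))))
  union_list <- GenomicRanges::reduce(
    GenomicRanges::split(ex_gr, factor(exons$gene_id, gene_ids)))
  union_gr <- unlist(union_list)
  union_gene <- rep(gene_ids, S4Vectors::elementNROWS(union_list))

  # introns = span minus union exons, per gene
  span_list <- range(GenomicRanges::split(ex_gr, factor(exons$gene_id, gene_ids)))
  intron_list <- GenomicRanges::psetdiff(unlist(span_list), union_list)
  intron_gr <- unlist(intron_list)
  intron_gene <- rep(gene_ids, S4Vectors::elementNROWS(intron_list))

  union_df <- cbind(gene_id = union_gene, granges_to_df(union_gr))
  intron_df <- if (length(intron_gr) > 0) {
    cbind(gene_id = intron_gene, granges_to_df(intron_gr))
  } else {
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  }
  rownames(union_df) <- rownames(intron_df) <- NULL

  spans <- unlist(span_list)
  ex_len <- vapply(GenomicRanges::width(union_list), sum, 0L)
  n_intr <- S4Vectors::elementNROWS(intron_list)
  intr_len <- vapply(GenomicRanges::width(intron_list), sum, 0L)

  out_genes <- data.frame(
    gene_id = gene_ids,
    gene_type = genes$gene_type,
    category = classify_biotype(genes$gene_type, biotype_map),
    chrom = union_df$chrom[match(gene_ids, union_df$gene_id)],
    strand = exons$strand[match(gene_ids, exons$gene_id)],
    span_start = GenomicRanges::start(spans) - 1L,
    span_end = GenomicRanges::end(spans),
    exonic_length = as.integer(ex_len),
    n_introns = as.integer(n_intr),
    intron_length = as.integer(intr_len),
    overlaps_other_gene = FALSE,
    stringsAsFactors = FALSE
  )

  models <- structure(
    list(genes = out_genes, exons = union_df, introns = intron_df,
         multi_exonic = NULL),
    class = "gene_models"
  )
  compute_overlap_flags(models, stranded = overlap_stranded)
}

#' Set gene-overlap flags and multi-gene exonic regions
#'
#' `overlaps_other_gene` is true iff a gene's span intersects any other
#' gene's span on the same chromosome; this feeds the intron-rate filter.
#' Separately, exonic positions covered by union exons of two or more
#' distinct genes form the multi-gene regions that fragment assignment
#' excludes.
#'
#' @param models A `gene_models` object.
#' @param stranded If `TRUE`, only same-strand genes can overlap.
#' @return The models with `genes$overlaps_other_gene` and `multi_exonic` set.
#' @export
compute_overlap_flags <- function(models, stranded = FALSE) {
  g <- models$genes
  span_gr <- GenomicRanges::GRanges(
    g$chrom, to_iranges(g$span_start, g$span_end),
    strand = if (stranded) g$strand else "*")
  hits <- GenomicRanges::findOverlaps(span_gr, span_gr,
                                      ignore.strand = !stranded)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  g$overlaps_other_gene <- seq_len(nrow(g)) %in% S4Vectors::queryHits(hits)
  models$genes <- g

  ex_gr <- GenomicRanges::GRanges(models$exons$chrom,
                                  to_iranges(models$exons$start, models$exons$end))
  cov <- GenomicRanges::coverage(ex_gr)
  multi <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L, rangesOnly = TRUE))
  models$multi_exonic <- granges_to_df(multi)
  models
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$exons), "union exons,", nrow(x$introns), "introns\n")
  tab <- table(x$genes$category)
  cat("categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write gene models as BED12 with a JSON sidecar
#'
#' One BED12 record per gene (blocks = union exons) for inspection in a
#' genome browser, plus a JSON sidecar holding the per-gene summary table.
#'
#' @param models A `gene_models` object.
#' @param bed_path,json_path Output paths.
#' @export
write_gene_models <- function(models, bed_path, json_path = NULL) {
  g <- models$genes
  ex <- split(models$exons, models$exons$gene_id)
  rows <- vapply(g$gene_id, function(id) {
    e <- ex[[id]]
    e <- e[order(e$start), , drop = FALSE]
    paste(e$chrom[1], min(e$start), max(e$end), id, 0,
          g$strand[g$gene_id == id], min(e$start), max(e$end), "0",
          nrow(e), paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - min(e$start), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, bed_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(g, json_path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(bed_path)
}
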