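# one gene with exons [100,200)+[400,500), intron [200,400); and a second
# gene far away at [5000,6000) single exon
two_gene_models <- function() {
  build_gene_models(list(
    genes = data.frame(gene_id = c("G1", "G2"),
                       gene_type = "protein_coding",
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("G1", "G1", "G2"), chrom = "chrR",
                       start = c(100, 400, 5000), end = c(200, 500, 6000),
                       strand = "+")
  ))
}

test_that("region classification follows the 1 bp overlap rule", {
  m <- two_gene_models()
  fr <- rbind(frag(1, 150, 190),    # inside exon
              frag(2, 250, 270),    # inside intron
              frag(3, 8000, 8050),  # gene-free
              frag(4, 195, 230))    # straddles exon/intron boundary -> exonic
  reg <- classify_read_region(fr, m)
  expect_equal(reg$region, c("exonic", "intronic", "intergenic", "exonic"))
})

test_that("gene assignment honors minOverlap, ambiguity and overlap exclusion", {
  m <- two_gene_models()
  # 40 bp exon overlap, one gene -> assigned
  a <- assign_fragments(frag(1, 150, 190), m)
  expect_equal(a$status, "exonic_assigned")
  expect_equal(a$gene_id, "G1")

  # 10 bp on the exon, 65 bp in the intron -> below minOverlap, intronic tally
  b <- assign_fragments(frag(1, 190, 265), m)
  expect_equal(b$status, "intronic")
  expect_equal(b$gene_id, "G1")

  # 24 bp exon overlap fails, 25 passes (boundary of the rule)
  expect_equal(assign_fragments(frag(1, 176, 275), m)$status, "intronic")
  expect_equal(assign_fragments(frag(1, 175, 275), m)$status, "exonic_assigned")

  # two genes sharing exonic sequence: multi-gene region -> excluded
  m2 <- build_gene_models(list(
    genes = data.frame(gene_id = c("A", "B"), gene_type = "protein_coding",
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("A", "B"), chrom = "chrR",
                       start = c(100, 150), end = c(300, 350), strand = "+")
  ))
  d <- assign_fragments(frag(1, 160, 260), m2)
  expect_equal(d$status, "excluded_overlap")
  expect_true(is.na(d$gene_id))

  # two candidate genes without shared exon bases: ambiguous, counted for neither
  m3 <- build_gene_models(list(
    genes = data.frame(gene_id = c("A", "B"), gene_type = "protein_coding",
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("A", "A", "B"), chrom = "chrR",
                       start = c(0, 600, 100), end = c(50, 700, 500), strand = "+")
  ))
  spliced <- data.frame(fragment_id = 1, chrom = "chrR",
                        start = c(10, 120), end = c(50, 160),
                        strand = "+", is_unique = TRUE)
  e <- assign_fragments(spliced, m3)
  expect_equal(e$status, "ambiguous")

  expect_error(assign_fragments(frag(1, 150, 190), m, min_overlap = 0),
               "positive")
})

test_that("intronic ties go to the longest overlap, then lexicographic id", {
  # fragment spans the adjacent intron ends of two nested-intron genes
  m <- build_gene_models(list(
    genes = data.frame(gene_id = c("GA", "GB"), gene_type = "protein_coding",
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("GA", "GA", "GB", "GB"), chrom = "chrR",
                       start = c(0, 1000, 2000, 3000),
                       end = c(100, 1100, 2100, 3100), strand = "+")
  ))
  # 50 bp in GA's intron [100,1000), 25 bp in nothing else: intronic for GA
  a <- assign_fragments(frag(1, 500, 550), m)
  expect_equal(a$gene_id, "GA")

  # overlapping genes with a shared intron region: construct equal overlaps
  m2 <- build_gene_models(list(
    genes = data.frame(gene_id = c("GB", "GA"), gene_type = "protein_coding",
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("GB", "GB", "GA", "GA"), chrom = "chrR",
                       start = c(0, 900, 0, 900), end = c(50, 1000, 50, 1000),
                       strand = "+")
  ))
  # both genes have intron [50,900); equal overlap -> lexicographic: GA
  t1 <- assign_fragments(frag(1, 400, 460), m2)
  expect_equal(t1$status, "intronic")
  expect_equal(t1$gene_id, "GA")
})

test_that("count_sample satisfies its accounting invariants", {
  raw <- random_raw_records(n_genes = 25, chrom_length = 40000, seed = 11)
  m <- build_gene_models(raw)
  fr <- random_fragments(n = 2000, chrom_length = 40000, seed = 12)
  cs <- count_sample(fr, m, "s1")

  n_unique <- length(unique(fr$fragment_id[fr$is_unique]))
  expect_equal(sum(cs$categories), n_unique)
  expect_lte(cs$counted_library_size, cs$categories[["exonic"]])
  expect_equal(cs$counted_library_size, sum(cs$gene_counts$exonic))
  expect_true(all(cs$gene_counts$exonic >= 0 & cs$gene_counts$intronic >= 0))

  # permuting fragment order changes nothing
  perm <- fr[sample(nrow(fr)), ]
  cs2 <- count_sample(perm, m, "s1")
  expect_equal(cs2$gene_counts, cs$gene_counts)
  expect_equal(cs2$categories, cs$categories)
})

test_that("counting equals the nested-loop oracle on a random fixture", {
  raw <- random_raw_records(n_genes = 20, chrom_length = 30000, seed = 21)
  m <- build_gene_models(raw)
  fr <- random_fragments(n = 800, chrom_length = 30000, seed = 22)
  cs <- count_sample(fr, m, "s1")
  orc <- oracle_count_sample(fr, m)
  expect_equal(cs$gene_counts, orc$gene_counts)
  expect_equal(cs$categories, orc$categories)
  expect_equal(cs$counted_library_size, orc$counted_library_size)
})

test_that("exonic percentages reproduce the published per-replicate values", {
  tab <- replicate_qc_table()
  expect_equal(exonic_pct(tab$exonic_reads, tab$total_reads), tab$exonic_pct)
  expect_equal(exonic_pct(38254168, 50000000), 76.51)
  expect_equal(exonic_pct(11665272, 50000000), 23.33)
})

test_that("subsampling is uniform, reproducible and order-independent", {
  fr <- random_fragments(n = 1000, chrom_length = 30000, seed = 5)
  expect_setequal(subsample_fragments(fr, 1000, seed = 1)$fragment_id,
                  fr$fragment_id)
  expect_equal(nrow(subsample_fragments(fr, 0, seed = 1)), 0)
  s1 <- subsample_fragments(fr, 100, seed = 9)
  s2 <- subsample_fragments(fr, 100, seed = 9)
  expect_identical(s1, s2)
  s3 <- subsample_fragments(fr, 100, seed = 10)
  expect_false(identical(sort(unique(s1$fragment_id)),
                         sort(unique(s3$fragment_id))))
  # input order must not matter
  s4 <- subsample_fragments(fr[sample(nrow(fr)), ], 100, seed = 9)
  expect_equal(sort(unique(s4$fragment_id)), sort(unique(s1$fragment_id)))
  expect_error(subsample_fragments(fr, 1001, seed = 1), "cannot subsample")
})

test_that("non-unique fragments are dropped before counting", {
  m <- two_gene_models()
  fr <- rbind(frag(1, 150, 190), frag(2, 150, 190, unique = FALSE))
  cs <- count_sample(fr, m, "s")
  expect_equal(cs$n_unique_fragments, 1L)
  expect_equal(sum(cs$gene_counts$exonic), 1L)
})

test_that("fragments round-trip through BED12", {
  fr <- random_fragments(n = 50, chrom_length = 30000, seed = 31)
  fr <- validate_fragments(fr)
  path <- tempfile(fileext = ".bed")
  write_fragments_bed12(fr, path)
  back <- read_fragments_bed12(path)
  back <- back[order(as.integer(back$fragment_id), back$start), ]
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  expect_equal(back$is_unique, fr$is_unique)
  expect_equal(as.integer(back$fragment_id), fr$fragment_id)
})

test_that("empty fragment sets yield an all-zero column with a warning", {
  m <- two_gene_models()
  fr <- frag(1, 150, 190)[0, ]
  expect_warning(cs <- count_sample(fr, m, "empty"), "empty")
  expect_equal(sum(cs$gene_counts$exonic), 0L)
  expect_equal(sum(cs$categories), 0L)
})
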