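test_that("RPKM and CPM follow their definitions and invert algebraically", {
  expect_equal(compute_rpkm(10, 2000, 1e6), 5)
  expect_equal(compute_rpkm(0, 2000, 1e6), 0)
  expect_equal(compute_cpm(151, 1e6), 151)
  expect_equal(compute_cpm(numeric(5), 1e6), numeric(5))

  set.seed(1)
  counts <- matrix(rpois(60, 40), 20, 3)
  len <- sample(200:5000, 20)
  lib <- colSums(counts)
  rpkm <- compute_rpkm(counts, len, lib)
  # algebraic inversion reconstructs the counts exactly
  back <- sweep(rpkm * (len / 1000), 2, lib / 1e6, "*")
  expect_equal(back, counts, tolerance = 1e-12)

  cpm <- compute_cpm(counts, lib)
  expect_equal(colSums(cpm), rep(1e6, 3), ignore_attr = TRUE)

  expect_error(compute_rpkm(1, 1000, 0), "positive")
  expect_error(compute_rpkm(1, 0, 1e6), "positive")
})

test_that("replicate merging sums counts and equals pooled recounting", {
  m <- build_gene_models(random_raw_records(10, 20000, seed = 2))
  f1 <- random_fragments(400, 20000, seed = 3)
  f2 <- random_fragments(400, 20000, seed = 4)
  c1 <- count_sample(f1, m, "r1")
  c2 <- count_sample(f2, m, "r2")
  ct <- build_count_table(list(c1, c2))

  # identity for singleton groups
  mg <- merge_replicates(ct$exonic, c("a", "b"), ct$counted_library_size)
  expect_equal(mg$counts[, "a"], ct$exonic[, "r1"], ignore_attr = TRUE)

  # 4 equal replicates -> 4x counts
  four <- cbind(ct$exonic[, 1], ct$exonic[, 1], ct$exonic[, 1], ct$exonic[, 1])
  mg4 <- merge_replicates(four, rep("g", 4))
  expect_equal(mg4$counts[, "g"], 4 * ct$exonic[, 1], ignore_attr = TRUE)

  # merged RPKM equals RPKM of pooled fragments
  f2p <- f2
  f2p$fragment_id <- f2p$fragment_id + max(f1$fragment_id)
  pooled <- count_sample(rbind(f1, f2p), m, "pool")
  mg <- merge_replicates(ct$exonic, c("g", "g"), ct$counted_library_size)
  len <- m$genes$exonic_length
  expect_equal(
    compute_rpkm(mg$counts[, "g"], len, mg$library_size[["g"]]),
    compute_rpkm(pooled$gene_counts$exonic, len, pooled$counted_library_size),
    ignore_attr = TRUE)

  expect_error(merge_replicates(ct$exonic, "a"), "group")
})

test_that("detection classes partition genes with a strict threshold", {
  expect_equal(as.character(detection_classes(c(0.2, 0.2, 0.05, 0.05, 0.1),
                                              c(0.2, 0.05, 0.2, 0.05, 0.1))),
               c("Both", "PolyA", "RiboZ", "None", "None"))
  set.seed(8)
  a <- runif(500, 0, 0.3); b <- runif(500, 0, 0.3)
  cls <- detection_classes(a, b)
  # per-gene loop oracle
  oracle <- vapply(seq_along(a), function(i) {
    if (a[i] > 0.1 && b[i] > 0.1) "Both"
    else if (a[i] > 0.1) "PolyA"
    else if (b[i] > 0.1) "RiboZ"
    else "None"
  }, "")
  expect_equal(as.character(cls), oracle)
  expect_equal(sum(table(cls)), 500L)   # partition
})

test_that("biotype breakdowns are normalized fractions", {
  m <- build_gene_models(list(
    genes = data.frame(gene_id = sprintf("g%d", 1:10),
                       gene_type = c(rep("protein_coding", 5), "lincRNA",
                                     "lincRNA", "miRNA", "processed_pseudogene",
                                     "TR_J_gene"),
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chrR",
                       start = seq(0, 9000, 1000),
                       end = seq(0, 9000, 1000) + 100, strand = "+")
  ))
  bb <- biotype_breakdown(m, gene_ids = sprintf("g%d", 1:10))
  expect_equal(sum(bb$gene_fraction), 1)
  expect_equal(bb$gene_fraction,
               c(0.5, 0.2, 0.1, 0.1, 0.1))   # hand tally

  counts <- setNames(c(90, 0, 0, 0, 0, 5, 0, 3, 2, 0), sprintf("g%d", 1:10))
  rb <- biotype_breakdown(m, counts = counts)
  expect_equal(sum(rb$read_fraction), 1)
  expect_equal(rb$read_fraction, c(0.9, 0.05, 0.02, 0.03, 0))

  all_pc <- biotype_breakdown(m, gene_ids = sprintf("g%d", 1:5))
  expect_equal(all_pc$gene_fraction[all_pc$category == "protein-coding"], 1)
})

test_that("usable fraction and extra-depth arithmetic", {
  expect_equal(usable_fraction(35.5e6, 50e6), 0.71)
  expect_equal(usable_fraction(0, 50e6), 0)
  expect_error(usable_fraction(1, 0), "positive")

  expect_equal(extra_depth_required(0.5, 0.25)$raw, 100)
  expect_equal(extra_depth_required(0.5, 0.25)$rounded, 100)
  expect_equal(extra_depth_required(0.3, 0.3)$raw, 0)
  # monotone decreasing in the rRNA-depletion fraction
  r <- vapply(seq(0.1, 0.7, 0.1),
              function(f) extra_depth_required(0.7, f)$raw, 0)
  expect_true(all(diff(r) < 0))
  expect_error(extra_depth_required(0.7, 0), "positive")
})

test_that("correlation matrix filters low expression and matches the textbook formula", {
  m <- build_gene_models(random_raw_records(10, 20000, seed = 13))
  f1 <- random_fragments(600, 20000, seed = 14)
  c1 <- count_sample(f1, m, "s1")
  c2 <- count_sample(f1, m, "s2")           # duplicated sample
  ct <- build_count_table(list(c1, c2))
  expr <- expression_matrix(ct, m)
  cm <- correlation_matrix(expr)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(unname(diag(cm)), c(1, 1))
  expect_equal(cm[1, 2], 1)

  # textbook-formula oracle on a toy 5x3 matrix
  toy_cpm <- matrix(c(10, 40, 0, 7, 100,
                      12, 35, 1, 9, 90,
                      50, 2, 3, 80, 5), 5, 3)
  toy <- list(cpm = toy_cpm, rpkm = toy_cpm)   # all pass the filter
  cm2 <- correlation_matrix(toy, rpkm_filter = 0)
  x <- log2(toy_cpm + 1)
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm2[i, j], pearson(x[, i], x[, j]))
  }

  # genes below the filter in every sample are removed before correlating:
  # only one gene survives here, which is not enough to correlate
  rpkm <- matrix(c(0.4, 0.4, 5, 5, 0.2, 0.2), 3, 2, byrow = TRUE)
  cpm <- matrix(c(1, 100, 5, 5, 1, 100), 3, 2, byrow = TRUE)
  expect_error(correlation_matrix(list(rpkm = rpkm, cpm = cpm)), "survive")
})

test_that("per-biotype concordance flags large fold changes", {
  m <- build_gene_models(list(
    genes = data.frame(gene_id = c("p1", "p2", "p3", "n1", "n2"),
                       gene_type = c(rep("protein_coding", 3), "lincRNA",
                                     "lincRNA"),
                       chrom = "chrR", strand = "+"),
    exons = data.frame(gene_id = c("p1", "p2", "p3", "n1", "n2"),
                       chrom = "chrR", start = seq(0, 4000, 1000),
                       end = seq(0, 4000, 1000) + 200, strand = "+")
  ))
  cpm <- setNames(c(10, 50, 200, 5, 80), m$genes$gene_id)
  pc1 <- m$genes$gene_id[m$genes$category == "protein-coding"][1]
  same <- concordance_by_biotype(cpm, cpm, m)
  expect_equal(same$by_category$r[1:2], c(1, 1))
  expect_equal(nrow(same$flagged), 0)

  other <- cpm
  other[["p1"]] <- 0
  one <- concordance_by_biotype(other, cpm, m)   # p1: 0 -> 10? |log2(11/1)| > 3
  # flag oracle per gene
  lf <- log2((cpm + 1) / (other + 1))
  expect_setequal(one$flagged$gene_id, names(lf)[abs(lf) > 4])

  lo <- cpm; lo[[pc1]] <- 0
  hi <- cpm; hi[[pc1]] <- 100
  flagged <- concordance_by_biotype(lo, hi, m)
  expect_equal(flagged$flagged$gene_id, pc1)
  expect_gt(abs(flagged$flagged$log2fc), 4)

  empty_cat <- concordance_by_biotype(cpm, cpm, m)$by_category
  expect_true(is.na(empty_cat$r[empty_cat$category == "pseudogene"]))
})

test_that("intron rate applies the formula and the three gene filters", {
  # gene A: introns, clean; gene B: no introns; gene C,D: mutually overlapping
  m <- build_gene_models(list(
    genes = data.frame(gene_id = c("A", "B", "C", "D"),
                       gene_type = "protein_coding", chrom = "chrR",
                       strand = "+"),
    exons = data.frame(gene_id = c("A", "A", "B", "C", "C", "D"),
                       chrom = "chrR",
                       start = c(0, 900, 2000, 5000, 5900, 5400),
                       end = c(100, 1000, 2500, 5100, 6000, 5460),
                       strand = "+")
  ))
  exo <- matrix(c(70, 10, 10, 10), 4, 1,
                dimnames = list(c("A", "B", "C", "D"), "s1"))
  intr <- matrix(c(30, 0, 5, 0), 4, 1, dimnames = dimnames(exo))
  ct <- structure(list(exonic = exo, intronic = intr), class = "count_table")
  rpkm <- matrix(5, 4, 1, dimnames = dimnames(exo))

  ira <- intron_rate_analysis(ct, m, rpkm)
  expect_equal(ira$records$gene_id, "A")
  expect_equal(ira$records$intron_rate, 0.30)
  flt <- ira$filters
  expect_false(flt$filter_pass[flt$gene_id == "B"])   # no introns
  expect_false(flt$filter_pass[flt$gene_id == "C"])   # overlaps D
  expect_false(flt$filter_pass[flt$gene_id == "D"])

  # expression filter: below 1 RPKM in any sample excludes the gene
  rpkm2 <- rpkm; rpkm2["A", 1] <- 0.5
  ira2 <- intron_rate_analysis(ct, m, rpkm2)
  expect_equal(nrow(ira2$records), 0)
})

test_that("metrics are invariant to gene and sample ordering", {
  m <- build_gene_models(random_raw_records(12, 20000, seed = 17))
  f1 <- random_fragments(500, 20000, seed = 18)
  f2 <- random_fragments(500, 20000, seed = 19)
  ct <- build_count_table(list(count_sample(f1, m, "s1"),
                               count_sample(f2, m, "s2")))
  expr <- expression_matrix(ct, m)
  perm <- sample(nrow(expr$rpkm))
  cls1 <- detection_classes(expr$rpkm[, 1], expr$rpkm[, 2])
  cls2 <- detection_classes(expr$rpkm[perm, 1], expr$rpkm[perm, 2])
  expect_equal(as.vector(table(cls1)), as.vector(table(cls2)))
  expect_equal(correlation_matrix(expr)[1, 2],
               correlation_matrix(list(rpkm = expr$rpkm[perm, ],
                                       cpm = expr$cpm[perm, ]))[1, 2])
})
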