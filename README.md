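# prepcompare

Tools for comparing **polyA+ selection** and **rRNA-depletion** bulk RNA-seq
library preparations at the level of gene quantification, together with a
labelled synthetic-fragment generator that makes the whole comparison
testable without sequencing data.

The two protocols sequence different transcriptome fractions: polyA+
selection captures polyadenylated transcripts and implicitly drops polyA−
RNAs, while rRNA depletion retains polyA− transcripts *and* nascent pre-mRNA,
placing a large share of its reads in introns. The package implements the
full quantitative comparison between them:

* **Union-exon gene models** from a Gencode-dialect GTF: per gene, the
  interval union of all transcript exons, the complementary introns, a
  five-way biotype collapse (protein-coding, lncRNA, pseudogene, small RNA,
  TCR/BCR), gene-overlap flags and multi-gene exonic regions.
* **Fragment counting** with two distinct rules: region classification
  (exonic/intronic/intergenic at ≥ 1 bp overlap, for library QC) and gene
  assignment (total exon overlap ≥ 25 bp, exclusion of multi-gene exonic
  regions, ambiguity handling), plus intronic tallies for the intron-rate
  statistic.
* **Expression metrics**: RPKM/CPM, expressed-gene detection classes
  (Both/PolyA/RiboZ/None at RPKM > 0.1), biotype breakdowns of genes and of
  counted reads, sample correlations of log2(CPM+1) after an RPKM ≥ 0.5
  filter, and per-biotype concordance with |log2FC| > 4 flags.
* **Depth arithmetic**: usable-read fractions (counted/total reads) and the
  extra sequencing an rRNA-depleted library needs to match polyA+ exonic
  coverage, `(f_polyA / f_riboZ − 1) × 100` %.
* **Per-gene intron rate** `intronic / (intronic + exonic)` with the
  structural filters (no overlapping gene, ≥ 1 intron, RPKM ≥ 1 in every
  sample) and trend summaries versus intron length and intron count.
* **Differential capture** between protocols: exact pooled binomial test
  (a deliberate, pluggable substitute for a dispersion-aware GLM), literal
  Benjamini–Hochberg step-up, and the strict criteria FC > 2,
  adjusted p < 0.05, mean RPKM > 0.5, summarized by biotype and direction.
* **Synthetic data**: a 19-gene toy chromosome realizing the structural
  scenarios that drive the comparison (intron-dominated protein-coding
  genes, a dominant unspliced lncRNA at 2.7 % of counted reads, polyA−
  histone-like and small RNA genes, 60 bp genes nested in host introns), and
  a protocol-aware fragment simulator with per-fragment truth labels.

See `vignettes/protocol-comparison.Rmd` for the model, parameter and design
discussion, and the numbered drivers under `analysis/` for the end-to-end
workflow (`01_simulate` → `02_count` → `03_metrics` → `04_diffexp`, each
writing its tables under `results/`).

## Worked example

Simulate one blood-like sample per protocol, count, and compare:

```r
library(prepcompare)

ann   <- generate_annotation()
polya <- simulate_fragments(ann, protocol_sim_config("polyA", "blood",
                                                     n_fragments = 1e5, seed = 1))
riboz <- simulate_fragments(ann, protocol_sim_config("riboZ", "blood",
                                                     n_fragments = 1e5, seed = 2))
ct <- build_count_table(list(
  count_sample(polya$fragments, ann$models, "blood_polyA"),
  count_sample(riboz$fragments, ann$models, "blood_riboZ")))
ct$categories[, c("sample_id", "exonic", "intronic", "intergenic", "exonic_pct")]
#>     sample_id exonic intronic intergenic exonic_pct
#> 1 blood_polyA  93220     4739       2041      93.22
#> 2 blood_riboZ  57581    40437       1982      57.58
```

Under rRNA depletion 40 % of reads are intronic (nascent pre-mRNA); under
polyA+ selection 5 %. That shrinks the usable fraction and sets the extra
depth the depleted library would need for equal exonic coverage:

```r
uf <- usable_fraction(ct$counted_library_size, ct$total_sequenced_reads)
round(uf, 3)
#> blood_polyA blood_riboZ
#>       0.931       0.567
extra_depth_required(uf[["blood_polyA"]], uf[["blood_riboZ"]])
#> $raw 64.3  $rounded 60
```

(The published blood libraries, with their real rRNA/duplication losses,
show 71 % vs 22 % usable reads, i.e. 220 % extra depth; the same routine
reproduces that from the printed fractions.) The per-gene intron rate
separates the protocols sharply, and the 60 bp small RNA nested in a host
intron shows the classic overestimation artifact — its rRNA-depletion RPKM
(20001) is two orders of magnitude above its polyA+ RPKM (179) although its
configured mature abundance is 0.1 % of reads:

```r
expr <- expression_matrix(ct, ann$models)
intron_rate_analysis(ct, ann$models, expr$rpkm)$medians
#>     sample_id       category intron_rate
#> 1 blood_polyA         lncRNA  0.0557
#> 2 blood_riboZ         lncRNA  0.4077
#> 3 blood_polyA protein-coding  0.0560
#> 4 blood_riboZ protein-coding  0.4703
round(expr$rpkm["SMR1", ], 1)
#> blood_polyA blood_riboZ
#>       179.1     20001.3
```

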