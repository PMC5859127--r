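---
title: "Comparing polyA+ selection and rRNA-depletion RNA-seq at the gene level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing polyA+ selection and rRNA-depletion RNA-seq at the gene level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk RNA-seq libraries are prepared either by polyA+ selection (oligo(dT)
capture of polyadenylated transcripts) or by rRNA depletion (hybridization
removal of ribosomal RNA from total RNA). The two protocols sequence
different fractions of the transcriptome: polyA+ selection implicitly drops
polyA− RNAs (most histone mRNAs, many small RNAs, some lncRNAs), while rRNA
depletion retains them but also captures nascent, incompletely spliced
pre-mRNA, so a large share of its reads fall in introns. For gene
quantification this has three consequences that this package measures:

1. **Usable depth.** Only reads assigned to exonic regions quantify genes.
   The usable fraction (counted reads / total sequenced reads) is much lower
   under rRNA depletion, and the extra sequencing needed to match polyA+
   exonic coverage is `(usable_polyA / usable_riboZ - 1) x 100` percent.
2. **Pre-mRNA contamination.** The per-gene intron rate,
   `intronic / (intronic + exonic)` reads, quantifies nascent-transcript
   content per library.
3. **Assignment artifacts.** Genes nested inside other genes' introns
   (miRNAs, snoRNAs, TCR J segments in the TCR constant-gene intron) collect
   intronic reads of their host and are systematically overestimated under
   rRNA depletion.

All quantification is union-exon based: a gene is the interval union of all
its transcripts' exons; its introns are the complement within the gene span.

# Counting rules

Two deliberately different overlap rules coexist, because they answer
different questions:

* **Region classification** (library QC): a fragment is *exonic* if any
  alignment block overlaps any gene's union exon by >= 1 bp; otherwise
  *intronic* if it touches an intron; otherwise *intergenic*.
* **Gene assignment** (quantification): a fragment is counted for a gene
  only if its blocks overlap that gene's union exons by >= 25 bp in total
  (the featureCounts `--minOverlap 25` convention), no overlapped base lies
  in an exonic region shared by two or more genes, and no second gene also
  reaches 25 bp (otherwise the fragment is ambiguous and counted for no
  gene). Fragments that reach 25 bp nowhere but touch introns are tallied as
  intronic for the gene with the longest intronic overlap — these feed the
  intron rate, not the expression values.

Both rules are strand-blind by default. The library preparation in the
motivating study was stranded, but the counting strand mode was not fixed by
it, and strand-blind is the conservative choice for a comparison whose
synthetic data carry no antisense transcription. Only uniquely mapped,
deduplicated fragments are counted; read pairs count once.

The sum of assigned exonic counts per sample is always smaller than the
1-bp-rule exonic total (minOverlap, ambiguity and the multi-gene exclusion
all shave reads). This is why published usable-read fractions (71%/22%
blood, 70%/46% colon) sit below the same libraries' QC-table exonic
percentages (74–80% polyA+): the two tables use the two different rules.
The package computes and reports both and does not attempt to force them to
agree.

# Expression, detection and differential capture

* RPKM = count / (union-exon length in kb) / (library size in millions);
  CPM analogous. The library size is by default the per-sample **counted**
  reads (sum of assigned exonic counts); a "mapped" (unique fragments)
  alternative is available and the choice is recorded in the result. The
  counted definition was chosen because every downstream threshold in the
  protocol comparison is applied to quantities derived from assigned reads.
* A gene is *expressed* at RPKM > 0.1 (strict) in the merged counts of a
  condition; the four detection classes Both / PolyA / RiboZ / None
  partition the annotated genes.
* Sample correlations use Pearson on log2(CPM + 1) after removing genes with
  RPKM < 0.5 in every sample ("across all samples" is read as *all*, not
  *any*); Spearman is available by flag. Per-biotype concordance uses the
  same transform, flagging genes with |log2((cpm_riboZ+1)/(cpm_polyA+1))| > 4.
* Differential capture between protocols: fold change > 2, BH-adjusted
  p < 0.05, mean RPKM > 0.5 — all strict, as printed. The test behind the
  p-values is deliberately **not** a negative-binomial GLM: replicate counts
  are pooled per group and the split of each gene's pooled total is tested
  against Binomial(n, L_A/(L_A+L_B)) with two-sided tail doubling. This is
  labelled a substitute; externally computed per-gene p-values (e.g. from a
  dispersion-aware model) can be injected through `de_analysis(pvalues=)`.
  The log2 fold change uses group-mean CPM with a pseudo-count of 0.5 (the
  criteria source is silent on the pseudo-count; 0.5 keeps zero-count genes
  finite and symmetric), and "up" means higher under rRNA depletion.
  The direction summary (up/(up+down)) is normalized within each biotype;
  normalizing across all DE genes instead is exposed by recomputing from the
  returned counts.

# The intron-rate statistic

For each gene and sample, intron rate = intronic / (intronic + exonic)
assigned reads. A gene enters the statistic only if it overlaps no other
gene (span-vs-span, strand-blind), has at least one intron, and reaches
RPKM >= 1 in every sample; genes with a zero denominator are dropped. The
span/strand-blind overlap reading is the conservative interpretation of an
under-specified filter and both choices are arguments
(`compute_overlap_flags(stranded=)`). Trend summaries bin total intron
length in half-decade log10 bins and intron count as 1, 2–5, 6–10, 11–20,
>20; the source displays these trends without stating bins, so the bins are
package choices.

# What the synthetic generator emulates

`generate_annotation()` lays out a 350 kb toy chromosome with 19 genes that
realize every structural scenario the analysis depends on:

* six generic protein-coding genes, 6 x 250 bp exons separated by 5.7 kb
  introns (a 30 kb span that is 95% intron — human protein-coding genes are
  >90% intron by length, and an intron-dominated span is what makes the
  intron rate of a half-nascent library approach 0.5);
* a compact globin-like gene (3 x 200 bp exons, 150 bp introns) whose
  abundance is high in the blood preset and negligible in colon;
* an 8 kb unspliced, highly abundant lncRNA pinned at 2.7% of counted reads
  with polyA capture 0.05 (most of its mature transcripts are not
  polyadenylated);
* a polyA− intron-less histone-like gene (capture 0) and a spliced lncRNA
  (capture 0.7);
* a 60 bp small RNA nested mid-intron of a protein-coding host, and a
  receptor constant gene whose 20 kb intron hosts four 60 bp J-segment
  genes — all shorter than the 75 bp fragments, so they can never be fully
  covered by a mature read of their own;
* a processed pseudogene and a dominant free-standing small RNA (2% of
  counted reads, capture 0).

`simulate_fragments()` draws, per fragment: an intergenic position (default
2%), or a gene. A gene fragment is *nascent* with probability
`nascent_fraction` — a single 75 bp block uniform over the unspliced gene
span, the standard geometric picture of co-transcriptional sequencing of
pre-mRNA — or *mature*: uniform over the spliced union-exon transcript,
split into two blocks when it crosses a junction, truncated to the gene for
genes shorter than 75 bp. Default nascent fractions are 0.06 for polyA+
(the residual pre-mRNA seen in polyA-selected blood libraries) and 0.50
(blood) / 0.34 (colon) for rRNA depletion, matching the intronic read
shares the protocols show in those tissues. Under the polyA+ protocol gene
draws are additionally weighted by per-gene capture probabilities.

Abundances are specified as expected shares of **counted** reads. Because a
nascent fragment frequently misses every exon, genes with long introns
convert draws to counted reads inefficiently; the generator divides each
abundance by the gene's counting efficiency (computed exactly from per-base
exon coverage under the 25 bp rule) so that configured shares are recovered
in the counted output. This correction is per-gene and ignores cross-gene
assignment (a host's nascent reads counted for its nested small RNA), which
is precisely the artifact left visible: under rRNA depletion the nested
small RNA's RPKM exceeds both its polyA+ RPKM and the RPKM implied by its
true mature fragment count.

Every fragment carries a truth label (source gene, mature/nascent x
exonic/intronic, intergenic), and `truth_summaries()` recomputes the
expected intronic fraction from the annotation geometry through an
independent base-R interval check, so parameter recovery is tested against
the generator's own arithmetic rather than against the counting code.

What the generator does **not** emulate: sequence content and errors,
GC/positional bias, fragment-length variation, degradation, antisense
transcription, multi-mapping, or biological replicate dispersion beyond
multinomial sampling (replicates differ only by seed). Passing tests
therefore validate the bookkeeping — counting rules, normalization,
thresholds, filters, arithmetic — under a known generative model; they say
nothing about aligner behavior or dispersion modeling on real data.

# Numerical and design choices

* Coordinates are 0-based half-open internally; GTF I/O converts at the
  boundary (1-based closed). Interval algebra is delegated to
  IRanges/GenomicRanges.
* Intronic tie-breaks: longest intronic overlap, then lexicographic gene id
  — an arbitrary but deterministic rule, required for order-independence.
* `extra_depth_required()` rounds to the nearest 10% by default (matching
  "about 50%/220%" reporting) and always returns the raw value alongside.
* BH adjustment is the literal step-up implementation (tested against
  `p.adjust` on random vectors); degenerate inputs (empty fragment sets,
  empty categories, zero-total genes) return explicit zeros, missing values
  or p = 1 rather than errors, and all metrics are invariant to gene,
  sample and fragment input order.
* Problem sizes in the shipped analyses: 10^5 fragments per sample in the
  analysis scripts, 2 x 10^5 for the parameter-recovery checks, 10^4 per
  sample x 50 replications for the null false-positive study — sizes at
  which binomial sampling error on the recovered fractions is well below
  the tolerances being checked.

# Known limitations

* The exact binomial substitute ignores biological overdispersion; with
  truly replicated biological groups it is anticonservative, which is why
  the DE stage accepts external p-values.
* The five-way biotype collapse ships as an editable table keyed on Gencode
  `gene_type` strings; other annotation dialects need a custom table.
* Union-exon quantification understates expression of genes whose dominant
  isoform uses few exons; transcript-level models are out of scope.
* The toy annotation has 19 genes: detection-class and biotype fractions on
  synthetic data are illustrative, not calibrated to genome-wide counts.
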