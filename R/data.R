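#' Per-replicate QC metrics of the blood/colon protocol comparison
#'
#' The published per-replicate sequencing metrics of the two-protocol study
#' the pipeline is modeled on: 16 replicates (blood and colon, four
#' replicates each under polyA+ selection and rRNA depletion), with total
#' sequenced reads (after 50 M downsampling), uniquely mapped reads, exonic
#' reads (1 bp overlap rule) and the printed exonic percentage. Used as the
#' input for the depth arithmetic and as a cross-check of the percentage
#' routine.
#'
#' @return data.frame with columns `sample_id`, `tissue`, `protocol`,
#'   `replicate`, `total_reads`, `unique_mapped`, `exonic_reads`,
#'   `exonic_pct`.
#' @export
replicate_qc_table <- function() {
  read.delim(system.file("extdata", "table1_replicates.tsv",
                         package = "prepcompare"),
             stringsAsFactors = FALSE)
}

#' Published usable-read fractions of the protocol-comparison study
#'
#' Fractions of sequenced reads usable for gene quantification (counted
#' reads over total sequenced reads) as reported for the four merged
#' conditions; inputs to [extra_depth_required()].
#'
#' @return Named numeric vector for blood/colon x polyA/riboZ.
#' @export
published_usable_fractions <- function() {
  c(blood_polyA = 0.71, blood_riboZ = 0.22,
    colon_polyA = 0.70, colon_riboZ = 0.46)
}
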