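#' @importFrom stats median cor pbinom runif setNames aggregate
#' @importFrom utils read.delim write.table packageVersion
NULL

# enable data.table query semantics inside this package
.datatable.aware <- TRUE

# Internal coordinates are 0-based half-open throughout; IRanges is 1-based
# closed, so conversion happens exactly here and nowhere else.
to_iranges <- function(start0, end0) IRanges::IRanges(start = start0 + 1L, end = end0)

to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = to_iranges(df$start, df$end)
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
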