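#' Read and write interval sets as BED
#'
#' Interval sets (genes, segmental duplications, published CNVR sets, truth
#' events) are exchanged as BED. Internally all coordinates are 1-based
#' inclusive; BED files are 0-based half-open, and the conversion is handled
#' by `rtracklayer`. Chromosomes are named `chr1` ... `chr29` on disk and
#' stored as integers 1-29 in memory.
#'
#' @param path BED file path.
#' @return `read_bed()` returns a `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based inclusive) and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.integer(sub("^chr", "", as.character(GenomicRanges::seqnames(gr)))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) df$name <- gr$name
  df
}

#' @rdname read_bed
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional `name` column.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = paste0("chr", intervals$chrom),
      ranges = IRanges::IRanges(intervals$start, intervals$end)
    )
    if ("name" %in% names(intervals)) gr$name <- intervals$name
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# GRanges view of a (chrom, start, end) data.frame; 1-based inclusive.
intervals_to_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(df$start, df$end)
  )
}

# Put two GRanges on the union of their seqlevels so set operations between
# interval sets from different chromosomes stay silent.
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}
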