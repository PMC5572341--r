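#' Construct and validate a probe map
#'
#' A probe map is the coordinate backbone for all signal-level operations:
#' an ordered table of autosomal SNP probes with their genomic positions and,
#' optionally, the GC fraction of the 1 Mb window centred on each probe
#' (used by [gc_adjust_lrr()]).
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chrom Integer chromosome (autosomes 1-29).
#' @param pos Integer base-pair position, 1-based.
#' @param gc Optional numeric GC fraction in \[0, 1\] for the 1 Mb window
#'   centred on `pos`.
#'
#' @return A `data.frame` with columns `probe_id`, `chrom`, `pos` and
#'   optionally `gc`, strictly sorted by `(chrom, pos)`.
#' @export
probe_map <- function(probe_id, chrom, pos, gc = NULL) {
  df <- data.frame(
    probe_id = as.character(probe_id),
    chrom = as.integer(chrom),
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )
  if (!is.null(gc)) df$gc <- as.numeric(gc)
  validate_probe_map(df)
}

#' @rdname probe_map
#' @param probes A candidate probe-map `data.frame`.
#' @export
validate_probe_map <- function(probes) {
  stopifnot(is.data.frame(probes))
  req <- c("probe_id", "chrom", "pos")
  if (!all(req %in% names(probes))) {
    stop("probe map must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) stop("probe_ids must be unique")
  if (any(is.na(probes$chrom)) || any(probes$chrom < 1L) || any(probes$chrom > 29L)) {
    stop("all probes must be autosomal (chrom 1-29)")
  }
  o <- order(probes$chrom, probes$pos)
  key <- probes$chrom * 2^40 + probes$pos
  if (is.unsorted(key[o], strictly = TRUE)) {
    stop("probes must be strictly sorted by (chrom, pos): duplicate positions found")
  }
  if (is.unsorted(key, strictly = TRUE)) probes <- probes[o, , drop = FALSE]
  if ("gc" %in% names(probes)) {
    if (any(is.na(probes$gc)) || any(probes$gc < 0) || any(probes$gc > 1)) {
      stop("gc fractions must lie in [0, 1]")
    }
  }
  rownames(probes) <- NULL
  probes
}

#' Bundle probe map, LRR and BAF matrices into a signal object
#'
#' The container used throughout the package for probe-level array intensity
#' data: log R ratio (LRR, total intensity) and B-allele frequency (BAF,
#' allelic ratio), both probes x samples.
#'
#' @param probes A probe map (see [probe_map()]).
#' @param lrr Numeric matrix, probes x samples, finite log R ratios.
#' @param baf Numeric matrix, probes x samples, B-allele frequencies in \[0, 1\].
#'
#' @return An object of class `cnv_signal`: a list with elements `probes`,
#'   `samples`, `lrr`, `baf`.
#' @export
cnv_signal <- function(probes, lrr, baf) {
  lrr <- as.matrix(lrr)
  baf <- as.matrix(baf)
  if (nrow(lrr) != nrow(probes) || nrow(baf) != nrow(probes)) {
    stop("lrr/baf must have one row per probe")
  }
  o <- order(probes$chrom, probes$pos)
  probes <- validate_probe_map(probes[o, , drop = FALSE])
  lrr <- lrr[o, , drop = FALSE]
  baf <- baf[o, , drop = FALSE]
  if (!identical(dim(lrr), dim(baf))) stop("lrr and baf dimensions differ")
  if (ncol(lrr) > 0L && is.null(colnames(lrr))) {
    stop("lrr must carry sample ids as column names")
  }
  samples <- if (is.null(colnames(lrr))) character(0) else colnames(lrr)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (!identical(colnames(lrr), colnames(baf))) stop("lrr/baf sample order differs")
  if (any(!is.finite(lrr))) stop("lrr must be finite")
  if (any(is.na(baf)) || any(baf < 0) || any(baf > 1)) stop("baf must lie in [0, 1]")
  rownames(lrr) <- probes$probe_id
  rownames(baf) <- probes$probe_id
  structure(
    list(probes = probes, samples = samples, lrr = lrr, baf = baf),
    class = "cnv_signal"
  )
}

#' @export
print.cnv_signal <- function(x, ...) {
  cat(
    "cnv_signal:", nrow(x$probes), "probes x", length(x$samples), "samples,",
    length(unique(x$probes$chrom)), "chromosome(s),",
    if ("gc" %in% names(x$probes)) "with" else "without", "GC annotation\n"
  )
  invisible(x)
}

#' Read and write wide signal matrices
#'
#' The on-disk dialect is a Final-Report-like wide TSV: one row per probe with
#' columns `probe_id chrom pos [gc]` followed by `<sample>.LRR <sample>.BAF`
#' pairs.
#'
#' @param path File path.
#' @return `read_signal_tsv()` returns a `cnv_signal`; `write_signal_tsv()`
#'   invisibly returns `path`.
#' @export
read_signal_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  has_gc <- "gc" %in% names(df)
  meta_cols <- c("probe_id", "chrom", "pos", if (has_gc) "gc")
  sig_cols <- setdiff(names(df), meta_cols)
  lrr_cols <- grep("\\.LRR$", sig_cols, value = TRUE)
  baf_cols <- grep("\\.BAF$", sig_cols, value = TRUE)
  samples <- sub("\\.LRR$", "", lrr_cols)
  if (!identical(samples, sub("\\.BAF$", "", baf_cols))) {
    stop("signal TSV must carry paired <sample>.LRR / <sample>.BAF columns")
  }
  probes <- df[meta_cols]
  lrr <- as.matrix(df[lrr_cols]); colnames(lrr) <- samples
  baf <- as.matrix(df[baf_cols]); colnames(baf) <- samples
  cnv_signal(probes, lrr, baf)
}

#' @rdname read_signal_tsv
#' @param signal A `cnv_signal`.
#' @export
write_signal_tsv <- function(signal, path) {
  stopifnot(inherits(signal, "cnv_signal"))
  out <- signal$probes
  for (s in signal$samples) {
    out[[paste0(s, ".LRR")]] <- signal$lrr[, s]
    out[[paste0(s, ".BAF")]] <- signal$baf[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
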