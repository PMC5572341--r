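#' Population frequency of the B allele (PFB)
#'
#' Computes, for every probe, the arithmetic mean BAF across all samples in
#' the cohort. This per-probe population B-allele frequency is the standard
#' companion file for HMM-based CNV callers on SNP-array data.
#'
#' @param signal A [cnv_signal()].
#' @return Numeric vector, one value in \[0, 1\] per probe, named by probe id.
#' @export
compute_pfb <- function(signal) {
  stopifnot(inherits(signal, "cnv_signal"))
  if (length(signal$samples) == 0L) stop("no samples")
  rowMeans(signal$baf)
}

#' Write a PFB track to TSV
#'
#' @param signal A [cnv_signal()].
#' @param path Output path; columns `probe_id chrom pos pfb`.
#' @export
write_pfb_tsv <- function(signal, path) {
  pfb <- compute_pfb(signal)
  out <- data.frame(
    probe_id = signal$probes$probe_id,
    chrom = signal$probes$chrom,
    pos = signal$probes$pos,
    pfb = as.numeric(pfb),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GC-wave adjustment of log R ratios
#'
#' Genomic waves in array intensity data track local GC content. For each
#' sample this fits an ordinary least-squares regression of LRR on the probe
#' GC fraction (1 Mb window centred on the probe) and subtracts the
#' mean-centred fitted component, so each sample's mean LRR is preserved
#' exactly. BAF is untouched.
#'
#' With centred GC the correction for sample j is
#' `lrr_ij - beta_j * (gc_i - mean(gc))`, where `beta_j` is the OLS slope.
#' Residuals are uncorrelated with GC, so the operation is idempotent.
#'
#' @param signal A [cnv_signal()] whose probe map carries a `gc` column.
#' @return A `cnv_signal` with adjusted LRR.
#' @export
gc_adjust_lrr <- function(signal) {
  stopifnot(inherits(signal, "cnv_signal"))
  if (!"gc" %in% names(signal$probes)) {
    stop("probe map carries no gc column; GC adjustment needs per-probe GC fractions")
  }
  gc <- signal$probes$gc
  gc_c <- gc - mean(gc)
  ss <- sum(gc_c^2)
  if (ss == 0) return(signal) # constant GC: degenerate regression, no-op
  # OLS slope per sample in one pass: beta_j = <gc_c, lrr_j> / <gc_c, gc_c>
  beta <- as.numeric(crossprod(gc_c, signal$lrr)) / ss
  adj <- signal$lrr - outer(gc_c, beta)
  colnames(adj) <- signal$samples
  cnv_signal(signal$probes, adj, signal$baf)
}

#' Per-sample quality control of array intensity signal
#'
#' Computes three per-sample statistics and a pass flag:
#' \describe{
#'   \item{lrr_sd}{standard deviation of the sample's LRR over all probes.}
#'   \item{baf_drift}{fraction of probes with BAF in the open intervals
#'     (0.2, 0.25) or (0.75, 0.8) - probes drifting away from the canonical
#'     0 / 0.5 / 1 genotype bands, as used by PennCNV. The raw BAF standard
#'     deviation is also reported (`baf_sd`) but is not a usable QC metric:
#'     the tri-modal BAF distribution gives every sample `baf_sd` near 0.4.}
#'   \item{wave_factor}{SD of per-1-Mb-window median LRR over non-overlapping
#'     windows per chromosome; long-range "waviness" of the signal.}
#' }
#' A sample passes iff `lrr_sd <= lrr_sd_max`, `baf_drift <= baf_drift_max`
#' and `wave_factor <= wave_factor_max`.
#'
#' @param signal A [cnv_signal()].
#' @param lrr_sd_max Maximum LRR standard deviation (default 0.30).
#' @param baf_drift_max Maximum BAF drift fraction (default 0.002).
#' @param wave_factor_max Maximum wave factor (default 0.05).
#' @param window_bp Window size for the wave factor, default 1 Mb.
#' @return `data.frame` with one row per sample: `sample_id`, `lrr_sd`,
#'   `baf_sd`, `baf_drift`, `wave_factor`, `pass`.
#' @export
sample_qc <- function(signal, lrr_sd_max = 0.30, baf_drift_max = 0.002,
                      wave_factor_max = 0.05, window_bp = 1e6) {
  stopifnot(inherits(signal, "cnv_signal"))
  if (length(signal$samples) == 0L) stop("no samples")
  if (nrow(signal$probes) < 2L) stop("need at least 2 probes to compute SDs")
  lrr_sd <- apply(signal$lrr, 2L, stats::sd)
  baf_sd <- apply(signal$baf, 2L, stats::sd)
  drift <- (signal$baf > 0.2 & signal$baf < 0.25) |
    (signal$baf > 0.75 & signal$baf < 0.8)
  baf_drift <- colMeans(drift)
  win <- paste(signal$probes$chrom, (signal$probes$pos - 1L) %/% as.integer(window_bp))
  wave_factor <- apply(signal$lrr, 2L, function(x) {
    med <- tapply(x, win, stats::median)
    if (length(med) < 2L) 0 else stats::sd(med)
  })
  data.frame(
    sample_id = signal$samples,
    lrr_sd = as.numeric(lrr_sd),
    baf_sd = as.numeric(baf_sd),
    baf_drift = as.numeric(baf_drift),
    wave_factor = as.numeric(wave_factor),
    pass = lrr_sd <= lrr_sd_max & baf_drift <= baf_drift_max &
      wave_factor <= wave_factor_max,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Validate sample metadata
#'
#' @param meta `data.frame` with columns `sample_id`, `breed`, `group`
#'   (one of BAI, BRI, IBR, NLD, ALP, OTHER) and `sex`
#'   (male / female / unknown).
#' @return The validated `data.frame`.
#' @export
validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  req <- c("sample_id", "breed", "group", "sex")
  if (!all(req %in% names(meta))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("sample_ids must be unique")
  ok_groups <- c("BAI", "BRI", "IBR", "NLD", "ALP", "OTHER")
  if (!all(meta$group %in% ok_groups)) {
    stop("group labels must be one of: ", paste(ok_groups, collapse = ", "))
  }
  if (!all(meta$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male, female or unknown")
  }
  meta
}

#' Read and write sample metadata TSV
#' @param path File path.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(utils::read.table(path, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE))
}

#' @rdname read_sample_meta
#' @param meta Sample metadata `data.frame`.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(validate_sample_meta(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
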