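#' Read per-sample CNV calls in the PennCNV text dialect
#'
#' Parses whitespace-delimited records of the form
#' `chr1:100000-200000 numsnp=25 length=100,001 state2,cn=1 SAMPLE
#' startsnp=... endsnp=...`. Coordinates are 1-based inclusive. Records with
#' `cn=2` (normal copy) are rejected with a warning; records on non-autosomal
#' chromosomes (anything other than chr1-chr29) are skipped and counted in the
#' `n_skipped_nonautosomal` attribute; malformed lines are reported with their
#' line numbers.
#'
#' @param path Path to a `.rawcnv` file (header-less).
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `n_probes`, plus attribute `n_skipped_nonautosomal`.
#' @export
read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines_trim <- trimws(lines)
  keep <- nzchar(lines_trim)
  idx <- which(keep)
  empty <- data.frame(
    sample_id = character(), chrom = integer(), start = integer(),
    end = integer(), copy_state = integer(), n_probes = integer(),
    stringsAsFactors = FALSE
  )
  attr(empty, "n_skipped_nonautosomal") <- 0L
  if (length(idx) == 0L) return(empty)

  pat <- paste0(
    "^chr(\\S+):(\\d+)-(\\d+)\\s+numsnp=(\\d+)\\s+length=([0-9,]+)\\s+",
    "state\\d+,cn=(\\d+)\\s+(\\S+)"
  )
  txt <- lines_trim[idx]
  m <- regmatches(txt, regexec(pat, txt))
  bad <- idx[vapply(m, length, 1L) == 0L]
  if (length(bad) > 0L) {
    warning("skipping malformed .rawcnv line(s): ", paste(bad, collapse = ", "))
  }
  ok <- vapply(m, length, 1L) > 0L
  if (!any(ok)) return(empty)
  fields <- do.call(rbind, m[ok])
  chrom_chr <- fields[, 2L]
  autosomal <- grepl("^[0-9]+$", chrom_chr) &
    suppressWarnings(as.integer(chrom_chr)) >= 1L &
    suppressWarnings(as.integer(chrom_chr)) <= 29L
  n_skipped <- sum(!autosomal)
  cn <- as.integer(fields[, 7L])
  normal <- autosomal & cn == 2L
  if (any(normal)) {
    warning("rejecting ", sum(normal), " record(s) with cn=2 (normal copy number)")
  }
  use <- autosomal & cn != 2L
  calls <- data.frame(
    sample_id = fields[use, 8L],
    chrom = as.integer(chrom_chr[use]),
    start = as.integer(fields[use, 3L]),
    end = as.integer(fields[use, 4L]),
    copy_state = cn[use],
    n_probes = as.integer(fields[use, 5L]),
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  attr(calls, "n_skipped_nonautosomal") <- n_skipped
  validate_calls(calls)
}

#' @rdname read_rawcnv
#' @param calls A CNV call `data.frame` (see Value).
#' @export
write_rawcnv <- function(calls, path) {
  calls <- validate_calls(calls)
  # PennCNV HMM state labels for the emitted copy numbers
  state_of <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  if (nrow(calls) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  len <- formatC(calls$end - calls$start + 1L, big.mark = ",", format = "d")
  rec <- sprintf(
    "chr%d:%d-%d numsnp=%d length=%s state%d,cn=%d %s startsnp=NA endsnp=NA",
    calls$chrom, calls$start, calls$end, calls$n_probes, len,
    state_of[as.character(calls$copy_state)], calls$copy_state, calls$sample_id
  )
  writeLines(rec, path)
  invisible(path)
}

#' Validate a CNV call table
#'
#' Calls are 1-based inclusive autosomal events with copy state in
#' \{0, 1, 3, 4\} (2 = normal copy is never a call).
#'
#' @param calls `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `copy_state`, `n_probes`.
#' @return The validated `data.frame`.
#' @export
validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  req <- c("sample_id", "chrom", "start", "end", "copy_state", "n_probes")
  if (!all(req %in% names(calls))) {
    stop("call table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$copy_state == 2L)) stop("copy_state 2 (normal) is not a CNV call")
  if (!all(calls$copy_state %in% c(0L, 1L, 3L, 4L))) {
    stop("copy_state must be one of 0, 1, 3, 4")
  }
  if (any(calls$end < calls$start)) stop("end must be >= start")
  if (any(calls$chrom < 1L | calls$chrom > 29L)) stop("chrom must be autosomal (1-29)")
  if (any(calls$n_probes < 1L)) stop("n_probes must be >= 1")
  calls
}

#' Keep calls spanning at least `min_probes` SNPs
#'
#' Small calls supported by fewer than three array probes are unreliable and
#' are dropped before any downstream analysis.
#'
#' @param calls CNV call `data.frame`.
#' @param min_probes Minimum probe support, default 3.
#' @return The filtered calls, input order preserved.
#' @export
filter_calls <- function(calls, min_probes = 3L) {
  calls <- validate_calls(calls)
  if (min_probes < 1L) stop("min_probes must be >= 1")
  calls[calls$n_probes >= min_probes, , drop = FALSE]
}
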