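#' Truncate a percentage to two decimals for display
#'
#' CNVR frequencies and overlap percentages are displayed truncated (not
#' rounded) to two decimals - e.g. 145 of 149 supporters is 97.3154...%,
#' displayed as 97.31. The raw value is always retained for thresholding.
#'
#' @param x Numeric percentages.
#' @return `x` truncated to two decimals.
#' @export
pct_display <- function(x) floor(x * 100 + 1e-9) / 100

#' CNVR frequency in the cohort
#'
#' @param n_support Number of distinct supporting samples.
#' @param n_samples_cohort Cohort size.
#' @return Raw percentage `100 * n_support / n_samples_cohort`; use
#'   [pct_display()] for the 2-decimal display form.
#' @export
cnvr_frequency <- function(n_support, n_samples_cohort) {
  if (any(n_samples_cohort == 0)) stop("cohort size must be positive")
  if (any(n_support > n_samples_cohort)) stop("support exceeds cohort size")
  100 * n_support / n_samples_cohort
}

#' Build CNV regions by multi-sample interval union
#'
#' Per chromosome, calls are merged into connected components of the
#' at-least-1-bp overlap graph (transitive merging: A-B and B-C overlap puts
#' A, B, C in one component even if A and C do not touch). Components whose
#' calls come from at least two distinct samples become CNV regions (CNVRs);
#' components supported by a single sample are returned separately as
#' singleton clusters. A CNVR spans the minimum start to the maximum end of
#' its member calls; spans on one chromosome are pairwise disjoint by
#' construction. The class is `loss` when all member copy states are below 2,
#' `gain` when all are above 2, and `complex` otherwise.
#'
#' @param calls Filtered CNV call `data.frame`.
#' @param n_samples_cohort Cohort size used for the frequency denominator.
#' @return List with:
#'   \describe{
#'     \item{cnvrs}{`data.frame`: `cnvr_id`, `chrom`, `start`, `end`, `klass`,
#'       `n_samples` (distinct supporters), `freq_pct` (raw), `samples`
#'       (list column of supporter ids), `member_rows` (list column of row
#'       indices into `calls`).}
#'     \item{singletons}{`data.frame` of single-sample components:
#'       `component_id`, `chrom`, `start`, `end`, `klass`, `sample_id`,
#'       `member_rows` (list column).}
#'   }
#' @export
build_cnvrs <- function(calls, n_samples_cohort) {
  calls <- validate_calls(calls)
  if (n_samples_cohort < 1L) stop("cohort size must be positive")

  comps <- list()
  if (nrow(calls) > 0L) {
    o <- order(calls$chrom, calls$start, calls$end)
    cur_rows <- integer()
    cur_chrom <- NA_integer_
    cur_end <- -Inf
    flush <- function() {
      if (length(cur_rows) > 0L) comps[[length(comps) + 1L]] <<- cur_rows
    }
    for (i in o) {
      if (!isTRUE(calls$chrom[i] == cur_chrom) || calls$start[i] > cur_end) {
        flush()
        cur_rows <- i
        cur_chrom <- calls$chrom[i]
        cur_end <- calls$end[i]
      } else {
        cur_rows <- c(cur_rows, i)
        cur_end <- max(cur_end, calls$end[i])
      }
    }
    flush()
  }

  klass_of <- function(states) {
    if (all(states < 2L)) "loss" else if (all(states > 2L)) "gain" else "complex"
  }
  rows <- lapply(comps, function(r) {
    s <- unique(calls$sample_id[r])
    data.frame(
      chrom = calls$chrom[r[1L]],
      start = min(calls$start[r]),
      end = max(calls$end[r]),
      klass = klass_of(calls$copy_state[r]),
      n_samples = length(s),
      stringsAsFactors = FALSE
    )
  })
  multi <- vapply(comps, function(r) length(unique(calls$sample_id[r])) >= 2L, logical(1L))

  cnvrs <- do.call(rbind, rows[multi])
  if (is.null(cnvrs)) {
    cnvrs <- data.frame(
      chrom = integer(), start = integer(), end = integer(),
      klass = character(), n_samples = integer(), stringsAsFactors = FALSE
    )
  }
  cnvrs <- cbind(
    data.frame(cnvr_id = sprintf("CNVR_%04d", seq_len(nrow(cnvrs))),
               stringsAsFactors = FALSE),
    cnvrs
  )
  cnvrs$freq_pct <- cnvr_frequency(cnvrs$n_samples, n_samples_cohort)
  cnvrs$samples <- I(lapply(comps[multi], function(r) unique(calls$sample_id[r])))
  cnvrs$member_rows <- I(comps[multi])

  single <- do.call(rbind, rows[!multi])
  if (is.null(single)) {
    single <- data.frame(
      chrom = integer(), start = integer(), end = integer(),
      klass = character(), n_samples = integer(), stringsAsFactors = FALSE
    )
  }
  singles <- data.frame(
    component_id = sprintf("SGL_%04d", seq_len(nrow(single))),
    chrom = single$chrom, start = single$start, end = single$end,
    klass = single$klass,
    sample_id = vapply(comps[!multi], function(r) calls$sample_id[r[1L]],
                       character(1L)),
    stringsAsFactors = FALSE
  )
  singles$member_rows <- I(comps[!multi])
  rownames(cnvrs) <- NULL
  rownames(singles) <- NULL
  list(cnvrs = cnvrs, singletons = singles)
}

#' Per-chromosome CNVR summary statistics
#'
#' @param cnvrs CNVR `data.frame` from [build_cnvrs()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   names are chromosome numbers.
#' @return `data.frame` per chromosome carrying CNVRs: `chrom`, `n_cnvrs`,
#'   `cumulative_length` (sum of CNVR span lengths; spans are disjoint),
#'   `coverage_pct` (of the chromosome), `mean_gap_bp` (mean distance between
#'   consecutive CNVR spans, `NA` for a single CNVR).
#' @export
chromosome_stats <- function(cnvrs, chrom_lengths) {
  chroms <- sort(unique(cnvrs$chrom))
  miss <- setdiff(as.character(chroms), names(chrom_lengths))
  if (length(miss) > 0L) {
    stop("no chromosome length supplied for chrom(s): ", paste(miss, collapse = ", "))
  }
  do.call(rbind, lapply(chroms, function(cc) {
    x <- cnvrs[cnvrs$chrom == cc, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    len <- sum(x$end - x$start + 1)
    gaps <- if (nrow(x) >= 2L) {
      x$start[-1L] - x$end[-nrow(x)] - 1
    } else {
      NA_real_
    }
    data.frame(
      chrom = cc,
      n_cnvrs = nrow(x),
      cumulative_length = len,
      coverage_pct = 100 * len / chrom_lengths[[as.character(cc)]],
      mean_gap_bp = mean(gaps),
      stringsAsFactors = FALSE
    )
  }))
}

#' Annotate CNVRs with overlapping reference intervals
#'
#' @param cnvrs CNVR `data.frame` (needs `cnvr_id`, `chrom`, `start`, `end`).
#' @param reference Interval `data.frame` (`chrom`, `start`, `end`, optional
#'   `name`), same assembly and 1-based inclusive coordinates.
#' @param min_overlap Minimum overlap in bp to count a hit, default 1.
#' @return `data.frame` of hits: `cnvr_id`, `ref_row`, `ref_name` (row index
#'   when no names), `overlap_bp`.
#' @export
annotate_intervals <- function(cnvrs, reference, min_overlap = 1L) {
  empty <- data.frame(cnvr_id = character(), ref_row = integer(),
                      ref_name = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(cnvrs) == 0L || nrow(reference) == 0L) return(empty)
  h <- harmonize_seqlevels(intervals_to_granges(cnvrs),
                           intervals_to_granges(reference))
  q <- h[[1L]]
  s <- h[[2L]]
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = as.integer(min_overlap))
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qh],
                                           IRanges::ranges(s)[sh]))
  nm <- if ("name" %in% names(reference)) {
    reference$name[sh]
  } else {
    as.character(sh)
  }
  data.frame(
    cnvr_id = cnvrs$cnvr_id[qh],
    ref_row = sh,
    ref_name = nm,
    overlap_bp = ov,
    stringsAsFactors = FALSE
  )
}

#' Filter segmental duplications to those longer than a cutoff
#'
#' Only large segmental duplications (strictly longer than 5 kb by default)
#' are retained: these are the ones prone to non-allelic homologous
#' recombination. An SD of exactly 5,000 bp is excluded.
#'
#' @param segdups Interval `data.frame` (`chrom`, `start`, `end`).
#' @param min_length_bp Strict lower bound on length, default 5000.
#' @return The filtered `data.frame`.
#' @export
filter_segdups <- function(segdups, min_length_bp = 5000L) {
  segdups[(segdups$end - segdups$start + 1) > min_length_bp, , drop = FALSE]
}

#' Overlap accounting against published reference CNVR sets
#'
#' For each named reference set: the number and percentage of reference
#' regions overlapped (at least 1 bp) by any current CNVR, and the percentage
#' of the reference set's cumulative length intersected by the current CNVRs.
#' A current CNVR is *novel* iff it overlaps no interval in the union of all
#' reference sets.
#'
#' @param cnvrs CNVR `data.frame` from [build_cnvrs()].
#' @param references Named list of interval `data.frame`s.
#' @return List with `reports` (`data.frame`: `set`, `n_ref`,
#'   `ref_cumulative_length`, `n_overlapped`, `pct_overlapped`,
#'   `pct_length_overlapped`) and `novel` (character vector of novel CNVR
#'   ids).
#' @export
compare_with_reference_sets <- function(cnvrs, references) {
  stopifnot(is.list(references), length(references) >= 1L,
            !is.null(names(references)))
  cnvr_gr <- GenomicRanges::reduce(intervals_to_granges(cnvrs))
  reports <- do.call(rbind, lapply(names(references), function(nm) {
    ref <- references[[nm]]
    n_ref <- nrow(ref)
    if (n_ref == 0L) {
      return(data.frame(
        set = nm, n_ref = 0L, ref_cumulative_length = 0,
        n_overlapped = 0L, pct_overlapped = 0, pct_length_overlapped = 0,
        stringsAsFactors = FALSE
      ))
    }
    h <- harmonize_seqlevels(intervals_to_granges(ref), cnvr_gr)
    ref_gr <- h[[1L]]
    n_ov <- sum(IRanges::overlapsAny(ref_gr, h[[2L]], minoverlap = 1L))
    ref_len <- sum(ref$end - ref$start + 1)
    inter <- sum(IRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(ref_gr), h[[2L]]
    )))
    data.frame(
      set = nm, n_ref = n_ref, ref_cumulative_length = ref_len,
      n_overlapped = n_ov,
      pct_overlapped = 100 * n_ov / n_ref,
      pct_length_overlapped = 100 * inter / ref_len,
      stringsAsFactors = FALSE
    )
  }))
  novel <- cnvrs$cnvr_id
  if (nrow(cnvrs) > 0L) {
    all_ref <- do.call(rbind, lapply(references, function(r) {
      r[c("chrom", "start", "end")]
    }))
    if (nrow(all_ref) > 0L) {
      h <- harmonize_seqlevels(intervals_to_granges(cnvrs),
                               intervals_to_granges(all_ref))
      hit <- IRanges::overlapsAny(h[[1L]], h[[2L]], minoverlap = 1L)
      novel <- cnvrs$cnvr_id[!hit]
    }
  }
  list(reports = reports, novel = novel)
}

#' Write CNVRs as TSV and BED
#'
#' @param cnvrs CNVR `data.frame` from [build_cnvrs()].
#' @param path Output TSV path (`cnvr_id chrom start end class n_samples
#'   freq_pct`, frequency displayed truncated to 2 decimals).
#' @export
write_cnvr_tsv <- function(cnvrs, path) {
  out <- data.frame(
    cnvr_id = cnvrs$cnvr_id, chrom = cnvrs$chrom, start = cnvrs$start,
    end = cnvrs$end, class = cnvrs$klass, n_samples = cnvrs$n_samples,
    freq_pct = sprintf("%.2f", pct_display(cnvrs$freq_pct)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvr_tsv
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  bed <- data.frame(
    chrom = cnvrs$chrom, start = cnvrs$start, end = cnvrs$end,
    name = paste0(cnvrs$cnvr_id, "_", cnvrs$klass),
    stringsAsFactors = FALSE
  )
  write_bed(bed, path)
}
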