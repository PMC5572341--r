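#' Per-probe V_st between two groups
#'
#' V_st is a fixation-index-like statistic on probe intensity: for each probe,
#' `V_T` is the variance of LRR over all samples of the two groups pooled and
#' `V_S` is the size-weighted average of the within-group variances,
#' `(n_A * V_A + n_B * V_B) / (n_A + n_B)`. Then `vst = (V_T - V_S) / V_T`,
#' ranging from 0 (no differentiation) to 1 (complete differentiation).
#' Population variances (denominator n) are used so that two identical group
#' distributions give exactly 0 on finite samples; when `V_T = 0` the
#' statistic is defined as 0. Values below 0 (within-group variance exceeding
#' the total) are retained unclamped.
#'
#' V_st is computed on whatever LRR matrix is supplied; pass GC-adjusted LRR
#' (see [gc_adjust_lrr()]) to avoid wave-driven artifacts.
#'
#' @param lrr Numeric LRR matrix, probes x samples, with sample column names.
#' @param samples_a,samples_b Character vectors of sample ids for the two
#'   groups; each must have at least 2 samples.
#' @param weighted If `FALSE`, `V_S` is the unweighted mean of the two
#'   within-group variances.
#' @param population_variance If `FALSE`, sample variances (denominator n-1)
#'   are used throughout.
#' @return Numeric vector of per-probe V_st, aligned to the rows of `lrr`.
#' @export
per_probe_vst <- function(lrr, samples_a, samples_b, weighted = TRUE,
                          population_variance = TRUE) {
  stopifnot(is.matrix(lrr), !is.null(colnames(lrr)))
  miss <- setdiff(c(samples_a, samples_b), colnames(lrr))
  if (length(miss) > 0L) stop("samples absent from LRR matrix: ",
                              paste(miss, collapse = ", "))
  na <- length(samples_a)
  nb <- length(samples_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")

  rowvar <- function(m, pop) {
    mu <- rowMeans(m)
    ss <- rowSums((m - mu)^2)
    ss / (ncol(m) - if (pop) 0L else 1L)
  }
  va <- rowvar(lrr[, samples_a, drop = FALSE], population_variance)
  vb <- rowvar(lrr[, samples_b, drop = FALSE], population_variance)
  vt <- rowvar(lrr[, c(samples_a, samples_b), drop = FALSE], population_variance)
  vs <- if (weighted) (na * va + nb * vb) / (na + nb) else (va + vb) / 2
  vst <- ifelse(vt == 0, 0, (vt - vs) / vt)
  as.numeric(vst)
}

#' Scan a V_st track for differentiated probe runs
#'
#' Finds maximal runs of at least `min_probes` consecutive probes on one
#' chromosome whose V_st strictly exceeds `threshold`. This is equivalent to
#' sliding a `min_probes`-wide window with a one-probe shift and merging
#' overlapping significant windows. Runs never cross chromosome boundaries.
#'
#' @param vst Per-probe V_st vector aligned to `probes`.
#' @param probes Probe map (see [probe_map()]).
#' @param threshold Strict V_st threshold, default 0.35.
#' @param min_probes Minimum run length in probes, default 3.
#' @return `data.frame` of runs: `chrom`, `first_probe`, `last_probe` (global
#'   row indices into the probe map), `start`, `end` (bp), `n_probes`,
#'   `min_vst`.
#' @export
scan_differentiated_runs <- function(vst, probes, threshold = 0.35,
                                     min_probes = 3L) {
  stopifnot(length(vst) == nrow(probes))
  hot <- vst > threshold
  # break runs at chromosome boundaries by rle over (chrom, hot) pairs
  grp <- cumsum(c(TRUE, diff(probes$chrom) != 0L | diff(hot) != 0L))
  runs <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (!hot[idx[1L]] || length(idx) < min_probes) next
    runs[[length(runs) + 1L]] <- data.frame(
      chrom = probes$chrom[idx[1L]],
      first_probe = idx[1L],
      last_probe = idx[length(idx)],
      start = probes$pos[idx[1L]],
      end = probes$pos[idx[length(idx)]],
      n_probes = length(idx),
      min_vst = min(vst[idx]),
      stringsAsFactors = FALSE
    )
  }
  if (length(runs) == 0L) {
    return(data.frame(
      chrom = integer(), first_probe = integer(), last_probe = integer(),
      start = integer(), end = integer(), n_probes = integer(),
      min_vst = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Map differentiated runs to CNVs or CNVRs
#'
#' A CNV or CNVR is flagged population-differentiated only when its span
#' fully contains the bp span of a differentiated run - a run that merely
#' half-overlaps an event does not qualify.
#'
#' @param runs Output of [scan_differentiated_runs()].
#' @param intervals Interval `data.frame` (`chrom`, `start`, `end`) with an
#'   id column (`cnvr_id`, `component_id`, or `sample_id`+coords for raw
#'   calls).
#' @param id_col Name of the id column in `intervals`; default picks
#'   `cnvr_id` if present, else row numbers.
#' @return `runs` with a list column `contained_in` of interval ids fully
#'   containing each run (empty character vector when unmapped).
#' @export
map_runs_to_cnvs <- function(runs, intervals, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- if ("cnvr_id" %in% names(intervals)) "cnvr_id" else NULL
  }
  ids <- if (is.null(id_col)) {
    as.character(seq_len(nrow(intervals)))
  } else {
    as.character(intervals[[id_col]])
  }
  runs$contained_in <- I(lapply(seq_len(nrow(runs)), function(i) {
    hit <- intervals$chrom == runs$chrom[i] &
      intervals$start <= runs$start[i] &
      intervals$end >= runs$end[i]
    ids[hit]
  }))
  runs
}

#' Flag differentiated runs driven by sex-dosage artifacts
#'
#' Autosomal probes carrying mis-assembled sex-chromosome sequence show a
#' dosage difference between males and females, which masquerades as
#' population differentiation whenever group sex ratios differ. For every run,
#' each sample's mean LRR over the run's probes is compared between sexes with
#' a two-sided Wilcoxon rank-sum test; a run is flagged as a sex artifact when
#' its Bonferroni-adjusted p-value (across all runs tested) is below `alpha`.
#'
#' @param runs Output of [scan_differentiated_runs()].
#' @param lrr LRR matrix, probes x samples (same probe order as the scan).
#' @param meta Sample metadata with `sample_id` and `sex`.
#' @param alpha Significance level after Bonferroni adjustment, default 0.05.
#' @return `runs` with columns `sex_p_raw`, `sex_p_bonferroni` and
#'   `sex_artifact` (logical; `NA` = untestable when either sex has fewer
#'   than 2 known-sex samples).
#' @export
sex_artifact_filter <- function(runs, lrr, meta, alpha = 0.05) {
  stopifnot(is.matrix(lrr), !is.null(colnames(lrr)))
  males <- intersect(meta$sample_id[meta$sex == "male"], colnames(lrr))
  females <- intersect(meta$sample_id[meta$sex == "female"], colnames(lrr))
  n_runs <- nrow(runs)
  runs$sex_p_raw <- rep(NA_real_, n_runs)
  runs$sex_p_bonferroni <- rep(NA_real_, n_runs)
  runs$sex_artifact <- rep(NA, n_runs)
  if (n_runs == 0L) return(runs)
  if (length(males) < 2L || length(females) < 2L) {
    return(runs) # untestable: a sex absent or (almost) absent
  }
  for (i in seq_len(n_runs)) {
    span <- runs$first_probe[i]:runs$last_probe[i]
    mm <- colMeans(lrr[span, males, drop = FALSE])
    ff <- colMeans(lrr[span, females, drop = FALSE])
    runs$sex_p_raw[i] <- suppressWarnings(
      stats::wilcox.test(mm, ff, exact = FALSE, correct = TRUE)
    )$p.value
  }
  runs$sex_p_bonferroni <- pmin(1, runs$sex_p_raw * n_runs)
  runs$sex_artifact <- runs$sex_p_bonferroni < alpha
  runs
}

#' Write a V_st track to TSV
#'
#' @param vst Per-probe V_st vector.
#' @param probes Probe map.
#' @param path Output path; columns `probe_id chrom pos vst`.
#' @export
write_vst_tsv <- function(vst, probes, path) {
  out <- data.frame(
    probe_id = probes$probe_id, chrom = probes$chrom, pos = probes$pos,
    vst = as.numeric(vst), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
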