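#' Partition CNV calls into singletons and shared calls
#'
#' A call is *shared* iff it overlaps, by at least one base pair on the same
#' chromosome, a call from a different sample; otherwise it is a singleton.
#' Overlapping calls within one and the same sample do not make each other
#' shared. Adjacent calls (zero-bp overlap) do not count.
#'
#' @param calls CNV call `data.frame`.
#' @return List with elements `singletons` and `shared`, a disjoint and
#'   exhaustive partition of the input rows (order preserved).
#' @export
identify_singletons <- function(calls) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0L) return(list(singletons = calls, shared = calls))
  gr <- intervals_to_granges(calls)
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = 1L, drop.self = TRUE)
  other <- calls$sample_id[S4Vectors::queryHits(hits)] !=
    calls$sample_id[S4Vectors::subjectHits(hits)]
  shared_idx <- unique(S4Vectors::queryHits(hits)[other])
  is_shared <- seq_len(nrow(calls)) %in% shared_idx
  list(
    singletons = calls[!is_shared, , drop = FALSE],
    shared = calls[is_shared, , drop = FALSE]
  )
}

#' Per-sample CNV burden
#'
#' Counts and cumulative lengths of CNV calls per sample, with genic subsets
#' when a gene interval set is supplied. Call length is `end - start + 1`
#' (1-based inclusive coordinates). A call is genic iff it overlaps at least
#' one gene by at least one base pair; `n_genic_deletions` counts genic calls
#' with copy state below 2.
#'
#' @param calls CNV call `data.frame`.
#' @param genes Optional gene interval `data.frame` (`chrom`, `start`, `end`).
#' @param samples Optional character vector of sample ids to report (samples
#'   with no calls get an all-zero row); defaults to the samples present in
#'   `calls`.
#' @return `data.frame` with columns `sample_id`, `n_cnvs`,
#'   `cumulative_length`, `n_genic_cnvs`, `pct_genic_cnvs`,
#'   `cumulative_genic_length`, `n_genic_deletions`.
#' @export
per_sample_burden <- function(calls, genes = NULL, samples = NULL) {
  calls <- validate_calls(calls)
  if (is.null(samples)) samples <- unique(calls$sample_id)
  genic <- rep(FALSE, nrow(calls))
  if (!is.null(genes) && nrow(calls) > 0L && nrow(genes) > 0L) {
    h <- harmonize_seqlevels(intervals_to_granges(calls),
                             intervals_to_granges(genes))
    hits <- GenomicRanges::findOverlaps(h[[1L]], h[[2L]], minoverlap = 1L)
    genic[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  len <- if (nrow(calls) > 0L) calls$end - calls$start + 1 else numeric()
  per <- function(ids, values, f = sum) {
    out <- tapply(values, factor(ids, levels = samples), f, default = 0)
    as.numeric(out)
  }
  n_cnvs <- per(calls$sample_id, rep(1L, nrow(calls)))
  n_genic <- per(calls$sample_id, as.integer(genic))
  data.frame(
    sample_id = samples,
    n_cnvs = n_cnvs,
    cumulative_length = per(calls$sample_id, len),
    n_genic_cnvs = n_genic,
    pct_genic_cnvs = ifelse(n_cnvs > 0, 100 * n_genic / n_cnvs, 0),
    cumulative_genic_length = per(calls$sample_id, len * genic),
    n_genic_deletions = per(calls$sample_id, as.integer(genic & calls$copy_state < 2L)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Remove per-breed burden outliers
#'
#' Within every breed represented by more than five samples, a sample is
#' dropped when its CNV count or cumulative CNV length falls outside
#' mean plus/minus 3 SD of the breed. The breed mean and SD for each sample
#' are computed from the *other* samples of the breed (leave-one-out):
#' with the small per-breed sample sizes typical of these cohorts, a
#' contaminated sample included in its own reference statistics could never
#' reach the 3 SD cut. Breeds with five or fewer samples are left untouched.
#'
#' @param burdens Output of [per_sample_burden()].
#' @param breed_map Named character vector or `data.frame`
#'   (`sample_id`, `breed`) mapping samples to breeds.
#' @param n_sd SD multiplier, default 3.
#' @param min_breed_size Breeds with more than this many samples are screened
#'   (default 5).
#' @return Character vector of retained sample ids.
#' @export
remove_outlier_samples <- function(burdens, breed_map, n_sd = 3, min_breed_size = 5L) {
  stopifnot(is.data.frame(burdens), all(c("n_cnvs", "cumulative_length") %in% names(burdens)))
  if (is.data.frame(breed_map)) {
    breed_map <- stats::setNames(breed_map$breed, breed_map$sample_id)
  }
  breed <- breed_map[burdens$sample_id]
  if (any(is.na(breed))) stop("breed missing for some samples")
  drop <- rep(FALSE, nrow(burdens))
  loo_outlier <- function(x, n_sd) {
    vapply(seq_along(x), function(i) {
      rest <- x[-i]
      m <- mean(rest)
      s <- stats::sd(rest)
      if (is.na(s) || s == 0) x[i] != m else abs(x[i] - m) > n_sd * s
    }, logical(1L))
  }
  for (b in unique(breed)) {
    idx <- which(breed == b)
    if (length(idx) <= min_breed_size) next
    out <- loo_outlier(burdens$n_cnvs[idx], n_sd) |
      loo_outlier(burdens$cumulative_length[idx], n_sd)
    drop[idx[out]] <- TRUE
  }
  burdens$sample_id[!drop]
}

#' Group comparison of CNV burden
#'
#' Overall differentiation of per-sample CNV counts between groups is tested
#' with a (tie-corrected) Kruskal-Wallis test, and of cumulative CNV length
#' with a one-way ANOVA. When an overall test is significant at `alpha`, all
#' pairwise comparisons follow: Mann-Whitney (Wilcoxon rank-sum) tests for
#' counts and two-sample t-tests for lengths, with Bonferroni correction
#' (raw p multiplied by the number of pairs, capped at 1). Rank-sum tests use
#' exact enumeration when both groups have at most 8 samples and no ties, and
#' the normal approximation with continuity correction otherwise.
#'
#' @param burdens Output of [per_sample_burden()].
#' @param groups Named character vector or `data.frame`
#'   (`sample_id`, `group`) mapping samples to groups.
#' @param alpha Significance level gating the post hoc tests, default 0.05.
#' @return A `cnv_group_tests` list: `overall` (`data.frame` of the two
#'   omnibus tests) and `pairwise` (`data.frame` of post hoc tests with raw
#'   and Bonferroni-adjusted p-values; zero rows when no omnibus test passes).
#' @export
group_burden_tests <- function(burdens, groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  g <- factor(groups[burdens$sample_id])
  if (any(is.na(g))) stop("group missing for some samples")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 samples")

  kw <- stats::kruskal.test(burdens$n_cnvs, g)
  av <- stats::anova(stats::lm(burdens$cumulative_length ~ g))
  overall <- data.frame(
    metric = c("n_cnvs", "cumulative_length"),
    test = c("kruskal_wallis", "one_way_anova"),
    statistic = c(unname(kw$statistic), av$`F value`[1L]),
    p_value = c(kw$p.value, av$`Pr(>F)`[1L]),
    stringsAsFactors = FALSE
  )

  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  n_pairs <- length(pairs)
  pairwise <- list()
  run_pairwise <- function(metric, overall_p, test_fun) {
    if (overall_p >= alpha) return(NULL)
    do.call(rbind, lapply(pairs, function(pr) {
      xa <- burdens[[metric]][g == pr[1L]]
      xb <- burdens[[metric]][g == pr[2L]]
      p <- test_fun(xa, xb)
      data.frame(
        metric = metric, group_a = pr[1L], group_b = pr[2L],
        p_raw = p, p_bonferroni = min(1, p * n_pairs),
        stringsAsFactors = FALSE
      )
    }))
  }
  mw <- function(xa, xb) {
    exact <- length(xa) <= 8L && length(xb) <= 8L
    suppressWarnings(stats::wilcox.test(xa, xb, exact = exact, correct = TRUE))$p.value
  }
  tt <- function(xa, xb) stats::t.test(xa, xb)$p.value
  pairwise <- rbind(
    run_pairwise("n_cnvs", overall$p_value[1L], mw),
    run_pairwise("cumulative_length", overall$p_value[2L], tt)
  )
  if (is.null(pairwise)) {
    pairwise <- data.frame(
      metric = character(), group_a = character(), group_b = character(),
      p_raw = numeric(), p_bonferroni = numeric(), stringsAsFactors = FALSE
    )
  }
  structure(list(overall = overall, pairwise = pairwise, alpha = alpha),
            class = "cnv_group_tests")
}

#' @export
print.cnv_group_tests <- function(x, ...) {
  cat("Overall burden tests:\n")
  print(x$overall, row.names = FALSE)
  if (nrow(x$pairwise) > 0L) {
    cat("\nPost hoc pairwise tests (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  } else {
    cat("\nNo omnibus test significant at alpha =", x$alpha,
        "- post hoc tests skipped\n")
  }
  invisible(x)
}
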