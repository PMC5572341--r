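test_that("build_cnvrs merges overlapping calls from different samples", {
  res <- build_cnvrs(toy_calls(
    list("A", 1, 100, 200, 1),
    list("B", 1, 150, 250, 1)
  ), n_samples_cohort = 2L)
  expect_equal(nrow(res$cnvrs), 1L)
  expect_equal(res$cnvrs$start, 100L)
  expect_equal(res$cnvrs$end, 250L)
  expect_setequal(res$cnvrs$samples[[1]], c("A", "B"))
  expect_equal(res$cnvrs$klass, "loss")

  # transitive merging: A-B and B-C overlap chains A, B, C together
  res3 <- build_cnvrs(toy_calls(
    list("A", 1, 100, 200, 1),
    list("B", 1, 190, 300, 1),
    list("C", 1, 290, 400, 3)
  ), n_samples_cohort = 3L)
  expect_equal(nrow(res3$cnvrs), 1L)
  expect_equal(c(res3$cnvrs$start, res3$cnvrs$end), c(100L, 400L))
  expect_equal(res3$cnvrs$klass, "complex")
  expect_setequal(res3$cnvrs$samples[[1]], c("A", "B", "C"))

  # single-sample components come back as singleton clusters
  mix <- build_cnvrs(toy_calls(
    list("A", 1, 100, 200, 1),
    list("A", 1, 150, 250, 1),
    list("B", 2, 100, 200, 3)
  ), n_samples_cohort = 2L)
  expect_equal(nrow(mix$cnvrs), 0L)
  expect_equal(nrow(mix$singletons), 2L)
  expect_equal(mix$singletons$sample_id, c("A", "B"))
  expect_equal(mix$singletons$start, c(100L, 100L))
  expect_equal(mix$singletons$end, c(250L, 200L))
})

test_that("build_cnvrs matches the base-pair bitmap oracle on random instances", {
  set.seed(1234)
  for (r in 1:200) {
    calls <- random_toy_calls(max_calls = 30L, max_coord = 3000L)
    res <- build_cnvrs(calls, n_samples_cohort = 6L)
    oracle <- bitmap_cnvrs(calls)
    o_multi <- Filter(function(x) length(x$samples) >= 2L, oracle)
    o_single <- Filter(function(x) length(x$samples) < 2L, oracle)

    expect_equal(nrow(res$cnvrs), length(o_multi))
    expect_equal(nrow(res$singletons), length(o_single))
    for (k in seq_along(o_multi)) {
      expect_equal(res$cnvrs$chrom[k], o_multi[[k]]$chrom)
      expect_equal(res$cnvrs$start[k], o_multi[[k]]$start)
      expect_equal(res$cnvrs$end[k], o_multi[[k]]$end)
      expect_setequal(res$cnvrs$samples[[k]], o_multi[[k]]$samples)
      expect_equal(res$cnvrs$klass[k], o_multi[[k]]$klass)
    }
    for (k in seq_along(o_single)) {
      expect_equal(res$singletons$start[k], o_single[[k]]$start)
      expect_equal(res$singletons$end[k], o_single[[k]]$end)
    }
  }
})

test_that("every call lands in exactly one component and spans are disjoint", {
  set.seed(99)
  for (r in 1:50) {
    calls <- random_toy_calls()
    res <- build_cnvrs(calls, n_samples_cohort = 6L)
    assigned <- c(unlist(res$cnvrs$member_rows), unlist(res$singletons$member_rows))
    expect_setequal(assigned, seq_len(nrow(calls)))
    expect_equal(length(assigned), nrow(calls))
    # CNVR spans per chromosome never overlap
    for (cc in unique(res$cnvrs$chrom)) {
      x <- res$cnvrs[res$cnvrs$chrom == cc, ]
      x <- x[order(x$start), ]
      if (nrow(x) > 1L) expect_true(all(x$start[-1] > x$end[-nrow(x)]))
    }
    # class partition covers all CNVRs
    expect_equal(sum(res$cnvrs$klass %in% c("loss", "gain", "complex")),
                 nrow(res$cnvrs))
  }
})

test_that("cnvr_frequency reproduces the cohort percentages", {
  expect_equal(pct_display(cnvr_frequency(2, 149)), 1.34)
  expect_equal(pct_display(cnvr_frequency(145, 149)), 97.31)
  expect_equal(cnvr_frequency(149, 149), 100)
  expect_error(cnvr_frequency(1, 0), "positive")
  expect_error(cnvr_frequency(5, 4), "exceeds")
})

test_that("chromosome_stats summarizes counts, coverage and gaps", {
  cnvrs <- data.frame(
    cnvr_id = c("r1", "r2", "r3"),
    chrom = c(1L, 1L, 2L),
    start = c(1L, 21L, 1000001L),
    end = c(10L, 30L, 2000000L),
    stringsAsFactors = FALSE
  )
  st <- chromosome_stats(cnvrs, c(`1` = 1000L, `2` = 100e6))
  expect_equal(st$n_cnvrs, c(2L, 1L))
  expect_equal(st$cumulative_length[1], 20)
  expect_equal(st$mean_gap_bp[1], 10) # 21 - 10 - 1
  expect_true(is.na(st$mean_gap_bp[2]))
  expect_equal(st$coverage_pct[2], 1) # 1 Mb of a 100 Mb chromosome
  expect_error(chromosome_stats(cnvrs, c(`1` = 1000L)), "chromosome length")

  # cumulative length agrees with a bitmap union oracle (spans are disjoint)
  set.seed(41)
  calls <- random_toy_calls(max_calls = 40L, max_coord = 5000L)
  res <- build_cnvrs(calls, n_samples_cohort = 6L)
  if (nrow(res$cnvrs) > 0L) {
    st2 <- chromosome_stats(res$cnvrs, setNames(rep(10000, 2), c("1", "2")))
    for (i in seq_len(nrow(st2))) {
      x <- res$cnvrs[res$cnvrs$chrom == st2$chrom[i], ]
      bitmap <- logical(10000)
      for (k in seq_len(nrow(x))) bitmap[x$start[k]:x$end[k]] <- TRUE
      expect_equal(st2$cumulative_length[i], sum(bitmap))
    }
  }
})

test_that("annotate_intervals applies the 1 bp rule and the SD length filter", {
  cnvrs <- data.frame(cnvr_id = "r1", chrom = 1L, start = 100L, end = 200L,
                      stringsAsFactors = FALSE)
  gene_hit <- data.frame(chrom = 1L, start = 200L, end = 300L, name = "G1")
  gene_miss <- data.frame(chrom = 1L, start = 201L, end = 300L, name = "G2")
  expect_equal(annotate_intervals(cnvrs, gene_hit)$overlap_bp, 1L)
  expect_equal(nrow(annotate_intervals(cnvrs, gene_miss)), 0L)

  # strictly longer than 5 kb: a 5,000 bp SD is excluded
  sds <- data.frame(chrom = 1L, start = c(1L, 10001L),
                    end = c(5000L, 15001L)) # lengths 5000 and 5001
  kept <- filter_segdups(sds)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 10001L)
})

test_that("compare_with_reference_sets accounts overlap by count and length", {
  set.seed(55)
  calls <- random_toy_calls(max_calls = 30L, max_coord = 5000L)
  res <- build_cnvrs(calls, n_samples_cohort = 6L)
  cnvrs <- res$cnvrs
  if (nrow(cnvrs) < 2L) skip("random instance produced too few CNVRs")

  # identical reference: 100% by count and by length, nothing novel
  self_ref <- cnvrs[c("chrom", "start", "end")]
  cmp <- compare_with_reference_sets(cnvrs, list(self = self_ref))
  expect_equal(cmp$reports$pct_overlapped, 100)
  expect_equal(cmp$reports$pct_length_overlapped, 100)
  expect_length(cmp$novel, 0L)

  # disjoint reference: 0% everywhere, every CNVR novel
  far <- data.frame(chrom = 25L, start = c(1L, 100L), end = c(50L, 200L))
  cmp2 <- compare_with_reference_sets(cnvrs, list(far = far))
  expect_equal(cmp2$reports$pct_overlapped, 0)
  expect_equal(cmp2$reports$pct_length_overlapped, 0)
  expect_setequal(cmp2$novel, cnvrs$cnvr_id)

  # empty reference set: zero-filled report
  cmp3 <- compare_with_reference_sets(
    cnvrs, list(none = far[0, ], self = self_ref)
  )
  expect_equal(cmp3$reports$n_overlapped[1], 0L)
  expect_equal(cmp3$reports$pct_overlapped[1], 0)
  # novelty is judged against the union of all reference sets
  expect_length(cmp3$novel, 0L)
})

test_that("CNVR tables and BED round-trip to disk", {
  res <- build_cnvrs(toy_calls(
    list("A", 1, 100, 200, 1),
    list("B", 1, 150, 250, 1),
    list("A", 2, 500, 700, 3),
    list("C", 2, 600, 800, 3)
  ), n_samples_cohort = 3L)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "cnvr.tsv")
  bed <- file.path(dir, "cnvr.bed")
  write_cnvr_tsv(res$cnvrs, tsv)
  write_cnvr_bed(res$cnvrs, bed)
  tab <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(tab$cnvr_id, res$cnvrs$cnvr_id)
  expect_equal(tab$n_samples, res$cnvrs$n_samples)
  expect_equal(tab$freq_pct, pct_display(res$cnvrs$freq_pct))
  back <- read_bed(bed)
  expect_equal(back$start, res$cnvrs$start)
  expect_equal(back$end, res$cnvrs$end)
  expect_equal(back$name, paste0(res$cnvrs$cnvr_id, "_", res$cnvrs$klass))
})
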