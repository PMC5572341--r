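test_that("identify_singletons partitions by cross-sample overlap", {
  calls <- toy_calls(
    list("A", 1, 100, 200),
    list("B", 1, 150, 250),
    list("C", 1, 300, 400)
  )
  parts <- identify_singletons(calls)
  expect_equal(parts$shared$sample_id, c("A", "B"))
  expect_equal(parts$singletons$sample_id, "C")

  # overlapping calls within the SAME sample stay singletons
  same <- toy_calls(list("A", 1, 100, 200), list("A", 1, 150, 250))
  parts2 <- identify_singletons(same)
  expect_equal(nrow(parts2$singletons), 2L)
  expect_equal(nrow(parts2$shared), 0L)

  # adjacency is not overlap
  adj <- toy_calls(list("A", 1, 100, 200), list("B", 1, 201, 300))
  parts3 <- identify_singletons(adj)
  expect_equal(nrow(parts3$singletons), 2L)
})

test_that("singletons and shared calls form an exhaustive disjoint partition", {
  set.seed(8)
  for (r in 1:20) {
    calls <- random_toy_calls()
    parts <- identify_singletons(calls)
    expect_equal(nrow(parts$singletons) + nrow(parts$shared), nrow(calls))
    key <- function(d) paste(d$sample_id, d$chrom, d$start, d$end, d$copy_state)
    expect_length(intersect(key(parts$singletons), key(parts$shared)), 0L)
    expect_setequal(c(key(parts$singletons), key(parts$shared)), key(calls))
  }
})

test_that("per_sample_burden counts calls, lengths and genic overlap", {
  calls <- toy_calls(
    list("A", 1, 100, 200, 1),   # genic by exactly 1 bp (gene starts at 200)
    list("A", 2, 1000, 1999, 3), # non-genic
    list("B", 1, 500, 599, 0)    # genic deletion
  )
  genes <- data.frame(chrom = c(1L, 1L), start = c(200L, 550L),
                      end = c(300L, 560L))
  b <- per_sample_burden(calls, genes = genes, samples = c("A", "B", "C"))
  expect_equal(b$sample_id, c("A", "B", "C"))
  expect_equal(b$n_cnvs, c(2, 1, 0))
  expect_equal(b$cumulative_length, c(101 + 1000, 100, 0))
  expect_equal(b$n_genic_cnvs, c(1, 1, 0))
  expect_equal(b$pct_genic_cnvs, c(50, 100, 0))
  expect_equal(b$cumulative_genic_length, c(101, 100, 0))
  expect_equal(b$n_genic_deletions, c(1, 1, 0))

  # a gene adjacent to a call (no shared base) does not count
  calls2 <- toy_calls(list("A", 1, 100, 200, 1))
  genes2 <- data.frame(chrom = 1L, start = 201L, end = 300L)
  expect_equal(per_sample_burden(calls2, genes = genes2)$n_genic_cnvs, 0)
})

test_that("burden totals are additive over disjoint call files", {
  set.seed(31)
  calls1 <- random_toy_calls(max_calls = 30L)
  calls2 <- random_toy_calls(max_calls = 30L)
  calls2$chrom <- calls2$chrom + 10L # keep the two files disjoint
  samples <- sort(unique(c(calls1$sample_id, calls2$sample_id)))
  b1 <- per_sample_burden(calls1, samples = samples)
  b2 <- per_sample_burden(calls2, samples = samples)
  b12 <- per_sample_burden(rbind(calls1, calls2), samples = samples)
  expect_equal(b12$n_cnvs, b1$n_cnvs + b2$n_cnvs)
  expect_equal(b12$cumulative_length, b1$cumulative_length + b2$cumulative_length)
})

test_that("remove_outlier_samples drops extreme samples in large breeds only", {
  mk <- function(counts, breed) {
    data.frame(
      sample_id = paste0(breed, seq_along(counts)),
      n_cnvs = counts,
      cumulative_length = rep(1000, length(counts)),
      stringsAsFactors = FALSE
    )
  }
  # breed of 6: one sample at mean + 5 SD of the other five is dropped
  base <- c(60, 62, 64, 66, 68)
  extreme <- mean(base) + 5 * sd(base)
  b6 <- mk(c(base, extreme), "X")
  breeds <- setNames(rep("X", 6), b6$sample_id)
  kept <- remove_outlier_samples(b6, breeds)
  expect_setequal(kept, b6$sample_id[1:5])

  # breed of exactly 5: untouched even with an extreme sample
  b5 <- mk(c(base[1:4], 1000), "Y")
  breeds5 <- setNames(rep("Y", 5), b5$sample_id)
  expect_setequal(remove_outlier_samples(b5, breeds5), b5$sample_id)

  # all samples identical: nothing removed
  b_id <- mk(rep(50, 8), "Z")
  breedsz <- setNames(rep("Z", 8), b_id$sample_id)
  expect_setequal(remove_outlier_samples(b_id, breedsz), b_id$sample_id)

  # outlier in size alone also triggers removal (union of the two metrics)
  bs <- mk(rep(50, 7), "W")
  bs$cumulative_length <- c(rep(1000, 6), 1e6)
  breedsw <- setNames(rep("W", 7), bs$sample_id)
  expect_setequal(remove_outlier_samples(bs, breedsw), bs$sample_id[1:6])
})

test_that("group_burden_tests runs the omnibus and post hoc battery", {
  set.seed(17)
  burdens <- data.frame(
    sample_id = paste0("S", 1:30),
    n_cnvs = c(rnorm(10, 50, 5), rnorm(10, 50, 5), rnorm(10, 90, 5)),
    cumulative_length = c(rnorm(10, 1e5, 1e4), rnorm(10, 1e5, 1e4),
                          rnorm(10, 3e5, 1e4)),
    stringsAsFactors = FALSE
  )
  groups <- setNames(rep(c("BAI", "BRI", "NLD"), each = 10), burdens$sample_id)
  res <- group_burden_tests(burdens, groups)
  expect_s3_class(res, "cnv_group_tests")
  expect_equal(res$overall$test, c("kruskal_wallis", "one_way_anova"))
  expect_true(all(res$overall$p_value < 0.05))
  expect_equal(nrow(res$pairwise), 2 * choose(3, 2))
  # Bonferroni-adjusted p >= raw p, capped at 1
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_bonferroni <= 1))
  # the shifted group NLD is significant against both others on both metrics
  nld <- res$pairwise[res$pairwise$group_a == "NLD" | res$pairwise$group_b == "NLD", ]
  expect_true(all(nld$p_bonferroni < 0.05))
})

test_that("identical group multisets give a zero Kruskal-Wallis statistic", {
  burdens <- data.frame(
    sample_id = paste0("S", 1:8),
    n_cnvs = rep(c(3, 1, 4, 1), 2),
    cumulative_length = rep(c(10, 20, 30, 40), 2),
    stringsAsFactors = FALSE
  )
  groups <- setNames(rep(c("BAI", "BRI"), each = 4), burdens$sample_id)
  res <- group_burden_tests(burdens, groups)
  expect_equal(res$overall$statistic[1], 0, tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 0L)
})

test_that("group_burden_tests rejects undersized groups", {
  burdens <- data.frame(sample_id = c("a", "b", "c"), n_cnvs = 1:3,
                        cumulative_length = 1:3, stringsAsFactors = FALSE)
  groups <- setNames(c("BAI", "BAI", "BRI"), burdens$sample_id)
  expect_error(group_burden_tests(burdens, groups), "at least 2 samples")
  expect_error(
    group_burden_tests(burdens[1:2, ], groups[1:2]),
    "at least 2 groups"
  )
})

test_that("a shifted group is flagged by the post hoc battery", {
  # counts shifted by +30 in one of five groups (n = 20, noise SD 5):
  # that group's pairwise count comparisons stay Bonferroni-significant
  labels <- c("BAI", "BRI", "IBR", "NLD", "ALP")
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    set.seed(4000L + r)
    burdens <- data.frame(
      sample_id = paste0("S", 1:100),
      n_cnvs = c(rnorm(80, 60, 5), rnorm(20, 90, 5)),
      cumulative_length = rnorm(100, 1e5, 1e4),
      stringsAsFactors = FALSE
    )
    groups <- setNames(rep(labels, each = 20), burdens$sample_id)
    res <- group_burden_tests(burdens, groups)
    pw <- res$pairwise[res$pairwise$metric == "n_cnvs" &
                         (res$pairwise$group_a == "ALP" |
                            res$pairwise$group_b == "ALP"), ]
    if (nrow(pw) == 4L && all(pw$p_bonferroni < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
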