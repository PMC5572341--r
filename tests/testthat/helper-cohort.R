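# Shared fixture builders (all fixtures are generated in code).

# Minimal signal object: one chromosome unless chrom given, evenly spaced.
make_test_signal <- function(lrr, baf = NULL, spacing = 100000L,
                             chrom = NULL, gc = NULL) {
  lrr <- as.matrix(lrr)
  n <- nrow(lrr)
  if (is.null(baf)) {
    baf <- matrix(rep(c(0, 0.5, 1), length.out = n * ncol(lrr)), n)
  }
  if (is.null(colnames(lrr))) {
    colnames(lrr) <- paste0("S", seq_len(ncol(lrr)))
  }
  colnames(baf) <- colnames(lrr)
  if (is.null(chrom)) chrom <- rep(1L, n)
  pos <- integer(n)
  for (cc in unique(chrom)) {
    k <- which(chrom == cc)
    pos[k] <- spacing * seq_along(k)
  }
  probes <- data.frame(
    probe_id = paste0("p", seq_len(n)),
    chrom = chrom, pos = pos, stringsAsFactors = FALSE
  )
  if (!is.null(gc)) probes$gc <- gc
  cnv_signal(probes, lrr, baf)
}

# Call-table builder: toy_calls("A", 1, 100, 200, 1) rows.
toy_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      sample_id = r[[1]], chrom = as.integer(r[[2]]),
      start = as.integer(r[[3]]), end = as.integer(r[[4]]),
      copy_state = if (length(r) >= 5) as.integer(r[[5]]) else 1L,
      n_probes = if (length(r) >= 6) as.integer(r[[6]]) else 5L,
      stringsAsFactors = FALSE
    )
  }))
}

default_two_groups <- function(n_per_group) {
  list(
    list(group = "BAI", breeds = "BAIbr", samples_per_breed = n_per_group,
         sex_ratio = 0.5),
    list(group = "BRI", breeds = "BRIbr", samples_per_breed = n_per_group,
         sex_ratio = 0.5)
  )
}

# Two-group cohort configuration used by the recovery and clustering suites:
# `n_per_group` samples per group, one breed each, small probe map.
two_group_config <- function(catalog, n_per_group = 20L, seed = 1L,
                             probes_per_chrom = 100L, n_chroms = 2L,
                             lrr_noise_sd = 0.15, ...) {
  sim_config(
    n_chroms = n_chroms, probes_per_chrom = probes_per_chrom,
    groups = list(
      list(group = "BAI", breeds = "BAIbr", samples_per_breed = n_per_group,
           sex_ratio = 0.5),
      list(group = "BRI", breeds = "BRIbr", samples_per_breed = n_per_group,
           sex_ratio = 0.5)
    ),
    cnv_catalog = catalog,
    lrr_noise_sd = lrr_noise_sd,
    seed = seed,
    ...
  )
}
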