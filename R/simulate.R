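#' Describe one copy-number polymorphism for the cohort simulator
#'
#' A polymorphism is a segregating CNV allele: a probe span on one chromosome,
#' a copy state, and a carrier frequency per breed group. Groups absent from
#' `freq` have frequency 0.
#'
#' @param chrom Chromosome (1-29).
#' @param start_probe,end_probe Probe indices within the chromosome
#'   (1-based, inclusive); every event must span at least 3 probes so that
#'   planted truth survives the minimum-probe call filter.
#' @param copy_state Copy state in \{0, 1, 3, 4\}.
#' @param freq Named numeric vector of carrier frequencies in \[0, 1\],
#'   names are breed-group labels.
#' @return A `cnv_polymorphism` list.
#' @export
cnv_polymorphism <- function(chrom, start_probe, end_probe, copy_state, freq) {
  stopifnot(
    length(chrom) == 1L, length(copy_state) == 1L,
    copy_state %in% c(0L, 1L, 3L, 4L),
    end_probe - start_probe + 1L >= 3L,
    start_probe >= 1L,
    is.numeric(freq), !is.null(names(freq)),
    all(freq >= 0), all(freq <= 1)
  )
  structure(
    list(
      chrom = as.integer(chrom),
      start_probe = as.integer(start_probe),
      end_probe = as.integer(end_probe),
      copy_state = as.integer(copy_state),
      freq = freq
    ),
    class = "cnv_polymorphism"
  )
}

default_cnv_catalog <- function() {
  # Mostly deletions, a few gains, one loss/gain pair sharing a locus (so
  # CNVR construction sees a complex region), frequencies varying by group.
  list(
    cnv_polymorphism(1, 21, 30, 1, c(BAI = 0.40, BRI = 0.45, IBR = 0.30, NLD = 0.15, ALP = 0.15)),
    cnv_polymorphism(1, 101, 108, 0, c(BAI = 0.10, BRI = 0.12, IBR = 0.08, NLD = 0.05, ALP = 0.05)),
    cnv_polymorphism(1, 201, 206, 3, c(BAI = 0.20, BRI = 0.10, IBR = 0.10, NLD = 0.10, ALP = 0.10)),
    cnv_polymorphism(2, 41, 52, 1, c(BAI = 0.60, BRI = 0.55, IBR = 0.50, NLD = 0.45, ALP = 0.40)),
    cnv_polymorphism(2, 44, 50, 3, c(BAI = 0.10, BRI = 0.10, IBR = 0.10, NLD = 0.10, ALP = 0.10)),
    cnv_polymorphism(2, 141, 146, 1, c(BAI = 0.25, BRI = 0.30, IBR = 0.10, NLD = 0.05, ALP = 0.05)),
    cnv_polymorphism(3, 61, 70, 1, c(BRI = 0.80)),
    cnv_polymorphism(3, 181, 188, 4, c(BAI = 0.15, BRI = 0.05, IBR = 0.05, NLD = 0.05, ALP = 0.05)),
    cnv_polymorphism(4, 91, 99, 1, c(BAI = 0.05, BRI = 0.05, IBR = 0.05, NLD = 0.60, ALP = 0.55)),
    cnv_polymorphism(5, 121, 129, 3, c(BAI = 0.30, BRI = 0.05, IBR = 0.20, NLD = 0.05, ALP = 0.05))
  )
}

default_sim_groups <- function() {
  # Five European breed-group labels; two breeds each, four samples per breed
  # (40 samples), balanced sexes - a desk-scale image of a multi-breed cohort.
  list(
    list(group = "BAI", breeds = c("BUS", "POD"), samples_per_breed = 4L, sex_ratio = 0.5),
    list(group = "BRI", breeds = c("EL", "HL"), samples_per_breed = 4L, sex_ratio = 0.5),
    list(group = "IBR", breeds = c("PA", "SAY"), samples_per_breed = 4L, sex_ratio = 0.5),
    list(group = "NLD", breeds = c("DF", "HF"), samples_per_breed = 4L, sex_ratio = 0.5),
    list(group = "ALP", breeds = c("BS", "TGV"), samples_per_breed = 4L, sex_ratio = 0.5)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the probe map geometry, cohort composition, segregating CNV
#' catalog, noise levels, GC-wave coupling, deliberately noisy samples and
#' sex-linked dosage artifacts of a simulated SNP-array cohort.
#'
#' @param n_chroms Number of autosomes to simulate.
#' @param probes_per_chrom Probes per chromosome.
#' @param probe_spacing Distance between adjacent probes, bp.
#' @param groups List of group descriptors: `group` label, `breeds`,
#'   `samples_per_breed`, `sex_ratio` (probability a sample is male).
#' @param cnv_catalog List of [cnv_polymorphism()] objects.
#' @param lrr_noise_sd Per-probe LRR noise SD for clean samples.
#' @param baf_noise_sd Per-probe BAF noise SD around genotype bands.
#' @param gc_wave_amplitude SD of the GC-tracking LRR wave component.
#' @param n_noisy_samples Number of samples given `noisy_lrr_sd` noise.
#' @param noisy_lrr_sd LRR noise SD for the noisy samples.
#' @param sex_artifact_probes List of global probe index ranges
#'   `c(first, last)` where males receive a fixed LRR offset, mimicking
#'   sex-chromosome sequence mis-assembled onto autosomes.
#' @param sex_artifact_offset LRR offset added to males at artifact probes.
#' @param lrr_shift Named vector: mean LRR shift per copy state.
#' @param call_jitter If `TRUE`, emitted call boundaries are perturbed by
#'   plus/minus one probe relative to planted truth.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 5L,
                       probes_per_chrom = 400L,
                       probe_spacing = 20000L,
                       groups = default_sim_groups(),
                       cnv_catalog = default_cnv_catalog(),
                       lrr_noise_sd = 0.15,
                       baf_noise_sd = 0.03,
                       gc_wave_amplitude = 0.02,
                       n_noisy_samples = 0L,
                       noisy_lrr_sd = 0.5,
                       sex_artifact_probes = list(),
                       sex_artifact_offset = 0.3,
                       lrr_shift = c(`0` = -3.0, `1` = -0.66, `2` = 0.0,
                                     `3` = 0.40, `4` = 0.68),
                       call_jitter = FALSE,
                       seed = 1L) {
  # accept plain lists (e.g. from a YAML config) as polymorphism descriptors
  cnv_catalog <- lapply(cnv_catalog, function(p) {
    if (inherits(p, "cnv_polymorphism")) return(p)
    cnv_polymorphism(p$chrom, p$start_probe, p$end_probe, p$copy_state,
                     unlist(p$freq))
  })
  cfg <- structure(
    list(
      n_chroms = as.integer(n_chroms),
      probes_per_chrom = as.integer(probes_per_chrom),
      probe_spacing = as.integer(probe_spacing),
      groups = groups,
      cnv_catalog = cnv_catalog,
      lrr_noise_sd = lrr_noise_sd,
      baf_noise_sd = baf_noise_sd,
      gc_wave_amplitude = gc_wave_amplitude,
      n_noisy_samples = as.integer(n_noisy_samples),
      noisy_lrr_sd = noisy_lrr_sd,
      sex_artifact_probes = sex_artifact_probes,
      sex_artifact_offset = sex_artifact_offset,
      lrr_shift = lrr_shift,
      call_jitter = isTRUE(call_jitter),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_chroms < 1L || cfg$n_chroms > 29L) stop("n_chroms must be in 1..29")
  if (cfg$probes_per_chrom < 2L) stop("need at least 2 probes per chromosome")
  n_samples <- sum(vapply(
    cfg$groups,
    function(g) length(g$breeds) * g$samples_per_breed,
    1L
  ))
  if (n_samples < 1L) stop("configuration yields zero samples")
  for (p in cfg$cnv_catalog) {
    stopifnot(inherits(p, "cnv_polymorphism"))
    if (p$chrom > cfg$n_chroms || p$end_probe > cfg$probes_per_chrom) {
      stop("CNV polymorphism lies outside the simulated chromosomes")
    }
  }
  for (r in cfg$sex_artifact_probes) {
    if (length(r) != 2L || r[1] < 1L ||
        r[2] > cfg$n_chroms * cfg$probes_per_chrom || r[1] > r[2]) {
      stop("sex_artifact_probes ranges must be c(first, last) global probe indices")
    }
  }
  if (any(cfg$lrr_noise_sd < 0, cfg$baf_noise_sd < 0, cfg$gc_wave_amplitude < 0)) {
    stop("noise parameters must be non-negative")
  }
  cfg
}

baf_band <- function(n, copies, p, noise_sd) {
  # Genotype band positions for a given total copy number: B-allele count out
  # of `copies` draws, each allele B with probability p. Zero copies carry no
  # allelic information: BAF is uniform noise.
  if (copies == 0L) return(stats::runif(n))
  b <- stats::rbinom(n, copies, p)
  pmin(pmax(b / copies + stats::rnorm(n, 0, noise_sd), 0), 1)
}

#' Simulate a multi-group SNP-array cohort with known CNV truth
#'
#' Generates a probe map with a GC track, per-sample LRR/BAF matrices with
#' embedded copy-number events at group-specific carrier frequencies, sample
#' metadata and the exact list of planted events. Carriers are independent
#' Bernoulli draws per polymorphism and sample at the group's configured
#' frequency. Carrier probes take a copy-state-dependent LRR mean shift and
#' the matching BAF band structure (a single-copy state has no heterozygous
#' band; a three-copy state has bands near 0, 1/3, 2/3, 1). Every sample's
#' LRR carries a GC-tracking wave; designated noisy samples get inflated LRR
#' noise; designated probe ranges carry a male-specific LRR offset emulating
#' sex-chromosome mis-assembly.
#'
#' @param config A [sim_config()].
#' @return A `cnv_cohort` list: `probes` (probe map with `gc`), `signal`
#'   ([cnv_signal()]), `meta` (sample metadata with `noisy` flag), `truth`
#'   (planted events as a call table), `config`.
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)

  n_probes_chr <- config$probes_per_chrom
  chroms <- rep(seq_len(config$n_chroms), each = n_probes_chr)
  pos <- rep(config$probe_spacing * seq_len(n_probes_chr), times = config$n_chroms)
  gc <- 0.45 + 0.08 * sin(2 * pi * pos / 8e6)
  probes <- probe_map(
    probe_id = sprintf("snp_%d_%05d", chroms, rep(seq_len(n_probes_chr), config$n_chroms)),
    chrom = chroms, pos = pos, gc = gc
  )
  n_probes <- nrow(probes)

  meta <- do.call(rbind, lapply(config$groups, function(g) {
    do.call(rbind, lapply(g$breeds, function(b) {
      data.frame(
        sample_id = sprintf("%s_%02d", b, seq_len(g$samples_per_breed)),
        breed = b, group = g$group,
        sex = ifelse(stats::runif(g$samples_per_breed) < g$sex_ratio,
                     "male", "female"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(meta) <- NULL
  n_samples <- nrow(meta)
  meta$noisy <- FALSE
  if (config$n_noisy_samples > 0L) {
    meta$noisy[sample.int(n_samples, min(config$n_noisy_samples, n_samples))] <- TRUE
  }
  validate_sample_meta(meta)

  # Population allele frequency per probe, shared by all samples
  p_allele <- stats::runif(n_probes, 0.1, 0.9)
  gc_c <- gc - mean(gc)
  gc_unit <- if (stats::sd(gc_c) > 0) gc_c / stats::sd(gc_c) else gc_c

  lrr <- matrix(0, n_probes, n_samples)
  baf <- matrix(0, n_probes, n_samples)
  colnames(lrr) <- colnames(baf) <- meta$sample_id

  for (j in seq_len(n_samples)) {
    noise_sd <- if (meta$noisy[j]) config$noisy_lrr_sd else config$lrr_noise_sd
    wave_strength <- config$gc_wave_amplitude * stats::rnorm(1, 1, 0.25)
    lrr[, j] <- wave_strength * gc_unit + stats::rnorm(n_probes, 0, noise_sd)
    baf[, j] <- baf_band(n_probes, 2L, p_allele, config$baf_noise_sd)
  }

  # Plant CNV polymorphisms: Bernoulli carriers per group frequency
  truth <- list()
  for (poly in config$cnv_catalog) {
    offset <- (poly$chrom - 1L) * n_probes_chr
    span <- (offset + poly$start_probe):(offset + poly$end_probe)
    f <- poly$freq[meta$group]
    f[is.na(f)] <- 0
    carriers <- which(stats::runif(n_samples) < f)
    shift <- config$lrr_shift[as.character(poly$copy_state)]
    for (j in carriers) {
      lrr[span, j] <- lrr[span, j] + shift
      baf[span, j] <- baf_band(length(span), poly$copy_state,
                               p_allele[span], config$baf_noise_sd)
    }
    if (length(carriers) > 0L) {
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = meta$sample_id[carriers],
        chrom = poly$chrom,
        start = probes$pos[span[1L]],
        end = probes$pos[span[length(span)]],
        copy_state = poly$copy_state,
        n_probes = length(span),
        start_probe = span[1L],
        end_probe = span[length(span)],
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(truth) > 0L) {
    do.call(rbind, truth)
  } else {
    data.frame(
      sample_id = character(), chrom = integer(), start = integer(),
      end = integer(), copy_state = integer(), n_probes = integer(),
      start_probe = integer(), end_probe = integer(), stringsAsFactors = FALSE
    )
  }

  # Sex-linked dosage artifact: constant male LRR offset at designated probes
  males <- which(meta$sex == "male")
  for (r in config$sex_artifact_probes) {
    span <- r[1L]:r[2L]
    lrr[span, males] <- lrr[span, males] + config$sex_artifact_offset
  }

  if (config$call_jitter && nrow(truth) > 0L) {
    truth <- jitter_truth(truth, probes, n_probes_chr)
  }
  truth_calls <- truth[, c("sample_id", "chrom", "start", "end",
                           "copy_state", "n_probes")]
  rownames(truth_calls) <- NULL

  structure(
    list(
      probes = probes,
      signal = cnv_signal(probes, lrr, baf),
      meta = meta,
      truth = validate_calls(truth_calls),
      config = config
    ),
    class = "cnv_cohort"
  )
}

jitter_truth <- function(truth, probes, n_probes_chr) {
  # Perturb each call boundary by -1/0/+1 probe, clamped to the chromosome
  # and to a minimum width of 3 probes.
  for (i in seq_len(nrow(truth))) {
    lo <- (truth$chrom[i] - 1L) * n_probes_chr + 1L
    hi <- truth$chrom[i] * n_probes_chr
    s <- truth$start_probe[i] + sample(c(-1L, 0L, 1L), 1L)
    e <- truth$end_probe[i] + sample(c(-1L, 0L, 1L), 1L)
    s <- max(lo, min(s, hi))
    e <- max(lo, min(e, hi))
    if (e - s + 1L < 3L) { s <- truth$start_probe[i]; e <- truth$end_probe[i] }
    truth$start_probe[i] <- s
    truth$end_probe[i] <- e
    truth$start[i] <- probes$pos[s]
    truth$end[i] <- probes$pos[e]
    truth$n_probes[i] <- e - s + 1L
  }
  truth
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("cnv_cohort:", nrow(x$meta), "samples,", nrow(x$probes), "probes,",
      nrow(x$truth), "planted CNV calls\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the four cohort artifacts into `out_dir`: `signal.tsv` (wide
#' LRR/BAF layout of [write_signal_tsv()]), `truth.rawcnv` (planted events in
#' the PennCNV call dialect), `samples.tsv` (metadata) and `truth.bed`
#' (planted event spans, 0-based half-open). All files round-trip through the
#' package readers.
#'
#' @param cohort A `cnv_cohort` from [simulate_cohort()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    signal = file.path(out_dir, "signal.tsv"),
    rawcnv = file.path(out_dir, "truth.rawcnv"),
    meta = file.path(out_dir, "samples.tsv"),
    bed = file.path(out_dir, "truth.bed")
  )
  write_signal_tsv(cohort$signal, paths[["signal"]])
  write_rawcnv(cohort$truth, paths[["rawcnv"]])
  write_sample_meta(cohort$meta, paths[["meta"]])
  bed <- cohort$truth
  bed$name <- if (nrow(bed) > 0L) {
    sprintf("%s_cn%d", bed$sample_id, bed$copy_state)
  } else {
    character()
  }
  write_bed(bed, paths[["bed"]])
  invisible(paths)
}
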