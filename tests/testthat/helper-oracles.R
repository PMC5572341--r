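# Independent brute-force oracles used to freeze expected values.

# Base-pair bitmap oracle for CNVR construction: paints each call's covered
# bases onto a per-base bitmap (one row per call) and connects calls that
# share at least one covered base, transitively via union-find. If two calls
# share any base they share the base at the later of their two starts, so
# inspecting the bitmap columns at call-start positions visits every
# connection.
bitmap_cnvrs <- function(calls) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (cc in unique(calls$chrom)) {
    idx <- which(calls$chrom == cc)
    maxend <- max(calls$end[idx])
    cover <- matrix(FALSE, length(idx), maxend)
    for (k in seq_along(idx)) {
      cover[k, calls$start[idx[k]]:calls$end[idx[k]]] <- TRUE
    }
    for (b in unique(calls$start[idx])) {
      v <- idx[cover[, b]]
      if (length(v) > 1L) for (k in 2:length(v)) union2(v[1L], v[k])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(seq_len(n), roots)
  out <- lapply(comps, function(r) {
    states <- calls$copy_state[r]
    list(
      chrom = calls$chrom[r[1L]],
      start = min(calls$start[r]),
      end = max(calls$end[r]),
      samples = sort(unique(calls$sample_id[r])),
      klass = if (all(states < 2L)) "loss"
              else if (all(states > 2L)) "gain" else "complex",
      rows = sort(r)
    )
  })
  ord <- order(
    vapply(out, `[[`, 1, "chrom"),
    vapply(out, `[[`, 1, "start"),
    vapply(out, `[[`, 1, "end")
  )
  out[ord]
}

# Random toy call set on small coordinates for oracle-equivalence checks.
random_toy_calls <- function(max_calls = 50L, max_coord = 10000L,
                             n_samples = 6L, n_chroms = 2L) {
  n <- sample.int(max_calls, 1L)
  start <- sample.int(max_coord - 10L, n, replace = TRUE)
  len <- sample.int(500L, n, replace = TRUE)
  data.frame(
    sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
    chrom = sample.int(n_chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + len, max_coord),
    copy_state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
    n_probes = sample(3:20, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Canonical string form of a component list, for bulk oracle comparisons:
# one sorted line per component covering span, supporters and class.
canonical_components <- function(comps) {
  sort(unname(vapply(comps, function(x) {
    paste(x$chrom, x$start, x$end, x$klass,
          paste(sort(x$samples), collapse = "+"))
  }, character(1))))
}

# build_cnvrs output (CNVRs plus singleton clusters) in the same canonical form
canonical_build <- function(res) {
  a <- character(0)
  if (nrow(res$cnvrs) > 0L) {
    a <- vapply(seq_len(nrow(res$cnvrs)), function(k) {
      paste(res$cnvrs$chrom[k], res$cnvrs$start[k], res$cnvrs$end[k],
            res$cnvrs$klass[k],
            paste(sort(res$cnvrs$samples[[k]]), collapse = "+"))
    }, character(1))
  }
  b <- character(0)
  if (nrow(res$singletons) > 0L) {
    b <- vapply(seq_len(nrow(res$singletons)), function(k) {
      paste(res$singletons$chrom[k], res$singletons$start[k],
            res$singletons$end[k], res$singletons$klass[k],
            res$singletons$sample_id[k])
    }, character(1))
  }
  sort(c(a, b))
}

# Set-enumeration Jaccard oracle
jaccard_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      vi <- which(m[i, ] == 1L)
      vj <- which(m[j, ] == 1L)
      u <- length(union(vi, vj))
      d[i, j] <- if (u == 0L) 0 else 1 - length(intersect(vi, vj)) / u
    }
  }
  d
}

# Direct variance-arithmetic V_st oracle for a single probe
vst_oracle_probe <- function(a, b) {
  popvar <- function(x) mean((x - mean(x))^2)
  vt <- popvar(c(a, b))
  vs <- (length(a) * popvar(a) + length(b) * popvar(b)) / (length(a) + length(b))
  if (vt == 0) 0 else (vt - vs) / vt
}

# Cophenetic distances implied by an upgma_tree (2 * LCA height per pair)
upgma_cophenetic <- function(tree) {
  labs <- tree$labels
  d <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  walk <- function(node) {
    if (!is.null(node$label)) return(invisible(NULL))
    for (l1 in node$left$members) {
      for (l2 in node$right$members) {
        d[l1, l2] <<- 2 * node$height
        d[l2, l1] <<- 2 * node$height
      }
    }
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  d
}
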