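#' Binary CNVR presence/absence matrix
#'
#' One row per sample, one column per CNVR; entry 1 iff the sample is in the
#' CNVR's supporting set. Every column sums to at least 2 because every CNVR
#' has at least two supporters by construction.
#'
#' @param cnvrs CNVR `data.frame` from [build_cnvrs()] (uses the `samples`
#'   list column).
#' @param samples Character vector of sample ids (matrix row order).
#' @return Integer matrix, samples x CNVRs.
#' @export
binary_cnvr_matrix <- function(cnvrs, samples) {
  m <- matrix(0L, nrow = length(samples), ncol = nrow(cnvrs),
              dimnames = list(samples, cnvrs$cnvr_id))
  for (k in seq_len(nrow(cnvrs))) {
    m[intersect(cnvrs$samples[[k]], samples), k] <- 1L
  }
  m
}

#' Jaccard distance matrix between samples
#'
#' `d(i, j) = 1 - |Vi intersect Vj| / |Vi union Vj|` over the samples' CNVR
#' presence sets. Two samples with no CNVRs at all have identical (empty)
#' profiles; their similarity is defined as 1, i.e. distance 0.
#'
#' @param m Binary matrix, samples x CNVRs (see [binary_cnvr_matrix()]).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jaccard_distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, all(m %in% c(0L, 1L)))
  m <- matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  inter <- m %*% t(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, "+") - inter
  d <- ifelse(uni == 0, 0, 1 - inter / uni)
  diag(d) <- 0
  d
}

#' UPGMA hierarchical clustering
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' join the closest pair of clusters; the distance from the merged cluster to
#' any other is the size-weighted average of its members' distances, and each
#' internal node sits at height = joining distance / 2, so the tree is
#' ultrametric. Ties are broken deterministically by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by its
#' smallest member id), making the result invariant to input ordering.
#'
#' @param d Symmetric distance matrix with zero diagonal and sample ids as
#'   dimnames.
#' @return An object of class `upgma_tree`: `newick` (string with branch
#'   lengths), `root` (nested node list with `height`, `members` and either
#'   `label` or `left`/`right`), `labels`.
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  labels <- rownames(d)
  if (length(labels) < 2L) stop("need at least 2 samples")

  nodes <- lapply(labels, function(l) list(label = l, height = 0, members = l))
  reps <- labels
  sizes <- rep(1L, length(labels))
  D <- d

  while (length(nodes) > 1L) {
    n <- length(nodes)
    # closest pair, ties by lexicographically smallest representative pair
    best <- NULL
    best_d <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- sort(c(reps[i], reps[j]))
        if (D[i, j] < best_d - 1e-12 ||
            (abs(D[i, j] - best_d) <= 1e-12 && !is.null(best) &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, key = key)
          best_d <- min(best_d, D[i, j])
        }
      }
    }
    i <- best$i
    j <- best$j
    h <- D[i, j] / 2
    kids <- list(nodes[[i]], nodes[[j]])
    ord <- order(c(reps[i], reps[j]))
    new_node <- list(
      left = kids[[ord[1L]]], right = kids[[ord[2L]]], height = h,
      members = sort(c(nodes[[i]]$members, nodes[[j]]$members))
    )
    # size-weighted average distance to every other cluster
    keep <- setdiff(seq_len(n), c(i, j))
    new_row <- (sizes[i] * D[i, keep] + sizes[j] * D[j, keep]) / (sizes[i] + sizes[j])
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, new_row), c(new_row, 0))
    nodes <- c(nodes[keep], list(new_node))
    reps <- c(reps[keep], min(new_node$members))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }

  root <- nodes[[1L]]
  structure(
    list(newick = paste0(node_newick(root, parent_height = NULL), ";"),
         root = root, labels = sort(labels)),
    class = "upgma_tree"
  )
}

node_newick <- function(node, parent_height) {
  fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
  body <- if (!is.null(node$label)) {
    node$label
  } else {
    paste0("(", node_newick(node$left, node$height), ",",
           node_newick(node$right, node$height), ")")
  }
  if (is.null(parent_height)) body
  else paste0(body, ":", fmt(parent_height - node$height))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$labels), "samples, height",
      format(x$root$height, digits = 6), "\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Leaf sets of the two clades under the root
#'
#' @param tree An `upgma_tree`.
#' @return List of two character vectors (sorted sample ids).
#' @export
root_bipartition <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  r <- tree$root
  if (!is.null(r$label)) stop("tree has a single leaf")
  list(r$left$members, r$right$members)
}

#' Write a tree in Newick format
#'
#' @param tree An `upgma_tree`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}
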