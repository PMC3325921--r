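#' Pairwise distance matrix between expression profiles
#'
#' Default metric is 1 minus the uncentered Pearson correlation (the classic
#' gene-expression clustering similarity: cosine of the angle between
#' profiles, which is sensitive to both shape and sign of the response, not
#' to overall magnitude). Euclidean distance is available as an alternative.
#'
#' @param profiles numeric matrix, rows = items to cluster (genes or
#'   conditions), columns = observations (typically log2 ratios).
#' @param metric `"uncentered"` (default) or `"euclidean"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(profiles, metric = c("uncentered", "euclidean")) {
  metric <- match.arg(metric)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(profiles, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(profiles^2))
    if (any(nrm == 0)) {
      bad <- rownames(profiles)[which(nrm == 0)[1L]]
      if (is.null(bad)) bad <- which(nrm == 0)[1L]
      stop("uncentered correlation undefined for all-zero profile '", bad, "'")
    }
    s <- tcrossprod(profiles / nrm)
    d <- 1 - s
    d[d < 0] <- 0  # clip numerical negatives
    diag(d) <- 0
    d <- (d + t(d)) / 2
    dimnames(d) <- list(rownames(profiles), rownames(profiles))
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted mean of all cross-pair distances. At each step the closest
#' pair of clusters is merged; exact ties are broken deterministically in
#' favour of the pair containing the smallest leaf index (then the smallest
#' second leaf index). Merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix (or `dist` object).
#' @return an object of class `hclust` (method `"average"`), usable with
#'   [stats::cutree()], [as_newick()], plotting, etc.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  labels <- rownames(d)
  D <- (d + t(d)) / 2

  # active cluster bookkeeping: id (hclust convention: -leaf or merge row),
  # size, smallest member leaf for tie-breaking
  id <- -seq_len(n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    best_d <- Inf
    for (ai in seq_along(act)[-length(act)]) {
      i <- act[ai]
      for (j in act[(ai + 1L):length(act)]) {
        dij <- D[i, j]
        lo <- min(minleaf[i], minleaf[j]); hi <- max(minleaf[i], minleaf[j])
        if (dij < best_d ||
            (dij == best_d && (lo < best[3L] || (lo == best[3L] && hi < best[4L])))) {
          best_d <- dij
          best <- c(i, j, lo, hi)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    a <- id[i]; b <- id[j]
    # hclust row convention: singletons (by leaf index) before clusters
    merge[step, ] <- if (a < 0L && b < 0L) {
      if (-a <= -b) c(a, b) else c(b, a)
    } else if (a < 0L) c(a, b) else if (b < 0L) c(b, a) else {
      if (a <= b) c(a, b) else c(b, a)
    }
    height[step] <- best_d
    # UPGMA update: size-weighted mean of cross-pair distances
    newd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- 0
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
  }

  order <- leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "precomputed"),
            class = "hclust")
}

# depth-first leaf order from an hclust merge matrix
leaf_order <- function(merge) {
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}

#' Cluster the top-ranked genes across conditions
#'
#' Builds the log2-ratio profile matrix of the top `n` ranked genes and
#' clusters both genes (rows) and conditions (columns) by average linkage.
#' Rows of the returned matrix are reordered to the gene dendrogram's leaf
#' order, columns to the condition dendrogram's leaf order, ready for
#' heatmap-style display.
#'
#' @param scores ranked score table from [score_genes()].
#' @param calls the called `call_matrix` holding the ratios.
#' @param n number of top-ranked genes (default 50; clamped with a warning
#'   when fewer genes were scored).
#' @param metric passed to [distance_matrix()].
#' @param ratio_floor ratios are floored here before log2 (guards zeros).
#' @return list with `gene_tree` and `condition_tree` (`hclust`) and
#'   `profiles` (the reordered log2-ratio matrix).
#' @export
cluster_top <- function(scores, calls, n = 50L,
                        metric = c("uncentered", "euclidean"),
                        ratio_floor = 1e-6) {
  metric <- match.arg(metric)
  if (n > nrow(scores)) {
    warning("only ", nrow(scores), " scored genes available; clamping n")
    n <- nrow(scores)
  }
  if (n < 2L) stop("need at least 2 genes to cluster")
  top <- scores$gene_id[seq_len(n)]
  profiles <- log2(pmax(calls$ratio[top, , drop = FALSE], ratio_floor))
  gene_tree <- average_linkage(distance_matrix(profiles, metric))
  condition_tree <- average_linkage(distance_matrix(t(profiles), metric))
  list(gene_tree = gene_tree, condition_tree = condition_tree,
       profiles = profiles[gene_tree$order, condition_tree$order, drop = FALSE])
}

#' Leaf labels of the two branches at a dendrogram's root
#'
#' @param tree an `hclust`.
#' @return list of two character vectors (or integer indices when the tree
#'   is unlabelled), the leaves under each child of the root.
#' @export
root_bipartition <- function(tree) {
  m <- tree$merge
  grab <- function(k) {
    idx <- if (k < 0L) -k else leaf_order_sub(m, k)
    if (is.null(tree$labels)) idx else tree$labels[idx]
  }
  root <- nrow(m)
  list(grab(m[root, 1L]), grab(m[root, 2L]))
}

leaf_order_sub <- function(merge, k) {
  if (k < 0L) return(-k)
  c(leaf_order_sub(merge, merge[k, 1L]), leaf_order_sub(merge, merge[k, 2L]))
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
as_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
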