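# Average-linkage clustering, dendrogram cuts and threshold estimators.
#
# The merge distance between clusters X and Y is the mean of all pairwise
# dataset distances across the two clusters (UPGMA). The agglomeration itself
# is delegated to stats::hclust(method = "average"); the resulting merge
# sequence is re-expressed with leaves 0..N-1 (input order) and internal nodes
# N, N+1, ... in merge order.

#' Average-linkage hierarchical clustering
#'
#' @param dm an `mx_distmat` (or a plain symmetric distance matrix with zero
#'   diagonal).
#' @return a `linkage_tree`: list with `merges` (data.frame left, right,
#'   height, size), `n_leaves`, `labels`.
#' @export
average_linkage <- function(dm) {
  if (inherits(dm, "mx_distmat")) {
    d <- dm$d; labels <- dm$labels
  } else {
    d <- as.matrix(dm)
    labels <- rownames(d)
    if (is.null(labels)) labels <- sprintf("ds%03d", seq_len(nrow(d)))
  }
  n <- nrow(d)
  if (n < 2) mx_validation_error("need at least 2 leaves to cluster")
  if (any(!is.finite(d))) mx_validation_error("distance matrix has non-finite entries")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    mx_validation_error("distance matrix must be symmetric with zero diagonal")
  h <- stats::hclust(stats::as.dist(d), method = "average")
  node <- function(v) ifelse(v < 0, -v - 1L, n - 1L + v)
  left <- node(h$merge[, 1])
  right <- node(h$merge[, 2])
  swap <- left > right
  tmp <- left[swap]; left[swap] <- right[swap]; right[swap] <- tmp
  size <- integer(n - 1)
  nodesize <- c(rep(1L, n), size)
  for (i in seq_len(n - 1)) {
    s <- nodesize[left[i] + 1L] + nodesize[right[i] + 1L]
    size[i] <- s
    nodesize[n + i] <- s
  }
  structure(list(merges = data.frame(left = as.integer(left),
                                     right = as.integer(right),
                                     height = h$height, size = size),
                 n_leaves = n, labels = labels),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("average-linkage tree: %d leaves, %d merges, heights %.3g..%.3g\n",
              x$n_leaves, nrow(x$merges), min(x$merges$height),
              max(x$merges$height)))
  invisible(x)
}

#' Plot a dendrogram with an optional threshold line
#' @param x a `linkage_tree`.
#' @param threshold optional height at which to draw the cut.
#' @param ... passed to `plot.hclust`.
#' @export
plot.linkage_tree <- function(x, threshold = NULL, ...) {
  n <- x$n_leaves
  back <- function(v) ifelse(v < n, -(v + 1L), v - n + 1L)
  h <- list(merge = cbind(back(x$merges$left), back(x$merges$right)),
            height = x$merges$height, labels = x$labels,
            method = "average", call = match.call(),
            order = seq_len(n))
  h$order <- stats::order.dendrogram(stats::as.dendrogram(structure(h, class = "hclust")))
  class(h) <- "hclust"
  plot(h, ylab = "linkage distance", xlab = "", sub = "", ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}

# member leaf indices (0-based) of every cluster after applying merges with
# height <= threshold
partition_members <- function(tree, threshold) {
  n <- tree$n_leaves
  m <- tree$merges
  members <- c(lapply(seq_len(n) - 1L, identity), vector("list", nrow(m)))
  consumed <- rep(FALSE, n + nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$height[i] <= threshold) {
      li <- m$left[i] + 1L; ri <- m$right[i] + 1L
      members[[n + i]] <- c(members[[li]], members[[ri]])
      consumed[c(li, ri)] <- TRUE
    }
  }
  alive <- which(!consumed & !vapply(members, is.null, logical(1)))
  lapply(alive, function(i) sort(members[[i]]))
}

#' Cut a linkage tree at a threshold
#'
#' `mode = "all"` returns the full partition induced by removing merges above
#' the threshold; `mode = "largest"` returns only the cluster with the most
#' members (ties resolved to the cluster containing the smallest leaf index).
#'
#' @param tree a `linkage_tree`.
#' @param threshold linkage height (inclusive).
#' @param mode `"largest"` (default) or `"all"`.
#' @return a `cluster_selection`: list with `threshold`, `mode`, `clusters`
#'   (list of member-label vectors) and `indices` (0-based leaf indices).
#' @export
cut_clusters <- function(tree, threshold, mode = c("largest", "all")) {
  mode <- match.arg(mode)
  if (threshold < 0) mx_validation_error("threshold must be >= 0")
  parts <- partition_members(tree, threshold)
  if (mode == "largest") {
    sizes <- lengths(parts)
    cand <- which(sizes == max(sizes))
    firstleaf <- vapply(parts[cand], min, numeric(1))
    parts <- parts[cand[which.min(firstleaf)]]
  } else {
    parts <- parts[order(vapply(parts, min, numeric(1)))]
  }
  structure(list(threshold = threshold, mode = mode,
                 clusters = lapply(parts, function(ix) tree$labels[ix + 1L]),
                 indices = parts),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("cut at %.4g (mode %s): %d cluster(s), sizes %s\n", x$threshold,
              x$mode, length(x$clusters),
              paste(lengths(x$clusters), collapse = " ")))
  invisible(x)
}

# largest-component size after each merge, plus the node realising it (ties
# resolved, as in cut_clusters, to the component containing the smallest leaf)
largest_by_merge <- function(tree) {
  n <- tree$n_leaves
  m <- tree$merges
  minleaf <- c(seq_len(n) - 1L, integer(nrow(m)))
  for (i in seq_len(nrow(m)))
    minleaf[n + i] <- min(minleaf[m$left[i] + 1L], minleaf[m$right[i] + 1L])
  best_size <- integer(nrow(m)); best_node <- integer(nrow(m))
  cur_size <- 1L; cur_node <- 0L; cur_min <- 0L
  for (i in seq_len(nrow(m))) {
    s <- m$size[i]; nd <- n + i - 1L
    if (s > cur_size || (s == cur_size && minleaf[nd + 1L] < cur_min)) {
      cur_size <- s; cur_node <- nd; cur_min <- minleaf[nd + 1L]
    }
    best_size[i] <- cur_size; best_node[i] <- cur_node
  }
  list(size = best_size, node = best_node)
}

#' Threshold estimate from largest-cluster growth
#'
#' Fast heuristic: evaluates the size of the largest cluster at every distinct
#' merge height (ascending) and locates the height at which the size increase
#' over the previous height is maximal (earliest such height on ties). The
#' returned threshold is the merge height just below that jump, i.e. the
#' largest cut at which the dominant cluster has assembled but the maximal
#' accretion - typically the merge that would join a distinct isomorphism
#' class - has not yet been applied. When the maximal jump is the very first
#' merge, that first height is returned.
#'
#' @param tree a `linkage_tree`.
#' @return estimated threshold (a merge height).
#' @export
threshold_by_growth <- function(tree) {
  m <- tree$merges
  lb <- largest_by_merge(tree)
  hs <- unique(m$height)
  # size of the largest cluster after all merges at each distinct height
  size_at <- vapply(hs, function(h) lb$size[max(which(m$height <= h))], integer(1))
  inc <- diff(c(1L, size_at))
  k <- which.max(inc)
  if (k == 1) hs[1] else hs[k - 1]
}

#' Minimal threshold reaching a completeness target
#'
#' Scans merge heights in ascending order; at each height pools the unique
#' asymmetric-unit reflections of the largest cluster and computes the
#' completeness against the theoretical unique count at `d_min`. Returns the
#' smallest height whose largest cluster is at least `target` complete; if the
#' target is never reached the maximal height is returned with a warning.
#'
#' @param tree a `linkage_tree` built over `datasets`.
#' @param datasets list of `partial_dataset` objects, in leaf order.
#' @param target completeness fraction, default 0.98.
#' @param anomalous logical; count Friedel mates separately.
#' @param d_min resolution limit for the completeness calculation; defaults to
#'   the best resolution observed across all datasets.
#' @return the estimated threshold, with attribute `completeness` (the value
#'   achieved there).
#' @export
threshold_by_completeness <- function(tree, datasets, target = 0.98,
                                      anomalous = FALSE, d_min = NULL) {
  n <- tree$n_leaves
  if (length(datasets) != n)
    mx_validation_error("tree has %d leaves but %d datasets given", n,
                        length(datasets))
  if (is.null(d_min)) {
    d_min <- min(vapply(datasets, function(ds)
      min(d_spacing(ds$observations$h, ds$observations$k, ds$observations$l,
                    ds$cell)), numeric(1)))
  }
  keysets <- lapply(datasets, function(ds) {
    merge_within_dataset(ds, anomalous = anomalous, d_min = d_min)$key
  })
  cell <- mean_cell(datasets)
  n_theor <- count_unique(cell, datasets[[1]]$spacegroup, d_min, anomalous)

  # per-node pooled unique-key counts, built bottom-up
  m <- tree$merges
  nodekeys <- c(keysets, vector("list", nrow(m)))
  nodecount <- c(vapply(keysets, function(k) length(unique(k)), integer(1)),
                 integer(nrow(m)))
  for (i in seq_len(nrow(m))) {
    u <- unique(c(nodekeys[[m$left[i] + 1L]], nodekeys[[m$right[i] + 1L]]))
    nodekeys[[n + i]] <- u
    nodecount[n + i] <- length(u)
  }
  lb <- largest_by_merge(tree)

  comp0 <- max(nodecount[seq_len(n)]) / n_theor
  if (comp0 >= target) return(structure(0, completeness = comp0))
  hs <- unique(m$height)
  for (h in hs) {
    i <- max(which(m$height <= h))
    comp <- nodecount[lb$node[i] + 1L] / n_theor
    if (comp >= target) return(structure(h, completeness = comp))
  }
  warning(sprintf("completeness target %.3g never reached (best %.3g); returning maximal height",
                  target, nodecount[lb$node[nrow(m)] + 1L] / n_theor))
  structure(max(m$height),
            completeness = nodecount[lb$node[nrow(m)] + 1L] / n_theor)
}

# component-wise mean of member cells: merged statistics need one nominal cell
mean_cell <- function(datasets) {
  p <- rowMeans(vapply(datasets, function(d) cell_as_numeric(d$cell),
                       numeric(6)))
  crystal_cell(p[1], p[2], p[3], p[4], p[5], p[6])
}
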