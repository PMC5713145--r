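# Non-isomorphism distances between partial datasets.
#
# Default metric: d = sqrt(1 - cc^2), with cc the Pearson correlation of the
# common reflection intensities of a pair of datasets. Pairs whose unit cells
# differ by more than 1% in any parameter are assigned d = 1 (null
# correlation) before any correlation is attempted, which isolates outlier
# crystals. The alternative metric is the maximal variation of a cell edge.

# collapse one wedge to one inverse-variance-weighted intensity per ASU key,
# sorted by key (deterministic pairing order)
merge_within_dataset <- function(ds, anomalous = FALSE, d_min = NULL) {
  o <- ds$observations
  if (!is.null(d_min)) {
    d <- d_spacing(o$h, o$k, o$l, ds$cell)
    o <- o[d >= d_min, , drop = FALSE]
  }
  if (nrow(o) == 0)
    return(data.frame(key = numeric(0), i = numeric(0), sig = numeric(0)))
  r <- asu_reduce(cbind(o$h, o$k, o$l), ds$spacegroup, anomalous)
  key <- encode_hkl(r$hkl)
  if (anomalous) key <- key * 2 + (r$friedel == "minus")
  w <- 1 / o$sigma^2
  dt <- data.table::as.data.table(list(key = key, wi = w * o$intensity, w = w))
  m <- dt[, .(i = sum(wi) / sum(w), sig = sqrt(1 / sum(w))), by = key]
  data.table::setorder(m, key)
  data.frame(key = m$key, i = m$i, sig = m$sig)
}

#' Common reflection intensities of a dataset pair
#'
#' Each dataset is first collapsed to one intensity per asymmetric-unit key
#' (inverse-variance weighted mean over repeated in-wedge observations); the
#' result pairs the intersection of the two key sets, sorted by key.
#'
#' @param ds_a,ds_b `partial_dataset` objects.
#' @param anomalous logical; keep Friedel mates separate when matching keys.
#' @return data.frame with columns `i_a`, `i_b` (one row per shared unique
#'   reflection).
#' @export
common_pairs <- function(ds_a, ds_b, anomalous = FALSE) {
  ma <- merge_within_dataset(ds_a, anomalous)
  mb <- merge_within_dataset(ds_b, anomalous)
  idx <- match(ma$key, mb$key)
  sel <- !is.na(idx)
  data.frame(i_a = ma$i[sel], i_b = mb$i[idx[sel]])
}

#' Pearson correlation of paired intensities
#'
#' @param pairs data.frame as returned by [common_pairs()] (or any two-column
#'   numeric frame).
#' @param n_min minimum number of pairs for a defined correlation (default 3);
#'   below it, or with zero variance in either vector, the correlation is
#'   undefined and `NA` is returned (mapped to distance 1 downstream).
#' @return correlation in [-1, 1], with attribute `n` = number of pairs, or
#'   `NA` when undefined.
#' @export
intensity_correlation <- function(pairs, n_min = 3) {
  n <- nrow(pairs)
  if (n < n_min) return(structure(NA_real_, n = n))
  va <- stats::var(pairs[[1]]); vb <- stats::var(pairs[[2]])
  if (!is.finite(va) || !is.finite(vb) || va == 0 || vb == 0)
    return(structure(NA_real_, n = n))
  structure(stats::cor(pairs[[1]], pairs[[2]]), n = n)
}

#' Convert a correlation coefficient to a non-isomorphism distance
#'
#' d = sqrt(1 - cc^2) for cc > 0. Undefined or non-positive correlations map
#' to the maximal distance 1 (an anticorrelated pair is maximally
#' non-isomorphous; 1 is also the sentinel used for incompatible cells).
#'
#' @param cc numeric vector of correlations (NA allowed).
#' @return distances in [0, 1].
#' @examples
#' cc_to_distance(c(1, 0.9165, NA)) # 0, ~0.40, 1
#' @export
cc_to_distance <- function(cc) {
  ifelse(is.na(cc) | cc <= 0, 1, sqrt(pmax(0, 1 - pmin(cc, 1)^2)))
}

#' Correlation implied by a linkage distance
#'
#' Inverse of [cc_to_distance()] on its informative branch: cc = sqrt(1 -
#' d^2). A dendrogram cut at height d therefore selects clusters whose member
#' pairs correlate, on average, at least this strongly.
#'
#' @param d distances in [0, 1].
#' @return correlations in [0, 1].
#' @examples
#' 100 * distance_to_cc(0.4) # ~91.65 percent
#' @export
distance_to_cc <- function(d) {
  if (any(d < 0 | d > 1)) mx_validation_error("distances must lie in [0, 1]")
  sqrt(pmax(0, 1 - d^2))
}

#' Unit-cell variation distance
#'
#' Maximal absolute difference of the cell edge lengths a, b, c (Angstrom).
#'
#' @param cell_a,cell_b unit cells.
#' @return distance in Angstrom.
#' @export
cell_distance <- function(cell_a, cell_b) {
  pa <- as_crystal_cell(cell_a); pb <- as_crystal_cell(cell_b)
  max(abs(pa$a - pb$a), abs(pa$b - pb$b), abs(pa$c - pb$c))
}

#' Pairwise non-isomorphism distance matrix
#'
#' Builds the symmetric distance matrix over all dataset pairs. Under the
#' default correlation metric, a pair first passes the unit-cell compatibility
#' gate ([cells_compatible()], 1% default); incompatible pairs get distance 1
#' without a correlation being attempted. Otherwise the distance is
#' `cc_to_distance(intensity_correlation(common_pairs(a, b)))`. Under the
#' `cell` metric the distance is [cell_distance()] for every pair.
#'
#' @param datasets list of `partial_dataset` objects (all sharing one space
#'   group when `metric = "cc"`).
#' @param metric `"cc"` (default) or `"cell"`.
#' @param anomalous logical; match Friedel-separated keys (default FALSE).
#' @param n_min minimum common reflections for a defined correlation.
#' @param d_min optional resolution prefilter (Angstrom): only observations
#'   with d >= d_min enter the correlation.
#' @param cell_tol relative tolerance of the compatibility gate.
#' @return an `mx_distmat`: list with `labels`, `d` (symmetric matrix),
#'   `n_common` (common-reflection counts, cc metric), `metric`.
#' @export
build_distance_matrix <- function(datasets, metric = c("cc", "cell"),
                                  anomalous = FALSE, n_min = 3, d_min = NULL,
                                  cell_tol = 0.01) {
  metric <- match.arg(metric)
  n <- length(datasets)
  if (n < 2) mx_validation_error("need at least 2 datasets")
  labels <- vapply(datasets, `[[`, character(1), "id")
  d <- matrix(0, n, n)
  n_common <- matrix(NA_integer_, n, n)
  if (metric == "cell") {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- cell_distance(datasets[[i]]$cell, datasets[[j]]$cell)
    }
  } else {
    sgs <- vapply(datasets, function(x) x$spacegroup$number, integer(1))
    if (length(unique(sgs)) > 1)
      mx_validation_error("mixed space groups under the cc metric: %s",
                          paste(sprintf("%s (#%d)", labels, sgs)[sgs != sgs[1]],
                                collapse = ", "))
    merged <- lapply(datasets, merge_within_dataset, anomalous = anomalous,
                     d_min = d_min)
    diag(n_common) <- vapply(merged, nrow, integer(1))
    cells <- lapply(datasets, function(x) cell_as_numeric(x$cell))
    for (i in seq_len(n - 1)) {
      ki <- merged[[i]]$key; ii <- merged[[i]]$i
      for (j in (i + 1):n) {
        idx <- match(ki, merged[[j]]$key)
        sel <- which(!is.na(idx))
        m <- length(sel)
        n_common[i, j] <- n_common[j, i] <- m
        pa <- cells[[i]]; pb <- cells[[j]]
        if (any(abs(pa - pb) / ((pa + pb) / 2) > cell_tol)) {
          d[i, j] <- d[j, i] <- 1
          next
        }
        # inline Pearson cc (same contract as intensity_correlation)
        dij <- 1
        if (m >= n_min) {
          xa <- ii[sel]; xb <- merged[[j]]$i[idx[sel]]
          xa <- xa - sum(xa) / m; xb <- xb - sum(xb) / m
          va <- sum(xa * xa); vb <- sum(xb * xb)
          if (va > 0 && vb > 0) {
            cc <- sum(xa * xb) / sqrt(va * vb)
            if (cc > 0) dij <- sqrt(max(0, 1 - min(cc, 1)^2))
          }
        }
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  structure(list(labels = labels, d = d, n_common = n_common, metric = metric),
            class = "mx_distmat")
}

#' @export
print.mx_distmat <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("%s-metric distance matrix over %d datasets (off-diagonal range %.3g..%.3g)\n",
              x$metric, length(x$labels), min(off), max(off)))
  invisible(x)
}
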