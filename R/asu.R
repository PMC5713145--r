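# Asymmetric-unit reduction and unique-reflection enumeration.
#
# The canonical representative of a symmetry orbit is the lexicographically
# greatest (h, k, l) over all rotational equivalents (and Friedel mates when
# Friedel's law is assumed). This choice is library independent and makes
# reduction trivially idempotent.

.mx_cache <- new.env(parent = emptyenv())

.KEY_BASE <- 1025L
.KEY_HALF <- 512L

# encode integer Miller triples as a single double for fast set operations;
# valid for |index| <= 511
encode_hkl <- function(hkl) {
  if (max(abs(hkl)) > .KEY_HALF - 1)
    mx_validation_error("Miller index magnitude exceeds %d", .KEY_HALF - 1)
  ((hkl[, 1] + .KEY_HALF) * .KEY_BASE + (hkl[, 2] + .KEY_HALF)) * .KEY_BASE +
    (hkl[, 3] + .KEY_HALF)
}

lex_greater <- function(a, b) {
  a[, 1] > b[, 1] |
    (a[, 1] == b[, 1] & (a[, 2] > b[, 2] |
                           (a[, 2] == b[, 2] & a[, 3] > b[, 3])))
}

# lexicographic max over the rotational orbit of each row of hkl
orbit_max <- function(hkl, sg, negate = FALSE) {
  s <- if (negate) -1 else 1
  best <- s * hkl %*% sg$rot[[1]]
  for (op in sg$rot[-1]) {
    cand <- s * hkl %*% op
    upd <- lex_greater(cand, best)
    if (any(upd)) best[upd, ] <- cand[upd, , drop = FALSE]
  }
  best
}

# matrix form of the reduction; returns representative indices plus the
# Friedel parity (and centric flag) of each input reflection
asu_reduce <- function(hkl, sg, anomalous = FALSE) {
  sg <- space_group(sg)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  if (any(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0))
    mx_validation_error("(0,0,0) is not a valid reflection")
  kp <- orbit_max(hkl, sg)
  km <- orbit_max(hkl, sg, negate = TRUE)
  centric <- kp[, 1] == km[, 1] & kp[, 2] == km[, 2] & kp[, 3] == km[, 3]
  merged <- kp
  lower <- lex_greater(km, kp)
  if (any(lower)) merged[lower, ] <- km[lower, , drop = FALSE]
  friedel <- rep("merged", nrow(hkl))
  if (anomalous) friedel <- ifelse(centric | !lower, "plus", "minus")
  list(hkl = merged, friedel = friedel, centric = centric)
}

#' Reduce Miller indices to the asymmetric unit
#'
#' Maps reflections to a canonical asymmetric-unit representative (the
#' lexicographically greatest orbit member). With `anomalous = FALSE`
#' (Friedel's law true) the mates (h,k,l) and (-h,-k,-l) collapse to one key;
#' with `anomalous = TRUE` the representative indices are the same but each
#' reflection additionally carries its Friedel parity (`"plus"`/`"minus"`;
#' centric reflections are always `"plus"`).
#'
#' @param h,k,l integer Miller indices (vectorised).
#' @param sg a `space_group` or an International Tables number.
#' @param anomalous logical; keep Friedel parity separate?
#' @return data.frame with columns `h`, `k`, `l`, `friedel`, `centric`.
#' @examples
#' reduce_to_asu(1, 2, 3, space_group(1))
#' @export
reduce_to_asu <- function(h, k, l, sg, anomalous = FALSE) {
  r <- asu_reduce(cbind(h, k, l), sg, anomalous)
  data.frame(h = as.integer(r$hkl[, 1]), k = as.integer(r$hkl[, 2]),
             l = as.integer(r$hkl[, 3]), friedel = r$friedel,
             centric = r$centric, stringsAsFactors = FALSE)
}

# systematic absence: h fixed by a rotation whose intrinsic translation gives
# a non-integral phase shift h.t
is_absent <- function(hkl, sg) {
  sg <- space_group(sg)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  absent <- rep(FALSE, nrow(hkl))
  for (i in seq_along(sg$rot)) {
    t <- sg$trans[[i]]
    if (all(t == 0)) next
    hr <- hkl %*% sg$rot[[i]]
    fixed <- hr[, 1] == hkl[, 1] & hr[, 2] == hkl[, 2] & hr[, 3] == hkl[, 3]
    phase <- (hkl %*% t) %% 1
    absent <- absent | (fixed & abs(phase) > 1e-9 & abs(phase - 1) > 1e-9)
  }
  absent
}

# Enumerate all theoretically observable unique reflections to d_min.
# Cached per (cell, sg, d_min, anomalous) since enumeration over the full
# index grid is the expensive step shared by completeness and shell logic.
enumerate_unique <- function(cell, sg, d_min, anomalous = FALSE) {
  cell <- as_crystal_cell(cell)
  sg <- space_group(sg)
  if (!is.finite(d_min) || d_min <= 0)
    mx_validation_error("d_min must be positive")
  key <- paste(c(sprintf("%.6g", cell_as_numeric(cell)), sg$number,
                 sprintf("%.6g", d_min), anomalous), collapse = "|")
  hit <- .mx_cache[[key]]
  if (!is.null(hit)) return(hit)

  lim <- floor(c(cell$a, cell$b, cell$c) / d_min) + 2L
  grid <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                                l = -lim[3]:lim[3]))
  grid <- grid[!(grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] == 0), ,
               drop = FALSE]
  g <- reciprocal_metric(cell)
  d <- 1 / sqrt(rowSums((grid %*% g) * grid))
  keep <- d >= d_min
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  keep <- !is_absent(grid, sg)
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  r <- asu_reduce(grid, sg, anomalous)
  code <- encode_hkl(r$hkl)
  if (anomalous) code <- code * 2 + (r$friedel == "minus")
  first <- !duplicated(code)
  out <- data.frame(h = as.integer(r$hkl[first, 1]),
                    k = as.integer(r$hkl[first, 2]),
                    l = as.integer(r$hkl[first, 3]),
                    friedel = r$friedel[first],
                    centric = r$centric[first],
                    d = d[first])
  .mx_cache[[key]] <- out
  out
}

#' Count theoretically observable unique reflections
#'
#' Number of distinct asymmetric-unit reflections with d-spacing at least
#' `d_min`, excluding (0,0,0) and systematic absences. With
#' `anomalous = TRUE` acentric Friedel mates are counted separately.
#'
#' @param cell a `crystal_cell`.
#' @param sg a `space_group` or IT number.
#' @param d_min high-resolution cutoff in Angstrom.
#' @param anomalous logical; Friedel mates distinct?
#' @return integer count.
#' @export
count_unique <- function(cell, sg, d_min, anomalous = FALSE) {
  nrow(enumerate_unique(cell, sg, d_min, anomalous))
}
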