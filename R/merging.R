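# Pooling, intensity merging and data-quality statistics.
#
# Merging is an inverse-variance weighted mean per asymmetric-unit key
# (Friedel-separated when the anomalous flag is on). No inter-dataset scaling
# is applied by default; an optional median-ratio scale to a running reference
# is available for inputs not already on a common scale.

#' Pool the observations of selected datasets
#'
#' Concatenates every observation of every member, tagged with its source
#' dataset and its asymmetric-unit key.
#'
#' @param members character vector of dataset ids (must be distinct), or a
#'   `cluster_selection` whose first cluster is used.
#' @param datasets named list of `partial_dataset` objects.
#' @param anomalous logical; Friedel's law false (keys keep parity)?
#' @param scale logical; apply a per-dataset median-ratio scale to the pooled
#'   running reference (default FALSE: data assumed on a common scale).
#' @return an `mx_pool` data.frame (one row per observation) with columns
#'   `dataset`, `h`, `k`, `l`, `friedel`, `centric`, `key`, `intensity`,
#'   `sigma`; attributes `cell` (mean member cell), `sg`, `anomalous`.
#' @export
pool_observations <- function(members, datasets, anomalous = FALSE,
                              scale = FALSE) {
  if (inherits(members, "cluster_selection")) members <- members$clusters[[1]]
  if (anyDuplicated(members))
    mx_validation_error("duplicate member id '%s'", members[duplicated(members)][1])
  missing <- setdiff(members, names(datasets))
  if (length(missing))
    mx_validation_error("member id not found: %s", paste(missing, collapse = ", "))
  sel <- datasets[members]
  sgn <- unique(vapply(sel, function(d) d$spacegroup$number, integer(1)))
  if (length(sgn) > 1)
    mx_validation_error("members span multiple space groups: %s",
                        paste(sgn, collapse = ", "))
  parts <- lapply(sel, function(ds) {
    o <- ds$observations
    r <- asu_reduce(cbind(o$h, o$k, o$l), ds$spacegroup, anomalous = TRUE)
    key <- encode_hkl(r$hkl)
    if (anomalous) key <- key * 2 + (r$friedel == "minus")
    data.table::as.data.table(list(
      dataset = rep(ds$id, nrow(o)),
      h = as.integer(r$hkl[, 1]), k = as.integer(r$hkl[, 2]),
      l = as.integer(r$hkl[, 3]), friedel = r$friedel,
      centric = r$centric, key = key,
      intensity = o$intensity, sigma = o$sigma))
  })
  pool <- data.table::rbindlist(parts)
  if (scale && length(sel) > 1) {
    # median ratio of each dataset to the mean of the others, per common key
    ref <- pool[, .(iref = stats::median(intensity)), by = key]
    for (id in members) {
      rows <- pool$dataset == id
      m <- ref$iref[match(pool$key[rows], ref$key)]
      ratio <- stats::median(m / pool$intensity[rows], na.rm = TRUE)
      if (is.finite(ratio) && ratio > 0) {
        pool$intensity[rows] <- pool$intensity[rows] * ratio
        pool$sigma[rows] <- pool$sigma[rows] * ratio
      }
    }
  }
  data.table::setorder(pool, key)
  structure(pool, class = c("mx_pool", class(pool)),
            cell = mean_cell(sel), sg = sel[[1]]$spacegroup,
            anomalous = anomalous)
}

#' Merge pooled observations per unique reflection
#'
#' Per asymmetric-unit key (Friedel-separated when anomalous): merged
#' intensity is the inverse-variance weighted mean sum(I/sigma^2) /
#' sum(1/sigma^2); merged sigma is sqrt(1 / sum(1/sigma^2)); multiplicity is
#' the observation count. With `anomalous = TRUE` each output row is one base
#' (h,k,l) and additionally carries the Friedel-separated merges (`i_plus`,
#' `sigma_plus`, `n_plus`, `i_minus`, ...), with `i_mean` the Friedel-combined
#' value.
#'
#' @param pool an `mx_pool` from [pool_observations()].
#' @param anomalous logical; default taken from the pool.
#' @return a `merged_reflections` data.frame, sorted by key, with attributes
#'   `cell`, `sg`, `anomalous`.
#' @export
merge_intensities <- function(pool, anomalous = attr(pool, "anomalous")) {
  if (nrow(pool) == 0) mx_validation_error("empty observation pool")
  dt <- data.table::copy(data.table::as.data.table(pool))
  dt[, `:=`(w = 1 / sigma^2, basekey = encode_hkl(cbind(h, k, l)))]
  base <- dt[, .(h = h[1], k = k[1], l = l[1], centric = centric[1],
                 i_mean = sum(w * intensity) / sum(w),
                 sigma = sqrt(1 / sum(w)),
                 multiplicity = .N), by = basekey]
  data.table::setorder(base, basekey)
  out <- as.data.frame(base[, !"basekey"])
  if (anomalous) {
    side <- dt[, .(i = sum(w * intensity) / sum(w), s = sqrt(1 / sum(w)),
                   n = .N), by = .(basekey, friedel)]
    plus <- side[side$friedel == "plus", ]
    minus <- side[side$friedel == "minus", ]
    ip <- match(base$basekey, plus$basekey)
    im <- match(base$basekey, minus$basekey)
    out$i_plus <- plus$i[ip]; out$sigma_plus <- plus$s[ip]
    out$n_plus <- ifelse(is.na(ip), 0L, plus$n[ip])
    out$i_minus <- minus$i[im]; out$sigma_minus <- minus$s[im]
    out$n_minus <- ifelse(is.na(im), 0L, minus$n[im])
  }
  structure(out, class = c("merged_reflections", "data.frame"),
            cell = attr(pool, "cell"), sg = attr(pool, "sg"),
            anomalous = anomalous)
}

#' Agreement R factors of a pooled cluster
#'
#' Computed over reflections observed at least twice (singletons enter
#' neither numerator nor denominator), with the unweighted group mean as the
#' reference: Rmerge = sum |I_i - <I>| / sum I_i; Rmeas multiplies each
#' group's numerator contribution by sqrt(n/(n-1)) (multiplicity-corrected);
#' Rpim by sqrt(1/(n-1)) (precision of the merged value).
#'
#' @param pool an `mx_pool`.
#' @return named list `r_merge`, `r_meas`, `r_pim` (each `NA` when no
#'   reflection has multiplicity >= 2), plus `n_groups` used.
#' @export
r_factors <- function(pool) {
  dt <- data.table::as.data.table(pool)
  g <- dt[, .(n = .N, num = sum(abs(intensity - mean(intensity))),
              den = sum(intensity)), by = key]
  g <- g[g$n >= 2, ]
  if (nrow(g) == 0)
    return(list(r_merge = NA_real_, r_meas = NA_real_, r_pim = NA_real_,
                n_groups = 0L))
  den <- sum(g$den)
  list(r_merge = sum(g$num) / den,
       r_meas = sum(g$num * sqrt(g$n / (g$n - 1))) / den,
       r_pim = sum(g$num * sqrt(1 / (g$n - 1))) / den,
       n_groups = nrow(g))
}

#' Half-set correlation CC1/2
#'
#' The observations of each unique reflection (multiplicity >= 2) are randomly
#' split into two halves; the per-reflection half means are correlated across
#' reflections. For odd multiplicities the extra observation is assigned to
#' the two halves alternately (in key order). The split is deterministic under
#' `seed`; the caller's RNG state is untouched.
#'
#' @param pool an `mx_pool`.
#' @param seed integer seed for the random split.
#' @return the half-set correlation (attribute `n` = reflections used), or
#'   `NA` when fewer than 2 reflections have multiplicity >= 2.
#' @export
cc_half <- function(pool, seed = 1) {
  dt <- data.table::as.data.table(pool)[, list(key, intensity)]
  dt[, n := .N, by = key]
  dt <- dt[dt$n >= 2, ]
  if (nrow(dt) == 0 || length(unique(dt$key)) < 2)
    return(structure(NA_real_, n = length(unique(dt$key))))
  data.table::setorder(dt, key)
  with_seed(seed, {
    dt[, u := stats::runif(.N)]
    data.table::setorder(dt, key, u) # random permutation within each group
    dt[, rnk := data.table::rowid(key)]
    # alternate which half receives the odd observation
    gi <- dt[, .(n = n[1]), by = key]
    gi[, oddidx := cumsum(n %% 2L == 1L)]
    gi[, k1 := n %/% 2L + (n %% 2L) * (oddidx %% 2L)]
    dt[, half1 := rnk <= gi$k1[match(key, gi$key)]]
    agg <- dt[, .(m = mean(intensity)), by = .(key, half1)]
    data.table::setorder(agg, key)
    m1 <- agg$m[agg$half1]; m2 <- agg$m[!agg$half1]
    structure(stats::cor(m1, m2), n = length(m1))
  })
}

#' Mean anomalous signal (sigAno)
#'
#' Mean over reflections with both Friedel mates measured of
#' |I+ - I-| / sqrt(sigma+^2 + sigma-^2). Computed on intensities. Under a
#' null anomalous signal this statistic concentrates near the half-normal
#' mean sqrt(2/pi) ~ 0.798.
#'
#' @param merged a `merged_reflections` produced with the anomalous flag on.
#' @return mean anomalous signal (attribute `n` = Bijvoet pairs used), or `NA`
#'   when no reflection has both mates.
#' @export
sig_ano <- function(merged) {
  if (!isTRUE(attr(merged, "anomalous")) || is.null(merged$i_plus))
    mx_validation_error("sig_ano requires Friedel-separated merged data")
  centric <- merged$centric
  if (is.null(centric))
    centric <- asu_reduce(cbind(merged$h, merged$k, merged$l),
                          attr(merged, "sg"))$centric
  ok <- merged$n_plus >= 1 & merged$n_minus >= 1 & !centric
  if (!any(ok)) return(structure(NA_real_, n = 0L))
  v <- abs(merged$i_plus[ok] - merged$i_minus[ok]) /
    sqrt(merged$sigma_plus[ok]^2 + merged$sigma_minus[ok]^2)
  structure(mean(v), n = sum(ok))
}

# equal-volume shell edges in 1/d^3 between d_max and d_min (descending d)
shell_edges <- function(d_max, d_min, n_shells) {
  s3 <- seq(1 / d_max^3, 1 / d_min^3, length.out = n_shells + 1)
  (1 / s3)^(1 / 3)
}

shell_index <- function(d, edges) {
  i <- findInterval(-d, -edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Merging statistics, overall and per resolution shell
#'
#' Computes, for the pooled observations of a cluster, the statistics block
#' customarily reported for a merged dataset: completeness, multiplicity,
#' CC1/2, Rmerge/Rmeas/Rpim, mean I/sigma(I) and (for anomalous data) sigAno,
#' overall and in `n_shells` shells of equal reciprocal volume between the
#' observed low-resolution limit and `d_min`.
#'
#' @param pool an `mx_pool`.
#' @param d_min high-resolution cutoff; default: best resolution observed.
#' @param n_shells number of resolution shells (default 10).
#' @param anomalous logical; default taken from the pool.
#' @param seed seed for the CC1/2 half-set split.
#' @return a `merge_stats` object: list with `overall` (one-row data.frame),
#'   `shells` (per-shell data.frame with edges), `d_min`, `d_max`, `anomalous`,
#'   `seed`.
#' @export
merge_statistics <- function(pool, d_min = NULL, n_shells = 10,
                             anomalous = attr(pool, "anomalous"), seed = 1) {
  cell <- attr(pool, "cell"); sg <- attr(pool, "sg")
  dt <- data.table::as.data.table(pool)
  dobs <- d_spacing(dt$h, dt$k, dt$l, cell)
  if (is.null(d_min)) d_min <- min(dobs)
  keep <- dobs >= d_min
  dt <- dt[keep, ]; dobs <- dobs[keep]
  d_max <- max(dobs)
  merged <- merge_intensities(
    structure(dt, class = class(pool), cell = cell, sg = sg,
              anomalous = anomalous), anomalous)
  dmerged <- d_spacing(merged$h, merged$k, merged$l, cell)

  theor <- enumerate_unique(cell, sg, d_min, anomalous = FALSE)
  theor <- theor[theor$d <= d_max + 1e-9, ]
  edges <- shell_edges(d_max + 1e-9, d_min, n_shells)

  sh_obs <- shell_index(dobs, edges)
  sh_mrg <- shell_index(dmerged, edges)
  sh_th <- shell_index(theor$d, edges)

  one_block <- function(obs_rows, mrg_rows, n_theor, shseed) {
    sub <- dt[obs_rows, ]
    msub <- merged[mrg_rows, , drop = FALSE]
    rf <- r_factors(sub)
    cch <- cc_half(sub, seed = shseed)
    res <- data.frame(
      n_total = nrow(sub),
      n_unique = nrow(msub),
      completeness = nrow(msub) / n_theor,
      multiplicity = nrow(sub) / max(1L, nrow(msub)),
      cc_half = as.numeric(cch),
      r_merge = rf$r_merge, r_meas = rf$r_meas, r_pim = rf$r_pim,
      i_over_sigma = mean(msub$i_mean / msub$sigma),
      sig_ano = NA_real_)
    if (anomalous) res$sig_ano <- as.numeric(sig_ano(msub))
    res
  }

  # completeness is counted on Friedel-merged unique reflections so that the
  # anomalous flag does not change the denominator convention
  base_mrg <- merge_intensities(
    structure(dt, class = class(pool), cell = cell, sg = sg,
              anomalous = FALSE), FALSE)
  dbase <- d_spacing(base_mrg$h, base_mrg$k, base_mrg$l, cell)
  sh_base <- shell_index(dbase, edges)

  shells <- do.call(rbind, lapply(seq_len(n_shells), function(s) {
    blk <- one_block(sh_obs == s, sh_mrg == s, sum(sh_th == s), seed + s)
    blk$n_unique <- sum(sh_base == s)
    blk$completeness <- min(1, blk$n_unique / sum(sh_th == s))
    blk$multiplicity <- blk$n_total / max(1L, blk$n_unique)
    cbind(data.frame(shell = s, d_high = edges[s + 1], d_low = edges[s]), blk)
  }))
  overall <- one_block(rep(TRUE, nrow(dt)), rep(TRUE, nrow(merged)),
                       nrow(theor), seed)
  overall$n_unique <- nrow(base_mrg)
  overall$completeness <- min(1, overall$n_unique / nrow(theor))
  overall$multiplicity <- overall$n_total / overall$n_unique
  structure(list(overall = overall, shells = shells, d_min = d_min,
                 d_max = d_max, n_shells = n_shells, anomalous = anomalous,
                 seed = seed),
            class = "merge_stats")
}

stats_as_list <- function(st) {
  list(overall = as.list(st$overall), shells = st$shells,
       d_min = st$d_min, d_max = st$d_max, anomalous = st$anomalous,
       seed = st$seed)
}

#' @export
print.merge_stats <- function(x, ...) {
  o <- x$overall
  hi <- x$shells[nrow(x$shells), ]
  f <- function(a, b, fmt = "%.3f") sprintf(paste0(fmt, " (", fmt, ")"), a, b)
  cat(sprintf("Resolution range (A)        %.2f-%.2f (%.2f-%.2f)\n",
              x$d_max, x$d_min, hi$d_low, hi$d_high))
  cat(sprintf("Total No. of reflections    %d (%d)\n", o$n_total, hi$n_total))
  cat(sprintf("No. of unique reflections   %d (%d)\n", o$n_unique, hi$n_unique))
  cat(sprintf("Completeness (%%)            %s\n",
              f(100 * o$completeness, 100 * hi$completeness, "%.1f")))
  cat(sprintf("Multiplicity                %s\n",
              f(o$multiplicity, hi$multiplicity, "%.1f")))
  cat(sprintf("Half-set correlation CC1/2  %s\n", f(o$cc_half, hi$cc_half)))
  cat(sprintf("<I/sigma(I)>                %s\n",
              f(o$i_over_sigma, hi$i_over_sigma, "%.1f")))
  cat(sprintf("Rmerge                      %s\n", f(o$r_merge, hi$r_merge)))
  cat(sprintf("Rmeas                       %s\n", f(o$r_meas, hi$r_meas)))
  cat(sprintf("Rpim                        %s\n", f(o$r_pim, hi$r_pim)))
  if (x$anomalous && is.finite(o$sig_ano))
    cat(sprintf("sigAno                      %s\n", f(o$sig_ano, hi$sig_ano)))
  invisible(x)
}
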