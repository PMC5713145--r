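# Independent brute-force references used to validate the fast paths.

# O(n^3) average-linkage: repeatedly join the pair of clusters with minimal
# mean inter-cluster distance, recomputed from the original matrix each step
brute_average_linkage <- function(D) {
  n <- nrow(D)
  cl <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    k <- length(cl)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(D[cl[[i]], cl[[j]]])
      if (dd < best) { best <- dd; bi <- i; bj <- j }
    }
    heights[s] <- best
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  heights
}

# per-key accumulation oracle for inverse-variance merging
brute_merge <- function(key, intensity, sigma) {
  out <- NULL
  for (k in sort(unique(key))) {
    sel <- key == k
    w <- 1 / sigma[sel]^2
    out <- rbind(out, data.frame(key = k,
                                 i_mean = sum(w * intensity[sel]) / sum(w),
                                 sigma = sqrt(1 / sum(w)),
                                 multiplicity = sum(sel)))
  }
  out
}

# brute-force agreement R factors over groups with n >= 2
brute_r_factors <- function(key, intensity) {
  num_m <- num_r <- num_p <- den <- 0
  for (k in unique(key)) {
    x <- intensity[key == k]
    n <- length(x)
    if (n < 2) next
    dev <- sum(abs(x - mean(x)))
    num_m <- num_m + dev
    num_r <- num_r + dev * sqrt(n / (n - 1))
    num_p <- num_p + dev * sqrt(1 / (n - 1))
    den <- den + sum(x)
  }
  list(r_merge = num_m / den, r_meas = num_r / den, r_pim = num_p / den)
}
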