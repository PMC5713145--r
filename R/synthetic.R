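# Synthetic multi-crystal wedge generator.
#
# Emulates a serial-crystallography experiment at the level hierarchical
# clustering actually consumes: many small partial datasets, each covering a
# few percent of the asymmetric unit, drawn from class-specific ground-truth
# intensity sets with controllable within-/between-class correlation, cell
# jitter, relative noise and (optionally) an anomalous signal. Wedges are
# index-block samples plus random scatter, not ray-traced rotation geometry.

#' Simulation configuration
#'
#' Defaults emulate a typical serial data collection from ~200 microcrystals
#' of a tetragonal protein: 184 integrated wedges at ~4.9% completeness each,
#' so that every wedge carries roughly 2500 observations to 1.8 Angstrom.
#'
#' @param cell unit cell (default 58.07, 58.07, 150.56, tetragonal).
#' @param sg space group number (default 92, P41212).
#' @param d_min resolution limit of the ground truth (default 1.8 Angstrom).
#' @param n_classes number of isomorphism classes (default 1).
#' @param datasets_per_class wedges per class (scalar or vector; default 184).
#' @param within_cc target expected pairwise correlation between datasets of
#'   one class (default 0.95).
#' @param between_cc target expected correlation between the class ground-truth
#'   intensity sets (default 0.30).
#' @param wedge_fraction expected per-dataset completeness fraction (default
#'   0.049).
#' @param noise_level relative per-observation noise sigma/I (default 0.1).
#' @param cell_jitter relative per-class cell perturbation s.d. (default
#'   0.002, i.e. inside the 1% compatibility gate so that the correlation
#'   metric, not the gate, separates classes).
#' @param anomalous_signal relative Bijvoet difference scale on acentric
#'   reflections (default 0, no anomalous signal).
#' @param multiplicity expected observations per sampled unique reflection
#'   within one wedge (default 2.07, reproducing ~2480 observations per wedge
#'   under the completeness default).
#' @param block_fraction share of a wedge's coverage taken by the contiguous
#'   index block (the rest is random scatter; default 0.5).
#' @param intensity_scale overall intensity scale (default 1000).
#' @param log_sd s.d. of the log-normal latent intensities (default 1).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(cell = crystal_cell(58.07, 58.07, 150.56),
                              sg = 92, d_min = 1.8, n_classes = 1,
                              datasets_per_class = 184, within_cc = 0.95,
                              between_cc = 0.30, wedge_fraction = 0.049,
                              noise_level = 0.1, cell_jitter = 0.002,
                              anomalous_signal = 0, multiplicity = 2.07,
                              block_fraction = 0.5, intensity_scale = 1000,
                              log_sd = 1, seed = 1) {
  if (!(between_cc >= 0 && between_cc <= within_cc && within_cc <= 1))
    mx_validation_error("need 0 <= between_cc <= within_cc <= 1")
  if (!(wedge_fraction > 0 && wedge_fraction <= 1))
    mx_validation_error("wedge_fraction must lie in (0, 1]")
  if (noise_level < 0 || cell_jitter < 0 || anomalous_signal < 0)
    mx_validation_error("noise_level, cell_jitter and anomalous_signal must be >= 0")
  if (multiplicity < 1) mx_validation_error("multiplicity must be >= 1")
  if (block_fraction < 0 || block_fraction > 1)
    mx_validation_error("block_fraction must lie in [0, 1]")
  if (length(datasets_per_class) == 1)
    datasets_per_class <- rep(datasets_per_class, n_classes)
  if (length(datasets_per_class) != n_classes)
    mx_validation_error("datasets_per_class must have length 1 or n_classes")
  structure(list(cell = as_crystal_cell(cell), sg = space_group(sg),
                 d_min = d_min, n_classes = as.integer(n_classes),
                 datasets_per_class = as.integer(datasets_per_class),
                 within_cc = within_cc, between_cc = between_cc,
                 wedge_fraction = wedge_fraction, noise_level = noise_level,
                 cell_jitter = cell_jitter, anomalous_signal = anomalous_signal,
                 multiplicity = multiplicity, block_fraction = block_fraction,
                 intensity_scale = intensity_scale, log_sd = log_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# within-class multiplicative perturbation s.d. solved from the variance
# decomposition so that the expected dataset-pair correlation hits within_cc:
#   cc_w = Var(J) / (Var(J) + (tau^2 + nl^2 (1 + tau^2)) E[J^2])
# with Var(J)/E[J^2] = 1 - exp(-log_sd^2) for log-normal truth
solve_tau <- function(within_cc, noise_level, log_sd) {
  r <- 1 - exp(-log_sd^2)
  tau2 <- (r * (1 / within_cc - 1) - noise_level^2) / (1 + noise_level^2)
  if (tau2 < -1e-12)
    mx_validation_error(paste("within_cc = %.3g is unreachable at noise_level",
                              "= %.3g: noise alone caps the correlation"),
                        within_cc, noise_level)
  sqrt(max(tau2, 0))
}

#' Generate per-class ground-truth intensities
#'
#' Latent Gaussian model: a shared standard-normal component S plus per-class
#' components, mixed so that the expected Pearson correlation between the
#' log-normal class intensity sets equals `between_cc` (the mixing weight is
#' solved from the log-normal correlation identity). Intensities are strictly
#' positive. Per class, the unit cell is jittered (lengths sharing a value are
#' jittered together, preserving the lattice constraint) and, if requested,
#' acentric reflections receive a relative Bijvoet difference.
#'
#' @param config a `sim_config`.
#' @return a `sim_truth`: list with `keys` (asymmetric-unit table with d and
#'   centric flag), `intensity` (matrix keys x classes), `delta` (Bijvoet
#'   fractions), `cells` (per-class `crystal_cell`), `config`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  keys <- enumerate_unique(config$cell, config$sg, config$d_min,
                           anomalous = FALSE)
  n <- nrow(keys)
  s2 <- config$log_sd^2
  rho_lat <- if (config$n_classes == 1 || config$between_cc == 1) 1
  else log(1 + config$between_cc * (exp(s2) - 1)) / s2
  with_seed(config$seed, {
    zs <- stats::rnorm(n)
    intensity <- matrix(0, n, config$n_classes)
    for (c_i in seq_len(config$n_classes)) {
      z <- if (rho_lat == 1) zs
      else sqrt(rho_lat) * zs + sqrt(1 - rho_lat) * stats::rnorm(n)
      intensity[, c_i] <- config$intensity_scale * exp(config$log_sd * z)
    }
    delta <- matrix(0, n, config$n_classes)
    if (config$anomalous_signal > 0) {
      acent <- !keys$centric
      for (c_i in seq_len(config$n_classes))
        delta[acent, c_i] <- stats::rnorm(sum(acent), 0, config$anomalous_signal)
    }
    cells <- lapply(seq_len(config$n_classes), function(c_i) {
      p <- cell_as_numeric(config$cell)
      lens <- p[1:3]
      for (v in unique(lens)) {
        f <- 1 + stats::rnorm(1, 0, config$cell_jitter)
        lens[lens == v] <- lens[lens == v] * f
      }
      crystal_cell(lens[1], lens[2], lens[3], p[4], p[5], p[6])
    })
    structure(list(keys = keys, intensity = intensity, delta = delta,
                   cells = cells, config = config),
              class = "sim_truth")
  })
}

#' Generate wedge-style partial datasets from a ground truth
#'
#' Each dataset samples a contiguous block of the (key-ordered) asymmetric
#' unit plus random scatter, with expected coverage `wedge_fraction`; each
#' sampled reflection is observed `1 + Poisson(multiplicity - 1)` times. The
#' observed intensity is the class truth times a per-dataset-per-reflection
#' multiplicative perturbation (sized analytically so the expected
#' within-class dataset correlation equals `within_cc`), a Bijvoet factor for
#' the randomly assigned Friedel parity, plus Gaussian noise of s.d.
#' `noise_level * I`; the sigma column records that true noise sigma.
#' Observation indices are presented as random symmetry equivalents, so
#' downstream code must genuinely reduce them to the asymmetric unit.
#'
#' @param config a `sim_config`.
#' @param truth a `sim_truth` from [generate_ground_truth()] (generated from
#'   `config` if missing).
#' @param dir optional directory: when given, each dataset is written as a
#'   plain-text reflection table, together with `manifest.txt` and a
#'   `truth.json` holding the class label of every dataset.
#' @return list with `datasets` (named list of `partial_dataset`), `labels`
#'   (named integer class per dataset), and (when `dir` is given)
#'   `manifest_path`.
#' @export
generate_partial_datasets <- function(config, truth = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- generate_ground_truth(config)
  keys <- truth$keys
  n_keys <- nrow(keys)
  tau <- solve_tau(config$within_cc, config$noise_level, config$log_sd)
  classes <- rep(seq_len(config$n_classes), config$datasets_per_class)
  n_ds <- length(classes)
  rots <- config$sg$rot
  sigma_floor <- 1e-6 * config$intensity_scale
  n_block <- round(config$block_fraction * config$wedge_fraction * n_keys)
  p_scatter <- (config$wedge_fraction * n_keys - n_block) / (n_keys - n_block)
  hkl_all <- as.matrix(keys[, c("h", "k", "l")])

  datasets <- with_seed(config$seed + 1L, lapply(seq_len(n_ds), function(i) {
    c_i <- classes[i]
    sel <- logical(n_keys)
    if (n_block > 0) {
      start <- sample.int(n_keys - n_block + 1L, 1)
      sel[start:(start + n_block - 1L)] <- TRUE
    }
    if (p_scatter > 0)
      sel[!sel] <- stats::runif(n_keys - n_block) < p_scatter
    idx <- which(sel)
    if (length(idx) == 0) idx <- sample.int(n_keys, 1)
    nobs <- 1L + stats::rpois(length(idx), config$multiplicity - 1)
    row <- rep(idx, nobs)
    pert <- rep(1 + stats::rnorm(length(idx), 0, tau), nobs)
    parity <- ifelse(keys$centric[row], 1L,
                     sample(c(1L, -1L), length(row), replace = TRUE))
    i_true <- truth$intensity[row, c_i] * pert *
      (1 + parity * truth$delta[row, c_i] / 2)
    sig <- config$noise_level * abs(i_true)
    i_obs <- i_true + stats::rnorm(length(row), 0, sig)
    sig <- pmax(sig, sigma_floor)
    hkl <- hkl_all[row, , drop = FALSE]
    op <- sample.int(length(rots), length(row), replace = TRUE)
    out <- matrix(0L, length(row), 3)
    for (o in seq_along(rots)) {
      rws <- op == o
      if (any(rws)) out[rws, ] <- hkl[rws, , drop = FALSE] %*% rots[[o]]
    }
    out <- out * parity
    new_partial_dataset(sprintf("w%03d", i), truth$cells[[c_i]], config$sg,
                        data.frame(h = as.integer(out[, 1]),
                                   k = as.integer(out[, 2]),
                                   l = as.integer(out[, 3]),
                                   intensity = i_obs, sigma = sig))
  }))
  names(datasets) <- vapply(datasets, `[[`, character(1), "id")
  labels <- stats::setNames(classes, names(datasets))
  out <- list(datasets = datasets, labels = labels)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(n_ds)
    for (i in seq_len(n_ds)) {
      files[i] <- paste0(names(datasets)[i], ".hkl")
      write_reflection_table(datasets[[i]], file.path(dir, files[i]))
    }
    mpath <- file.path(dir, "manifest.txt")
    writeLines(paste(names(datasets), files), mpath)
    jsonlite::write_json(as.list(labels), file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
    out$manifest_path <- mpath
  }
  out
}

#' Run a full simulation (ground truth + wedges)
#'
#' @inheritParams generate_partial_datasets
#' @return as [generate_partial_datasets()], plus `truth`.
#' @export
simulate_experiment <- function(config, dir = NULL) {
  truth <- generate_ground_truth(config)
  out <- generate_partial_datasets(config, truth, dir)
  out$truth <- truth
  out
}
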