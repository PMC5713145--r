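# End-to-end pipeline: read -> distances -> linkage -> threshold -> cut ->
# merge -> statistics -> outputs. This is the headless entry point the CLI
# wraps; every stage logs its counts and any error is tagged with its stage.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full clustering and merging pipeline
#'
#' @param input manifest file path, a `manifest`, or a named list of
#'   `partial_dataset` objects.
#' @param metric distance metric, `"cc"` (default) or `"cell"`.
#' @param mode merge the `"largest"` cluster (default) or `"all"` clusters
#'   below the threshold.
#' @param anomalous logical; merge with Friedel's law false (default TRUE).
#' @param threshold either a numeric linkage height, `"growth"` (default, the
#'   fast largest-cluster-growth estimator) or `"completeness"` (minimal
#'   threshold reaching `completeness_target`).
#' @param completeness_target completeness fraction for the
#'   `"completeness"` estimator (default 0.98).
#' @param d_min optional resolution prefilter (Angstrom) applied to the
#'   correlation distances and the statistics.
#' @param n_shells resolution shells in the statistics (default 10).
#' @param n_min minimum common reflections for a defined pair correlation.
#' @param seed integer seed (CC1/2 half-set splits).
#' @param outdir optional output directory; when given, [write_outputs()] is
#'   called.
#' @param quiet suppress progress messages.
#' @return an `mx_run`: list with `datasets`, `distmat`, `tree`, `threshold`,
#'   `selection`, `results` (per merged cluster: `members`, `merged`,
#'   `stats`), and the call parameters in `config`.
#' @export
run_pipeline <- function(input, metric = c("cc", "cell"),
                         mode = c("largest", "all"), anomalous = TRUE,
                         threshold = "growth", completeness_target = 0.98,
                         d_min = NULL, n_shells = 10, n_min = 3, seed = 1,
                         outdir = NULL, quiet = FALSE) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(sprintf(...))

  datasets <- stage("read", {
    if (is.character(input) || inherits(input, "manifest")) load_datasets(input)
    else input
  })
  say("read: %d datasets, %d observations total", length(datasets),
      sum(vapply(datasets, function(d) nrow(d$observations), integer(1))))

  distmat <- stage("distance", build_distance_matrix(
    datasets, metric = metric, n_min = n_min, d_min = d_min))
  say("distance: %s metric, %d pairs", metric,
      length(datasets) * (length(datasets) - 1) / 2)

  tree <- stage("linkage", average_linkage(distmat))
  say("linkage: %d merges, heights %.3g..%.3g", nrow(tree$merges),
      min(tree$merges$height), max(tree$merges$height))

  thr <- stage("threshold", {
    if (is.numeric(threshold)) threshold
    else if (identical(threshold, "growth")) threshold_by_growth(tree)
    else if (identical(threshold, "completeness"))
      threshold_by_completeness(tree, datasets, target = completeness_target,
                                anomalous = FALSE, d_min = d_min)
    else mx_validation_error(
      "threshold must be numeric, 'growth' or 'completeness'")
  })
  say("threshold: %.4g (%s)", as.numeric(thr),
      if (is.numeric(threshold)) "explicit" else threshold)

  selection <- stage("cut", cut_clusters(tree, as.numeric(thr), mode))
  say("cut: %d cluster(s), sizes %s", length(selection$clusters),
      paste(lengths(selection$clusters), collapse = " "))

  results <- stage("merge", {
    out <- list()
    for (cl in selection$clusters) {
      if (length(cl) < 2) {
        warning(sprintf("cluster {%s} has a single member: merging skipped",
                        cl))
        next
      }
      pool <- pool_observations(cl, datasets, anomalous = anomalous)
      merged <- merge_intensities(pool)
      stats <- merge_statistics(pool, d_min = d_min, n_shells = n_shells,
                                seed = seed)
      out[[length(out) + 1]] <- list(members = cl, merged = merged,
                                     stats = stats)
    }
    out
  })
  for (res in results)
    say("merged %d datasets: %d unique, completeness %.1f%%, CC1/2 %.3f",
        length(res$members), res$stats$overall$n_unique,
        100 * res$stats$overall$completeness, res$stats$overall$cc_half)

  run <- structure(list(datasets = datasets, distmat = distmat, tree = tree,
                        threshold = as.numeric(thr), selection = selection,
                        results = results,
                        config = list(metric = metric, mode = mode,
                                      anomalous = anomalous,
                                      threshold = threshold,
                                      completeness_target = completeness_target,
                                      d_min = d_min, n_shells = n_shells,
                                      n_min = n_min, seed = seed)),
                   class = "mx_run")
  if (!is.null(outdir)) {
    stage("write", write_outputs(run, outdir))
    say("outputs written to %s", outdir)
  }
  run
}

#' @export
print.mx_run <- function(x, ...) {
  cat(sprintf("clustering run: %d datasets, threshold %.4g, %d merged cluster(s)\n",
              length(x$datasets), x$threshold, length(x$results)))
  for (res in x$results) print(res$stats)
  invisible(x)
}
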