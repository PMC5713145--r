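# Reading and writing reflection files, manifests, and run outputs.
#
# Two input dialects are supported bit-exactly:
#  * XDS-ASCII unmerged files (!FORMAT=XDS_ASCII header), the native output of
#    XDS/XSCALE integration;
#  * a minimal whitespace table with a '# cell ...' / '# spacegroup N' header,
#    which is also the format the synthetic generator writes.
# Observations with sigma <= 0 (XDS misfit convention) are dropped, not
# errored, and the dropped count is recorded.

#' Construct a partial dataset in code
#'
#' Builds the in-memory representation of one crystal's unmerged observations.
#' The file readers return the same structure.
#'
#' @param id dataset label (unique within a run).
#' @param cell a `crystal_cell` (or numeric vector of 6).
#' @param sg a `space_group` or IT number.
#' @param observations data.frame with columns `h`, `k`, `l`, `intensity`,
#'   `sigma` (all sigma > 0).
#' @param wavelength optional wavelength (Angstrom).
#' @return a `partial_dataset`.
#' @export
partial_dataset <- function(id, cell, sg, observations, wavelength = NA_real_) {
  new_partial_dataset(id, cell, sg, observations, wavelength)
}

new_partial_dataset <- function(id, cell, sg, observations, wavelength = NA_real_,
                                source = NA_character_, n_dropped = 0L) {
  if (nrow(observations) == 0)
    mx_format_error("dataset '%s' has no usable observations", id)
  if (any(observations$sigma <= 0))
    mx_validation_error("observations must have sigma > 0")
  structure(list(id = id, cell = as_crystal_cell(cell), spacegroup = space_group(sg),
                 wavelength = wavelength, observations = observations,
                 source = source, n_dropped = as.integer(n_dropped)),
            class = "partial_dataset")
}

#' @export
print.partial_dataset <- function(x, ...) {
  cat(sprintf("partial dataset '%s': %d observations (%d dropped), %s, cell %.2f %.2f %.2f\n",
              x$id, nrow(x$observations), x$n_dropped, x$spacegroup$symbol,
              x$cell$a, x$cell$b, x$cell$c))
  invisible(x)
}

parse_obs_table <- function(txt, id, path, cols = 1:5) {
  if (length(txt) == 0) mx_format_error("'%s': no reflection records", path)
  m <- utils::read.table(text = txt, header = FALSE)
  if (ncol(m) < max(cols))
    mx_format_error("'%s': expected at least %d columns", path, max(cols))
  obs <- data.frame(h = as.integer(round(m[[cols[1]]])),
                    k = as.integer(round(m[[cols[2]]])),
                    l = as.integer(round(m[[cols[3]]])),
                    intensity = as.numeric(m[[cols[4]]]),
                    sigma = as.numeric(m[[cols[5]]]))
  keep <- obs$sigma > 0
  list(obs = obs[keep, , drop = FALSE], n_dropped = sum(!keep))
}

header_value <- function(lines, tag, path, required = TRUE) {
  hit <- grep(tag, lines, fixed = TRUE, value = TRUE)
  if (length(hit) == 0) {
    if (required) mx_format_error("'%s': missing header field %s", path, tag)
    return(NULL)
  }
  sub(".*=", "", hit[1])
}

#' Read an unmerged XDS-ASCII reflection file
#'
#' Parses the unmerged XDS-ASCII dialect: `!`-prefixed header lines carrying
#' `!UNIT_CELL_CONSTANTS=` and `!SPACE_GROUP_NUMBER=` (and optionally
#' `!X-RAY_WAVELENGTH=` and `!ITEM_*` column declarations), followed by
#' whitespace records of h k l I sigma(I). Extra record columns are ignored.
#' Observations with sigma <= 0 are dropped and counted in `$n_dropped`.
#'
#' @param path file path.
#' @param id dataset label; default is the file name stem.
#' @return a `partial_dataset`.
#' @export
read_xds_ascii <- function(path, id = NULL) {
  if (!file.exists(path)) mx_io_error("no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "!")]
  cellv <- scan(text = header_value(hdr, "!UNIT_CELL_CONSTANTS=", path),
                quiet = TRUE)
  if (length(cellv) < 6)
    mx_format_error("'%s': UNIT_CELL_CONSTANTS needs 6 values", path)
  sgnum <- as.integer(scan(text = header_value(hdr, "!SPACE_GROUP_NUMBER=", path),
                           quiet = TRUE)[1])
  wl <- header_value(hdr, "!X-RAY_WAVELENGTH=", path, required = FALSE)
  wl <- if (is.null(wl)) NA_real_ else scan(text = wl, quiet = TRUE)[1]
  item <- function(tag, default) {
    v <- header_value(hdr, tag, path, required = FALSE)
    if (is.null(v)) default else as.integer(scan(text = v, quiet = TRUE)[1])
  }
  cols <- c(item("!ITEM_H=", 1L), item("!ITEM_K=", 2L), item("!ITEM_L=", 3L),
            item("!ITEM_IOBS=", 4L), item("!ITEM_SIGMA(IOBS)=", 5L))
  body <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  p <- parse_obs_table(body, id, path, cols)
  new_partial_dataset(id, cellv, sgnum, p$obs, wl, path, p$n_dropped)
}

#' Read a plain-text reflection table
#'
#' Fallback dialect: comment header lines `# cell a b c alpha beta gamma`,
#' `# spacegroup N`, optional `# wavelength w` and `# id label`, followed by
#' whitespace records h k l I sigma(I).
#'
#' @inheritParams read_xds_ascii
#' @return a `partial_dataset`.
#' @export
read_reflection_table <- function(path, id = NULL) {
  if (!file.exists(path)) mx_io_error("no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- trimws(lines[startsWith(lines, "#")])
  take <- function(tag, required = TRUE) {
    hit <- hdr[startsWith(hdr, paste0("# ", tag))]
    if (length(hit) == 0) {
      if (required) mx_format_error("'%s': missing header field '%s'", path, tag)
      return(NULL)
    }
    trimws(sub(paste0("# ", tag), "", hit[1], fixed = TRUE))
  }
  cellv <- scan(text = take("cell"), quiet = TRUE)
  if (length(cellv) != 6) mx_format_error("'%s': cell header needs 6 values", path)
  sgnum <- as.integer(take("spacegroup"))
  wl <- take("wavelength", required = FALSE)
  wl <- if (is.null(wl)) NA_real_ else as.numeric(wl)
  hid <- take("id", required = FALSE)
  if (is.null(id)) id <- if (!is.null(hid)) hid else sub("\\.[^.]*$", "", basename(path))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  p <- parse_obs_table(body, id, path)
  new_partial_dataset(id, cellv, sgnum, p$obs, wl, path, p$n_dropped)
}

#' Read a reflection file of either supported dialect
#'
#' Dispatches on the first line: XDS-ASCII (`!` header) or the plain-text
#' table format.
#'
#' @inheritParams read_xds_ascii
#' @return a `partial_dataset`.
#' @export
read_reflections <- function(path, id = NULL) {
  if (!file.exists(path)) mx_io_error("no such file: '%s'", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "!")) read_xds_ascii(path, id)
  else read_reflection_table(path, id)
}

#' Write a partial dataset as a plain-text reflection table
#'
#' @param ds a `partial_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reflection_table <- function(ds, path) {
  hdr <- c(paste("# id", ds$id),
           paste("# cell", paste(mx_num(cell_as_numeric(ds$cell)), collapse = " ")),
           paste("# spacegroup", ds$spacegroup$number))
  if (!is.na(ds$wavelength)) hdr <- c(hdr, paste("# wavelength", mx_num(ds$wavelength)))
  o <- ds$observations
  rec <- sprintf("%d %d %d %s %s", o$h, o$k, o$l, mx_num(o$intensity), mx_num(o$sigma))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' One entry per line: either `id path` or just `path` (the id then defaults
#' to the file name stem). Blank lines and `#` comments are skipped. Paths are
#' resolved relative to the manifest location.
#'
#' @param path manifest file path.
#' @return an object of class `manifest`: data.frame with columns `id`,
#'   `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) mx_io_error("no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- trimws(lines[keep]); lineno <- lineno[keep]
  parts <- strsplit(lines, "[[:space:]]+")
  ids <- character(0); paths <- character(0)
  for (p in parts) {
    if (length(p) == 1) {
      ids <- c(ids, sub("\\.[^.]*$", "", basename(p)))
      paths <- c(paths, p)
    } else {
      ids <- c(ids, p[1]); paths <- c(paths, p[2])
    }
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    bad <- unique(dup)[1]
    mx_validation_error("duplicate dataset id '%s' on lines %s", bad,
                        paste(lineno[ids == bad], collapse = " and "))
  }
  if (anyDuplicated(paths))
    mx_validation_error("duplicate path in manifest: '%s'",
                        paths[duplicated(paths)][1])
  full <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                 file.path(dirname(path), paths))
  missing <- !file.exists(full)
  if (any(missing))
    mx_io_error("unreadable path on line %d: '%s'",
                lineno[missing][1], paths[missing][1])
  structure(data.frame(id = ids, path = full, stringsAsFactors = FALSE),
            class = c("manifest", "data.frame"))
}

#' Load every dataset listed in a manifest
#' @param manifest a `manifest` (or path to one).
#' @return named list of `partial_dataset` objects, in manifest order.
#' @export
load_datasets <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- Map(read_reflections, manifest$path, manifest$id)
  names(out) <- manifest$id
  out
}

#' Write a merged reflection list
#'
#' Plain-text format: header `# cell`, `# spacegroup`, `# anomalous`, then one
#' record per unique reflection: h k l i_mean sigma multiplicity, extended by
#' the Friedel-separated columns (i_plus sigma_plus n_plus i_minus sigma_minus
#' n_minus) when the data were merged with Friedel's law false.
#'
#' @param merged a `merged_reflections` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_merged <- function(merged, path) {
  cell <- attr(merged, "cell"); sg <- attr(merged, "sg")
  anomalous <- attr(merged, "anomalous")
  hdr <- c(paste("# cell", paste(mx_num(cell_as_numeric(cell)), collapse = " ")),
           paste("# spacegroup", sg$number),
           paste("# anomalous", if (anomalous) "true" else "false"))
  base <- c("h", "k", "l", "i_mean", "sigma", "multiplicity")
  cols <- if (anomalous)
    c(base, "i_plus", "sigma_plus", "n_plus", "i_minus", "sigma_minus", "n_minus")
  else base
  m <- as.data.frame(merged)[, cols]
  num <- vapply(m, is.double, logical(1))
  m[num] <- lapply(m[num], mx_num)
  writeLines(c(hdr, paste("#", paste(cols, collapse = " ")),
               do.call(paste, m)), path)
  invisible(path)
}

#' Read a merged reflection file written by [write_merged()]
#' @param path file path.
#' @return a `merged_reflections` data.frame with `cell`, `sg`, `anomalous`
#'   attributes.
#' @export
read_merged <- function(path) {
  if (!file.exists(path)) mx_io_error("no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- trimws(lines[startsWith(lines, "#")])
  grab <- function(tag) {
    hit <- hdr[startsWith(hdr, paste0("# ", tag))]
    if (!length(hit)) mx_format_error("'%s': missing header field '%s'", path, tag)
    trimws(sub(paste0("# ", tag), "", hit[1], fixed = TRUE))
  }
  cellv <- scan(text = grab("cell"), quiet = TRUE)
  sgnum <- as.integer(grab("spacegroup"))
  anomalous <- identical(grab("anomalous"), "true")
  colline <- hdr[grepl("^# h k l", hdr)]
  cols <- strsplit(sub("^# ", "", colline[1]), " ")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- utils::read.table(text = body, header = FALSE, col.names = cols,
                         na.strings = "NA")
  structure(m, class = c("merged_reflections", "data.frame"),
            cell = as_crystal_cell(cellv), sg = space_group(sgnum),
            anomalous = anomalous)
}

#' Write the distance matrix as labelled square text
#' @param dm an `mx_distmat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- dm$d
  dimnames(m) <- list(dm$labels, dm$labels)
  utils::write.table(format(m, digits = 10, trim = TRUE), path, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write the linkage table
#'
#' Four columns per merge: left_node, right_node, height, new_size. Leaves are
#' numbered 0..N-1 in manifest order; internal nodes N, N+1, ... in merge
#' order.
#'
#' @param tree a `linkage_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(tree, path) {
  m <- tree$merges
  writeLines(c("# left_node right_node height new_size",
               sprintf("%d %d %s %d", m$left, m$right, mx_num(m$height), m$size)),
             path)
  invisible(path)
}

#' Write all results of a clustering/merging run
#'
#' Creates, under `outdir`, the run-level `distance_matrix.txt` and
#' `linkage.txt`, and one `cluster_NN/` directory per merged cluster holding
#' the merged reflection file (`merged.hkl`), the statistics report
#' (`statistics.json`), the member list (`members.txt`) and the threshold used
#' (`threshold.txt`). Single-member clusters are skipped with a warning
#' (nothing to merge).
#'
#' @param run an `mx_run` object from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @param dendrogram logical; additionally render `dendrogram.png`.
#' @return character vector of paths written, invisibly.
#' @export
write_outputs <- function(run, outdir, dendrogram = FALSE) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) mx_io_error("cannot create output directory '%s'", outdir)
  paths <- character(0)
  p <- file.path(outdir, "distance_matrix.txt")
  write_distance_matrix(run$distmat, p); paths <- c(paths, p)
  p <- file.path(outdir, "linkage.txt")
  write_linkage(run$tree, p); paths <- c(paths, p)
  if (dendrogram) {
    p <- file.path(outdir, "dendrogram.png")
    grDevices::png(p, width = 900, height = 500)
    plot(run$tree, threshold = run$threshold)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  if (length(run$results) == 0) {
    warning("no clusters with more than one member: nothing merged")
    return(invisible(paths))
  }
  for (i in seq_along(run$results)) {
    res <- run$results[[i]]
    cdir <- file.path(outdir, sprintf("cluster_%02d", i))
    dir.create(cdir, showWarnings = FALSE)
    write_merged(res$merged, file.path(cdir, "merged.hkl"))
    jsonlite::write_json(stats_as_list(res$stats),
                         file.path(cdir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(res$members, file.path(cdir, "members.txt"))
    writeLines(mx_num(run$threshold), file.path(cdir, "threshold.txt"))
    paths <- c(paths, cdir)
  }
  invisible(paths)
}
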