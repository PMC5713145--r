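# Embedded space-group operator tables.
#
# Symmetry operators are stored as xyz triplets (International Tables style)
# and parsed into (rotation, translation) pairs at load time. The embedded set
# covers P1 plus the primitive orthorhombic/tetragonal groups of classic
# protein test crystals such as thaumatin and lysozyme; reciprocal-space
# bookkeeping only needs the rotation parts, translations are used to screen
# systematic absences.

.sg_table <- list(
  `1` = list(symbol = "P 1", ops = "x,y,z"),
  `19` = list(symbol = "P 21 21 21", ops = c(
    "x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z")),
  `92` = list(symbol = "P 41 21 2", ops = c(
    "x,y,z", "-x,-y,z+1/2",
    "-y+1/2,x+1/2,z+1/4", "y+1/2,-x+1/2,z+3/4",
    "-x+1/2,y+1/2,-z+1/4", "x+1/2,-y+1/2,-z+3/4",
    "y,x,-z", "-y,-x,-z+1/2")),
  `94` = list(symbol = "P 42 21 2", ops = c(
    "x,y,z", "-x,-y,z",
    "-y+1/2,x+1/2,z+1/2", "y+1/2,-x+1/2,z+1/2",
    "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2",
    "y,x,-z", "-y,-x,-z")),
  `96` = list(symbol = "P 43 21 2", ops = c(
    "x,y,z", "-x,-y,z+1/2",
    "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
    "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
    "y,x,-z", "-y,-x,-z+1/2"))
)

# Parse one xyz triplet such as "-y+1/2,x+1/2,z+1/4" into rotation matrix rows
# and a translation vector, by evaluating each component at unit coordinates.
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", triplet), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) mx_format_error("malformed symmetry operator '%s'", triplet)
  rot <- matrix(0, 3, 3)
  tra <- numeric(3)
  basis <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in 1:3) {
    e <- parse(text = parts[i])[[1]]
    t0 <- eval(e, list(x = 0, y = 0, z = 0))
    tra[i] <- t0
    for (j in 1:3) {
      v <- basis[[j]]
      rot[i, j] <- eval(e, list(x = v[1], y = v[2], z = v[3])) - t0
    }
  }
  list(rot = rot, trans = tra %% 1)
}

#' Space-group description
#'
#' Returns the symmetry operators of a supported space group by International
#' Tables number. The operator table is embedded in the package; the groups
#' provided (P1, P212121, P41212, P42212, P43212) cover primitive
#' orthorhombic/tetragonal protein crystals.
#'
#' @param number International Tables space-group number (1, 19, 92, 94, 96).
#' @return an object of class `space_group`: list with `number`, `symbol`,
#'   `rot` (list of 3x3 integer rotation matrices) and `trans` (list of
#'   translation vectors, components in [0,1)).
#' @examples
#' space_group(96)$symbol
#' @export
space_group <- function(number) {
  if (inherits(number, "space_group")) return(number)
  key <- as.character(as.integer(number))
  entry <- .sg_table[[key]]
  if (is.null(entry))
    mx_validation_error("unsupported space group %s (embedded groups: %s)",
                        key, paste(names(.sg_table), collapse = ", "))
  ops <- lapply(entry$ops, parse_symop)
  rot <- lapply(ops, `[[`, "rot")
  trans <- lapply(ops, `[[`, "trans")
  dets <- vapply(rot, det, numeric(1))
  if (!any(vapply(seq_along(rot), function(i)
    all(rot[[i]] == diag(3)) && all(trans[[i]] == 0), logical(1))))
    mx_validation_error("space group %s lacks the identity operation", key)
  if (any(abs(abs(dets) - 1) > 1e-9))
    mx_validation_error("space group %s has a rotation with |det| != 1", key)
  structure(list(number = as.integer(number), symbol = entry$symbol,
                 rot = rot, trans = trans),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (#%d), %d symmetry operators\n",
              x$symbol, x$number, length(x$rot)))
  invisible(x)
}
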