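#' Unit cell constructor
#'
#' Creates a validated crystal unit cell. Lengths are in Angstrom, angles in
#' degrees.
#'
#' @param a,b,c cell edge lengths (Angstrom), must be positive.
#' @param alpha,beta,gamma cell angles (degrees), each in (0, 180).
#' @return an object of class `crystal_cell` (named list with the six
#'   parameters).
#' @examples
#' crystal_cell(58.07, 58.07, 150.56)
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = unname(a), b = unname(b), c = unname(c), alpha = unname(alpha),
         beta = unname(beta), gamma = unname(gamma))
  if (any(!is.finite(p))) mx_validation_error("cell parameters must be finite")
  if (any(p[1:3] <= 0)) mx_validation_error("cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180))
    mx_validation_error("cell angles must lie in (0, 180) degrees")
  structure(as.list(p), class = "crystal_cell")
}

#' Coerce to a crystal_cell
#' @param x a `crystal_cell` or numeric vector of length 6 (a, b, c, alpha,
#'   beta, gamma).
#' @return a `crystal_cell`.
#' @export
as_crystal_cell <- function(x) {
  if (inherits(x, "crystal_cell")) return(x)
  if (is.numeric(x) && length(x) == 6)
    return(crystal_cell(x[1], x[2], x[3], x[4], x[5], x[6]))
  mx_validation_error("cannot interpret input as a unit cell")
}

cell_as_numeric <- function(cell) {
  unlist(cell[c("a", "b", "c", "alpha", "beta", "gamma")])
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# real-space metric tensor G; 1/d^2 = h' G^-1 h for Miller row-vector h
metric_tensor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c), 3, 3))
}

reciprocal_metric <- function(cell) solve(metric_tensor(cell))

#' Resolution (d-spacing) of reflections
#'
#' Computes the d-spacing in Angstrom of one or more Miller indices for a
#' given unit cell, using the general (triclinic) reciprocal metric tensor.
#'
#' @param h,k,l integer Miller indices (vectorised).
#' @param cell a `crystal_cell`.
#' @return numeric vector of d-spacings (Angstrom).
#' @examples
#' d_spacing(1, 0, 0, crystal_cell(10, 10, 10)) # 10
#' @export
d_spacing <- function(h, k, l, cell) {
  cell <- as_crystal_cell(cell)
  if (any(h == 0 & k == 0 & l == 0))
    mx_validation_error("d-spacing undefined for (0,0,0)")
  g <- reciprocal_metric(cell)
  hkl <- cbind(h, k, l)
  q <- rowSums((hkl %*% g) * hkl) # 1/d^2
  1 / sqrt(q)
}

#' Unit-cell compatibility test
#'
#' Two cells are compatible when every one of the six parameters differs by at
#' most `tol` (relative to the pairwise mean). Pairs of datasets failing this
#' gate are treated as maximally non-isomorphous (distance 1) by the
#' correlation metric, which flags outlier crystals.
#'
#' @param cell_a,cell_b unit cells.
#' @param tol relative tolerance; default 0.01 (1 percent).
#' @return logical scalar.
#' @export
cells_compatible <- function(cell_a, cell_b, tol = 0.01) {
  pa <- cell_as_numeric(as_crystal_cell(cell_a))
  pb <- cell_as_numeric(as_crystal_cell(cell_b))
  all(abs(pa - pb) / ((pa + pb) / 2) <= tol)
}
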