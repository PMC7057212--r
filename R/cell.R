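#' @title Unit-cell geometry helpers
#' @name cell-helpers
#' @keywords internal
NULL

.check_cell <- function(cell) {
  cell <- as.numeric(cell)
  if (length(cell) != 6L || anyNA(cell))
    stop("`cell` must be six numbers: a, b, c (Angstrom), alpha, beta, gamma (degrees)")
  if (any(cell[1:3] <= 0)) stop("cell edges must be positive")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell
}

# Direct-space metric tensor G (Angstrom^2)
cell_metric <- function(cell) {
  cell <- .check_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3L, 3L)
}

# Reciprocal metric tensor G* = G^-1 (Angstrom^-2)
recip_metric <- function(cell) solve(cell_metric(cell))

cell_volume <- function(cell) sqrt(det(cell_metric(cell)))

# Standard orthogonalization matrix (fractional -> cartesian, PDB convention:
# a along x, b in the xy plane)
frac_to_cart_matrix <- function(cell) {
  cell <- .check_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- cell_volume(cell)
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0,           v / (a * b * sin(ga))),
         3L, 3L, byrow = TRUE)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the interplanar spacing d(hkl) = 1 / sqrt(h' G* h) from the
#' reciprocal metric tensor of a general (triclinic) unit cell.
#'
#' @param hkl integer vector of length 3, or an n x 3 integer matrix of
#'   Miller indices.
#' @param cell numeric(6): a, b, c in Angstrom, alpha, beta, gamma in degrees.
#' @return numeric vector of d-spacings in Angstrom, one per reflection.
#' @examples
#' d_spacing(c(1, 0, 0), c(10, 20, 30, 90, 90, 90))  # 10 A
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "double"
  if (ncol(hkl) != 3L) stop("`hkl` must have three columns")
  if (any(rowSums(abs(hkl)) == 0))
    stop("invalid reflection (0,0,0): d-spacing is undefined")
  gs <- recip_metric(cell)
  unname(1 / sqrt(rowSums((hkl %*% gs) * hkl)))
}
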