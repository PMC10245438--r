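# Unit cells, fractional/orthogonal conversion, symmetry operators.

#' Crystallographic unit cell
#'
#' @param a,b,c cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, strictly inside (0, 180).
#' @return list with class `unit_cell`.
#' @export
#' @examples
#' unit_cell(10, 10, 10)
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) {
    stop("unit cell lengths must be positive", call. = FALSE)
  }
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) {
    stop("unit cell angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  out <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  class(out) <- "unit_cell"
  # fail early on degenerate angle combinations
  orthogonalization_matrices(out)
  out
}

#' Fractional/orthogonal conversion matrices for a unit cell
#'
#' Uses the standard PDB convention: crystallographic `a` along Cartesian x,
#' `b` in the xy plane. The two matrices are exact mutual inverses.
#'
#' @param cell a [unit_cell()].
#' @return list with elements `frac_to_orth` and `orth_to_frac`, both 3x3.
#' @export
#' @examples
#' m <- orthogonalization_matrices(unit_cell(10, 10, 10))
#' m$frac_to_orth  # 10 * identity
orthogonalization_matrices <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  al <- cell$alpha * DEG; be <- cell$beta * DEG; ga <- cell$gamma * DEG
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  vterm <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vterm <= 1e-12) {
    stop("degenerate unit cell: angle combination gives non-positive volume",
         call. = FALSE)
  }
  v <- sqrt(vterm)
  M <- matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
  list(frac_to_orth = M, orth_to_frac = solve(M))
}

#' Symmetry operator in the fractional basis
#'
#' @param rotation 3x3 matrix acting on fractional coordinates; its
#'   determinant must be +-1 (within 1e-6).
#' @param translation length-3 fractional translation.
#' @param label identifying string, e.g. `"SMTRY 2"`.
#' @return list with class `symmetry_operator`.
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0),
                              label = "op") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(abs(det(rotation)) - 1) > 1e-6) {
    stop("symmetry operator rotation must have determinant +-1", call. = FALSE)
  }
  out <- list(rotation = rotation, translation = as.numeric(translation),
              label = as.character(label))
  class(out) <- "symmetry_operator"
  out
}

is_identity_op <- function(op, tol = 1e-9) {
  max(abs(op$rotation - diag(3))) < tol && max(abs(op$translation)) < tol
}

#' Apply a symmetry operator to orthogonal coordinates
#'
#' The operator lives in the fractional basis; coordinates are converted with
#' the cell, transformed (optionally with an extra lattice translation), and
#' converted back. This is a rigid-body motion: all intra-molecular distances
#' are preserved.
#'
#' @param xyz n x 3 matrix of orthogonal coordinates (Angstrom).
#' @param op a [symmetry_operator()].
#' @param cell a [unit_cell()].
#' @param lattice integer length-3 lattice translation added to the
#'   operator's fractional translation (default none).
#' @return transformed n x 3 matrix.
#' @export
apply_symmetry <- function(xyz, op, cell, lattice = c(0, 0, 0)) {
  m <- orthogonalization_matrices(cell)
  fr <- xyz %*% t(m$orth_to_frac)
  fr <- fr %*% t(op$rotation) +
    matrix(op$translation + lattice, nrow(fr), 3, byrow = TRUE)
  fr %*% t(m$frac_to_orth)
}

# Convert an operator expressed in the orthogonal frame (as in REMARK 290
# SMTRY records: rotation acting on Angstrom coordinates, translation in
# Angstrom) into the fractional basis, and back.
op_orth_to_frac <- function(R_orth, t_orth, cell, label = "op") {
  m <- orthogonalization_matrices(cell)
  symmetry_operator(
    rotation = m$orth_to_frac %*% R_orth %*% m$frac_to_orth,
    translation = as.numeric(m$orth_to_frac %*% t_orth),
    label = label
  )
}

op_frac_to_orth <- function(op, cell) {
  m <- orthogonalization_matrices(cell)
  list(R = m$frac_to_orth %*% op$rotation %*% m$orth_to_frac,
       t = as.numeric(m$frac_to_orth %*% op$translation))
}
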