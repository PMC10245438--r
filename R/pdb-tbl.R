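# The central container: atoms as a tibble subclass ("pdb_tbl") carrying the
# unit cell, the symmetry operators and the source id as attributes, so the
# whole tidyverse toolchain works on it while crystallographic metadata rides
# along through dplyr verbs.

PDB_COLS <- c("model", "serial", "atom", "resname", "chain", "resno", "ins",
              "x", "y", "z", "occ", "b", "element", "het")

#' Construct a pdb_tbl from an atom table
#'
#' A `pdb_tbl` is a [tibble::tibble()] of atom records (one row per atom, one
#' block per model) with columns `model`, `serial`, `atom` (atom name),
#' `resname`, `chain`, `resno`, `ins`, `x`, `y`, `z`, `occ`, `b`, `element`
#' and `het`, plus three attributes: the unit cell, the symmetry operators
#' (fractional basis) and a free-form source identifier. Positions are in
#' Angstrom; residue numbers are author numbering and are never re-indexed.
#'
#' @param atoms data frame with at least `atom`, `resname`, `chain`, `resno`,
#'   `x`, `y`, `z` columns; missing bookkeeping columns are filled with
#'   defaults (`model = 1`, `occ = 1`, `b = 0`, `het = FALSE`).
#' @param cell unit cell created by [unit_cell()], or `NULL`.
#' @param symmetry list of operators created by [symmetry_operator()].
#' @param source_id character scalar naming the origin of the coordinates.
#' @return A `pdb_tbl`.
#' @export
#' @examples
#' pt <- pdb_tbl(tibble::tibble(
#'   atom = c("N", "CA", "C"), resname = "ALA", chain = "A", resno = 1,
#'   x = c(0, 1.46, 2.0), y = c(0, 0, 1.4), z = 0
#' ))
#' n_models(pt)
pdb_tbl <- function(atoms, cell = NULL, symmetry = list(), source_id = "") {
  atoms <- as_tibble(atoms)
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom)
  missing <- setdiff(PDB_COLS, names(atoms))
  if (length(missing)) {
    stop("atom table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c(PDB_COLS, setdiff(names(atoms), PDB_COLS))]
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("non-finite coordinates at atom row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(atoms$chain))) {
    stop("empty chain identifiers are not allowed", call. = FALSE)
  }
  atoms$occ <- pmin(1, pmax(0, atoms$occ))
  new_pdb_tbl(atoms, cell = cell, symmetry = symmetry, source_id = source_id)
}

new_pdb_tbl <- function(atoms, cell = NULL, symmetry = list(), source_id = "") {
  out <- as_tibble(atoms)
  attr(out, "cell") <- cell
  attr(out, "symmetry") <- symmetry
  attr(out, "source_id") <- source_id
  class(out) <- c("pdb_tbl", class(tibble()))
  out
}

#' @export
dplyr_reconstruct.pdb_tbl <- function(data, template) {
  new_pdb_tbl(data,
              cell = attr(template, "cell"),
              symmetry = attr(template, "symmetry"),
              source_id = attr(template, "source_id"))
}

#' @export
`[.pdb_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_pdb_tbl(out, cell = pdb_cell(x), symmetry = symmetry_ops(x),
                       source_id = source_id(x))
  }
  out
}

#' Accessors for pdb_tbl metadata
#'
#' @param x a `pdb_tbl`.
#' @return `pdb_cell()` returns the cell (or `NULL`), `symmetry_ops()` the
#'   operator list, `source_id()` the identifier string, `n_models()` the
#'   number of coordinate models.
#' @export
pdb_cell <- function(x) attr(x, "cell")

#' @rdname pdb_cell
#' @export
symmetry_ops <- function(x) attr(x, "symmetry") %||% list()

#' @rdname pdb_cell
#' @export
source_id <- function(x) attr(x, "source_id") %||% ""

#' @rdname pdb_cell
#' @export
n_models <- function(x) length(unique(x$model))

#' Coordinate matrix of an atom table
#'
#' @param x data frame with `x`, `y`, `z` columns.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(x) {
  m <- cbind(x = x$x, y = x$y, z = x$z)
  rownames(m) <- NULL
  m
}

set_coords <- function(x, xyz) {
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Heavy (non-hydrogen, non-HETATM) atoms of one model
#'
#' All mass and geometry computations in the package operate on heavy atoms;
#' hydrogens are absent from crystal structures and ligands are out of scope.
#'
#' @param x a `pdb_tbl` or atom tibble.
#' @param model model number to keep (default first model present).
#' @return filtered atom tibble.
#' @export
heavy_atoms <- function(x, model = NULL) {
  m <- model %||% min(x$model)
  dplyr::filter(x, .data$model == m, !.data$het,
                !.data$element %in% c("H", "D"))
}

# Standard atomic masses (u), heavy elements seen in protein structures.
ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  `NA` = 22.990, K = 39.098, CL = 35.45, BR = 79.904, I = 126.904,
  MN = 54.938, CU = 63.546, CO = 58.933, NI = 58.693
)

atomic_mass <- function(element) {
  m <- ATOMIC_MASS[toupper(element)]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# Infer the element from a PDB atom name when columns 77-78 are blank.
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "CU",
                          "NI", "CO"),
               two, gsub("[^A-Z].*$|[0-9]", "", substr(nm, 1, 1)))
  el[el == ""] <- substr(nm[el == ""], 1, 1)
  el
}

#' @export
print.pdb_tbl <- function(x, ...) {
  cell <- pdb_cell(x)
  cat(sprintf("# pdb_tbl: %d atoms, %d model(s), %d chain(s)%s\n",
              nrow(x) / max(1, n_models(x)), n_models(x),
              length(unique(x$chain)),
              if (nzchar(source_id(x))) paste0(" [", source_id(x), "]") else ""))
  if (!is.null(cell)) {
    cat(sprintf("# cell: a=%.2f b=%.2f c=%.2f alpha=%.1f beta=%.1f gamma=%.1f; %d symmetry op(s)\n",
                cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                length(symmetry_ops(x))))
  }
  NextMethod()
}
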