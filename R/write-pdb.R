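# Fixed-column PDB writing, including CRYST1 and REMARK 290 SMTRY records
# (operators converted back from the fractional basis to the orthogonal
# frame used by the format) and the per-residue B-factor exporter used by
# the HDX mapping.

#' Write a pdb_tbl to a PDB file
#'
#' Writes REMARK 290 SMTRY rows for any symmetry operators, a CRYST1 record
#' for the cell, and one MODEL/ENDMDL block per coordinate model (single
#' models are written without MODEL wrappers).
#'
#' @param structure a [pdb_tbl()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  cell <- pdb_cell(structure)
  ops <- symmetry_ops(structure)
  out <- character(0)
  if (length(ops)) {
    if (is.null(cell)) {
      stop("cannot write symmetry operators without a unit cell", call. = FALSE)
    }
    for (i in seq_along(ops)) {
      o <- op_frac_to_orth(ops[[i]], cell)
      for (r in 1:3) {
        out <- c(out, sprintf(
          "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
          r, i, o$R[r, 1], o$R[r, 2], o$R[r, 3], o$t[r]))
      }
    }
  }
  if (!is.null(cell)) {
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  }
  models <- sort(unique(structure$model))
  multi <- length(models) > 1
  for (m in models) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, format_atom_lines(structure[structure$model == m, ]))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

format_atom_lines <- function(atoms) {
  if (any(abs(atoms$x) >= 10000 | abs(atoms$y) >= 10000 |
          abs(atoms$z) >= 10000)) {
    stop("coordinates do not fit the 8-column PDB coordinate field",
         call. = FALSE)
  }
  if (any(abs(atoms$b) >= 1000)) {
    stop("B-factor value(s) with |v| >= 1000 are not representable in the ",
         "6-column field", call. = FALSE)
  }
  name <- ifelse(nchar(atoms$atom) >= 4, atoms$atom,
                 # one-letter elements are indented one space (column 14)
                 ifelse(nchar(atoms$element) == 1,
                        sprintf(" %-3s", atoms$atom),
                        sprintf("%-4s", atoms$atom)))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$het, "HETATM", "ATOM"),
          atoms$serial %% 100000, name, " ", atoms$resname, atoms$chain,
          atoms$resno, ifelse(nzchar(atoms$ins), atoms$ins, " "),
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
          substr(atoms$element, 1, 2))
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Every atom's temperature-factor column carries its residue's value
#' (formatted to two decimals); residues absent from `values` carry
#' `missing_sentinel`. This is the conventional channel for painting
#' residue-level measurements (e.g. HDX % deuteration) onto a structure in
#' molecular-graphics programs. All other columns are written unchanged.
#'
#' @param structure a [pdb_tbl()].
#' @param values data frame with columns `chain`, `resno`, `value`.
#' @param path output file path.
#' @param missing_sentinel value for residues not present in `values`
#'   (default 0).
#' @return `path`, invisibly; attribute `"missing_residues"` lists the
#'   (chain, resno) pairs that received the sentinel.
#' @export
write_pdb_with_residue_values <- function(structure, values, path,
                                          missing_sentinel = 0) {
  stopifnot(all(c("chain", "resno", "value") %in% names(values)))
  if (any(abs(values$value) >= 1000, na.rm = TRUE) ||
      abs(missing_sentinel) >= 1000) {
    stop("value(s) with |v| >= 1000 are not representable in the 6-column ",
         "B-factor field", call. = FALSE)
  }
  if (anyDuplicated(values[, c("chain", "resno")])) {
    stop("duplicate (chain, resno) keys in value table", call. = FALSE)
  }
  vals <- values[!is.na(values$value), c("chain", "resno", "value")]
  joined <- dplyr::left_join(
    as_tibble(structure), vals, by = c("chain", "resno"))
  missing <- dplyr::distinct(
    joined[is.na(joined$value), c("chain", "resno")])
  joined$b <- ifelse(is.na(joined$value), missing_sentinel, joined$value)
  joined$value <- NULL
  out <- new_pdb_tbl(joined, cell = pdb_cell(structure),
                     symmetry = symmetry_ops(structure),
                     source_id = source_id(structure))
  write_pdb(out, path)
  attr(path, "missing_residues") <- missing
  invisible(path)
}
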