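# Fixed-column PDB (v3.3) reading. Handles ATOM/HETATM, MODEL/ENDMDL,
# CRYST1 and REMARK 290 SMTRY records; everything else is ignored.

#' Read a PDB coordinate file
#'
#' Parses fixed-column ATOM/HETATM records (author residue numbering
#' preserved), CRYST1 into a [unit_cell()], and REMARK 290 SMTRY rows into
#' symmetry operators. SMTRY operators are written in the orthogonal frame in
#' PDB files; they are converted to the fractional basis on read. Multi-model
#' files yield one coordinate model per MODEL block, and all models must
#' contain the same atoms in the same order (ensembles).
#'
#' Alternate locations: the highest-occupancy conformer of each atom is kept
#' (ties go to the first encountered); use `altloc` to force a specific
#' conformer label instead (e.g. the two R119 states in structures where that
#' side chain is modelled twice).
#'
#' @param path path to a PDB file.
#' @param altloc optional single character: keep atoms with this alternate
#'   location indicator (plus unlabelled atoms) rather than selecting by
#'   occupancy.
#' @return a [pdb_tbl()].
#' @export
read_pdb <- function(path, altloc = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)

  cell <- parse_cryst1(lines, rec)
  symmetry <- parse_smtry(lines, cell)

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  model_id <- cumsum(is_model)
  model_id[model_id == 0] <- 1L
  atom_idx <- which(is_atom)
  if (!length(atom_idx)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  al <- lines[atom_idx]
  if (any(nchar(al) < 54)) {
    bad <- atom_idx[which(nchar(al) < 54)[1]]
    stop("malformed ATOM record (too short for fixed columns) at line ", bad,
         call. = FALSE)
  }
  num <- function(from, to) suppressWarnings(as.numeric(substr(al, from, to)))
  xyz <- cbind(num(31, 38), num(39, 46), num(47, 54))
  if (anyNA(xyz)) {
    bad <- atom_idx[which(rowSums(is.na(xyz)) > 0)[1]]
    stop("malformed ATOM coordinate field at line ", bad, call. = FALSE)
  }
  occ <- num(55, 60); occ[is.na(occ)] <- 1
  bfac <- num(61, 66); bfac[is.na(bfac)] <- 0
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  serial[is.na(serial)] <- seq_along(al)[is.na(serial)]
  resno <- suppressWarnings(as.integer(trimws(substr(al, 23, 26))))
  if (anyNA(resno)) {
    bad <- atom_idx[which(is.na(resno))[1]]
    stop("malformed residue number field at line ", bad, call. = FALSE)
  }
  element <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  element <- ifelse(nzchar(element), toupper(element), guess_element(name))

  atoms <- tibble(
    model = model_id[atom_idx],
    serial = serial,
    atom = name,
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = resno,
    ins = trimws(substr(al, 27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = occ, b = bfac,
    element = element,
    het = rec[atom_idx] == "HETATM"
  )
  if (any(!nzchar(atoms$chain))) atoms$chain[!nzchar(atoms$chain)] <- "A"
  atoms <- select_altloc(atoms, altloc)
  check_ensemble_consistency(atoms, path)

  pdb_tbl(atoms[, PDB_COLS], cell = cell, symmetry = symmetry,
          source_id = sub("\\.(pdb|ent)$", "", basename(path)))
}

parse_cryst1 <- function(lines, rec) {
  i <- which(rec == "CRYST1")
  if (!length(i)) return(NULL)
  ln <- lines[i[1]]
  num <- function(from, to) suppressWarnings(as.numeric(substr(ln, from, to)))
  vals <- c(num(7, 15), num(16, 24), num(25, 33),
            num(34, 40), num(41, 47), num(48, 54))
  if (anyNA(vals)) stop("malformed CRYST1 record at line ", i[1], call. = FALSE)
  unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
}

parse_smtry <- function(lines, cell) {
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (!length(sm)) return(list())
  if (is.null(cell)) {
    warning("REMARK 290 SMTRY records present but no CRYST1 cell; ",
            "symmetry operators ignored", call. = FALSE)
    return(list())
  }
  tok <- strsplit(trimws(sm), "\\s+")
  rows <- do.call(rbind, lapply(tok, function(t) {
    # REMARK 290 SMTRYn opnum r1 r2 r3 t
    c(row = as.integer(sub("SMTRY", "", t[3])),
      op = as.integer(t[4]),
      as.numeric(t[5:8]))
  }))
  ops <- list()
  for (op_id in sort(unique(rows[, "op"]))) {
    block <- rows[rows[, "op"] == op_id, , drop = FALSE]
    block <- block[order(block[, "row"]), , drop = FALSE]
    if (nrow(block) != 3) {
      stop("incomplete REMARK 290 SMTRY block for operator ", op_id,
           call. = FALSE)
    }
    R <- block[, 3:5]
    t <- block[, 6]
    ops[[length(ops) + 1]] <-
      op_orth_to_frac(R, t, cell, label = sprintf("SMTRY %d", op_id))
  }
  ops
}

# Alternate-location selection: per atom site keep the highest-occupancy
# conformer; tie -> first encountered.
select_altloc <- function(atoms, altloc = NULL) {
  if (!is.null(altloc)) {
    keep <- atoms$altloc %in% c(" ", "", altloc)
    return(atoms[keep, , drop = FALSE])
  }
  if (all(atoms$altloc %in% c(" ", ""))) return(atoms)
  atoms %>%
    group_by(.data$model, .data$chain, .data$resno, .data$ins, .data$atom) %>%
    slice(which.max(.data$occ)) %>%
    ungroup() %>%
    arrange(.data$model, .data$serial)
}

check_ensemble_consistency <- function(atoms, path) {
  ids <- unique(atoms$model)
  if (length(ids) < 2) return(invisible())
  key <- split(paste(atoms$chain, atoms$resno, atoms$atom), atoms$model)
  ref <- key[[1]]
  for (i in seq_along(key)[-1]) {
    if (length(key[[i]]) != length(ref) || any(key[[i]] != ref)) {
      stop("ensemble inconsistency in ", path, ": model ", ids[i],
           " differs from model ", ids[1],
           " in atom count or ordering", call. = FALSE)
    }
  }
  invisible()
}
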