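# Ideal helix construction from internal coordinates. The backbone is built
# atom by atom with the natural-extension reference frame (NeRF) from
# phi = -57, psi = -47, omega = 180 degrees; side-chain heavy atoms are
# built from ideal rotamer internal coordinates for the residue types the
# interface and chi1 analyses need. Emergent geometry of the default build:
# rise ~1.5 A/residue, twist ~100 deg/residue, Calpha radius ~2.3 A.

AA1TO3 <- c(A = "ALA", G = "GLY", W = "TRP", Q = "GLN", E = "GLU",
            D = "ASP", R = "ARG", T = "THR", S = "SER", C = "CYS",
            V = "VAL", K = "LYS", H = "HIS", I = "ILE", L = "LEU",
            M = "MET", N = "ASN", F = "PHE", P = "PRO", Y = "TYR")

# Side-chain build recipes: list per residue type of
# (atom, ref1, ref2, ref3, bond, angle, torsion). torsion "chi1" is replaced
# by the requested chi1; other entries are fixed ideal values (chi2+ = trans
# except where rings dictate otherwise).
SIDE_CHAIN_RECIPES <- list(
  TRP = list(
    list("CG",  "N",  "CA", "CB", 1.50, 114.0, "chi1"),
    list("CD1", "CA", "CB", "CG", 1.37, 127.0,  90),
    list("CD2", "CA", "CB", "CG", 1.43, 127.0, -90),
    list("NE1", "CB", "CG", "CD1", 1.38, 110.0, 180),
    list("CE2", "CB", "CG", "CD2", 1.40, 107.0, 180)
  ),
  GLN = list(
    list("CG",  "N",  "CA", "CB", 1.52, 114.0, "chi1"),
    list("CD",  "CA", "CB", "CG", 1.52, 112.0, 180),
    list("OE1", "CB", "CG", "CD", 1.23, 121.0, 0),
    list("NE2", "CB", "CG", "CD", 1.33, 116.0, 180)
  ),
  GLU = list(
    list("CG",  "N",  "CA", "CB", 1.52, 114.0, "chi1"),
    list("CD",  "CA", "CB", "CG", 1.52, 112.0, 180),
    list("OE1", "CB", "CG", "CD", 1.25, 118.0, 0),
    list("OE2", "CB", "CG", "CD", 1.25, 118.0, 180)
  ),
  ASP = list(
    list("CG",  "N",  "CA", "CB", 1.52, 112.0, "chi1"),
    list("OD1", "CA", "CB", "CG", 1.25, 118.0, 0),
    list("OD2", "CA", "CB", "CG", 1.25, 118.0, 180)
  ),
  ARG = list(
    list("CG",  "N",  "CA", "CB", 1.52, 114.0, "chi1"),
    list("CD",  "CA", "CB", "CG", 1.52, 111.0, 180),
    list("NE",  "CB", "CG", "CD", 1.46, 112.0, 180),
    list("CZ",  "CG", "CD", "NE", 1.33, 124.0, 180),
    list("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
    list("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)
  ),
  LYS = list(
    list("CG", "N",  "CA", "CB", 1.52, 114.0, "chi1"),
    list("CD", "CA", "CB", "CG", 1.52, 111.0, 180),
    list("CE", "CB", "CG", "CD", 1.52, 111.0, 180),
    list("NZ", "CG", "CD", "CE", 1.49, 112.0, 180)
  ),
  THR = list(
    list("OG1", "N", "CA", "CB", 1.43, 109.5, "chi1"),
    list("CG2", "N", "CA", "CB", 1.52, 111.0, "chi1-120")
  ),
  SER = list(list("OG", "N", "CA", "CB", 1.42, 110.5, "chi1")),
  CYS = list(list("SG", "N", "CA", "CB", 1.81, 114.0, "chi1")),
  VAL = list(
    list("CG1", "N", "CA", "CB", 1.52, 110.5, "chi1"),
    list("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1+122")
  ),
  ILE = list(
    list("CG1", "N", "CA", "CB", 1.53, 110.5, "chi1"),
    list("CG2", "N", "CA", "CB", 1.53, 110.5, "chi1-122"),
    list("CD1", "CA", "CB", "CG1", 1.52, 114.0, 180)
  ),
  HIS = list(
    list("CG",  "N",  "CA", "CB", 1.50, 114.0, "chi1"),
    list("ND1", "CA", "CB", "CG", 1.38, 122.0, -90),
    list("CD2", "CA", "CB", "CG", 1.36, 122.0, 90)
  )
)

#' Build an ideal (optionally kinked) alpha-helix
#'
#' Constructs a full heavy-atom backbone (N, CA, C, O, and CB except Gly)
#' from ideal internal coordinates (`phi = -57`, `psi = -47`,
#' `omega = 180` degrees by default), plus side-chain heavy atoms for residue
#' types with a build recipe (Trp, Gln, Glu, Asp, Arg, Lys, Thr, Ser, Cys,
#' Val, Ile, His); other residue types get a CB only. The finished helix is
#' aligned with its long axis along +z (N-terminus at low z) and its first
#' Calpha at the origin.
#'
#' @param n_residues number of residues (>= 4).
#' @param sequence optional 1-letter sequence of length `n_residues`
#'   (default poly-Ala).
#' @param substitutions optional named character vector of point
#'   substitutions applied to the sequence, e.g. `c("34" = "W")`.
#' @param phi,psi backbone dihedrals in degrees; scalars or per-residue
#'   vectors of length `n_residues` (per-residue values let parts of the
#'   chain be built extended, i.e. locally unfolded).
#' @param omega peptide-bond dihedral (degrees).
#' @param kink optional `list(position =, angle =)`: bend the helix axis at
#'   the given residue by the given angle in degrees (a 30-degree bend makes
#'   the Calpha kink angle read ~150 degrees).
#' @param chi1 side-chain chi1 dihedral used for all built side chains
#'   (degrees, default 300 = gauche-minus as mapped to \[0, 360)).
#' @param chain chain identifier.
#' @return a [pdb_tbl()]; the build arguments are kept in attribute
#'   `"helix_spec"` so ensemble generators can rebuild variants.
#' @export
#' @examples
#' h <- make_helix(30)
#' kink_angle(h, triplet = c(5, 15, 25))  # ~180 for a straight helix
make_helix <- function(n_residues, sequence = NULL, substitutions = NULL,
                       phi = -57, psi = -47, omega = 180, kink = NULL,
                       chi1 = 300, chain = "A") {
  if (n_residues < 4) stop("a helix needs at least 4 residues", call. = FALSE)
  seq1 <- parse_sequence(n_residues, sequence, substitutions)
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  if (!is.null(kink)) {
    if (kink$position <= 1 || kink$position >= n_residues) {
      stop("kink position must be interior to the chain", call. = FALSE)
    }
    if (kink$angle < 0 || kink$angle > 120) {
      stop("kink angle must lie in [0, 120] degrees", call. = FALSE)
    }
  }

  atoms <- build_backbone(seq1, phi, psi, omega, chi1, chain)
  atoms <- align_helix_z(atoms)
  if (!is.null(kink)) atoms <- apply_kink(atoms, kink$position, kink$angle)

  spec <- list(n_residues = n_residues, sequence = paste(seq1, collapse = ""),
               phi = phi, psi = psi, omega = omega, kink = kink,
               chi1 = chi1, chain = chain)
  out <- pdb_tbl(atoms, source_id = "synthetic-helix")
  attr(out, "helix_spec") <- spec
  out
}

parse_sequence <- function(n, sequence, substitutions) {
  seq1 <- if (is.null(sequence)) rep("A", n) else
    strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) != n) {
    stop("sequence length (", length(seq1), ") != n_residues (", n, ")",
         call. = FALSE)
  }
  if (!is.null(substitutions)) {
    pos <- as.integer(names(substitutions))
    if (anyNA(pos) || any(pos < 1 | pos > n)) {
      stop("substitution positions must be residue numbers within the chain",
           call. = FALSE)
    }
    seq1[pos] <- toupper(substitutions)
  }
  bad <- !seq1 %in% names(AA1TO3)
  if (any(bad)) {
    stop("unknown residue letter(s): ", paste(unique(seq1[bad]),
                                              collapse = ", "), call. = FALSE)
  }
  seq1
}

build_backbone <- function(seq1, phi, psi, omega, chi1, chain) {
  n <- length(seq1)
  rows <- list()
  add <- function(resno, resname, atom, p, element = NULL) {
    rows[[length(rows) + 1]] <<- list(
      atom = atom, resname = resname, chain = chain, resno = resno,
      x = p[1], y = p[2], z = p[3],
      element = element %||% guess_element(atom))
  }
  # residue 1 seeds the frame
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos((180 - 111.2) * DEG), sin((180 - 111.2) * DEG), 0)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    rn3 <- AA1TO3[[seq1[i]]]
    if (i > 1) {
      N <- nerf_place(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1])
      CA <- nerf_place(prev$CA, prev$C, N, 1.458, 121.7, omega)
      C <- nerf_place(prev$C, N, CA, 1.525, 111.2, phi[i])
    }
    O <- nerf_place(N, CA, C, 1.231, 120.5,
                    (if (i < n) psi[i] else psi[i]) + 180)
    add(i, rn3, "N", N); add(i, rn3, "CA", CA); add(i, rn3, "C", C)
    add(i, rn3, "O", O)
    if (rn3 != "GLY") {
      CB <- nerf_place(N, C, CA, 1.53, 109.5, 120)
      add(i, rn3, "CB", CB)
      pos <- list(N = N, CA = CA, C = C, CB = CB)
      for (rec in SIDE_CHAIN_RECIPES[[rn3]] %||% list()) {
        tor <- side_chain_torsion(rec[[7]], chi1)
        p <- nerf_place(pos[[rec[[2]]]], pos[[rec[[3]]]], pos[[rec[[4]]]],
                        rec[[5]], rec[[6]], tor)
        pos[[rec[[1]]]] <- p
        add(i, rn3, rec[[1]], p)
      }
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  df <- bind_rows(lapply(rows, as_tibble))
  df$model <- 1L
  df$serial <- seq_len(nrow(df))
  df
}

side_chain_torsion <- function(spec, chi1) {
  if (is.numeric(spec)) return(spec)
  switch(spec,
         "chi1" = chi1,
         "chi1-120" = chi1 - 120,
         "chi1-122" = chi1 - 122,
         "chi1+122" = chi1 + 122,
         stop("unknown torsion spec: ", spec, call. = FALSE))
}

# Rotate the build so the Calpha principal axis (N->C oriented) lies on +z
# and the first Calpha sits at the origin.
align_helix_z <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  xyz <- coords(ca)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  ax <- sv$v[, 1]
  nc <- as.numeric(xyz[nrow(xyz), ] - xyz[1, ])
  if (sum(ax * nc) < 0) ax <- -ax
  R <- rotation_between(ax, c(0, 0, 1))
  all_xyz <- coords(atoms) %*% t(R)
  origin <- all_xyz[which(atoms$atom == "CA")[1], ]
  set_coords(atoms, sweep(all_xyz, 2, origin))
}

# Bend the helix: rotate everything past the kink residue's Calpha about a
# perpendicular axis through that Calpha.
apply_kink <- function(atoms, position, angle) {
  pivot_idx <- which(atoms$atom == "CA" & atoms$resno == position)
  if (!length(pivot_idx)) stop("kink residue not found", call. = FALSE)
  pivot <- as.numeric(coords(atoms[pivot_idx, ]))
  R <- rotation_about(c(1, 0, 0), angle)
  move <- atoms$resno > position
  xyz <- coords(atoms)
  xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, "+")
  set_coords(atoms, xyz)
}

#' Set the chi1 dihedral of one residue
#'
#' Rotates all side-chain atoms beyond CB about the CA-CB axis so that the
#' N-CA-CB-gamma dihedral equals `chi1`.
#'
#' @param structure a [pdb_tbl()].
#' @param resno residue number.
#' @param chi1 target dihedral in degrees.
#' @param chain chain id (default first chain).
#' @param model model number (default all models).
#' @return the modified structure.
#' @export
set_chi1 <- function(structure, resno, chi1, chain = NULL, model = NULL) {
  ch <- chain %||% structure$chain[1]
  models <- model %||% unique(structure$model)
  for (m in models) {
    sel <- structure$model == m & structure$chain == ch &
      structure$resno == resno
    res <- structure[sel, , drop = FALSE]
    cur <- chi1_impl(res)
    delta <- chi1 - cur
    axis_from <- as.numeric(coords(res[res$atom == "CA", ]))
    axis_to <- as.numeric(coords(res[res$atom == "CB", ]))
    R <- rotation_about(axis_to - axis_from, delta)
    move <- sel & !structure$atom %in% c(BACKBONE_ATOMS, "CB")
    xyz <- coords(structure[move, , drop = FALSE])
    xyz <- sweep(sweep(xyz, 2, axis_to) %*% t(R), 2, axis_to, "+")
    structure[move, c("x", "y", "z")] <- as.data.frame(xyz)
  }
  structure
}
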