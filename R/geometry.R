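# Dimer geometry: centers of mass, inertia tensors, principal axes, the
# inter-chain angle between the long axes of two chains, crystallographic
# mate generation, and T/V packing classification.

#' Center of mass of an atom set
#'
#' @param atoms atom tibble (heavy atoms are used as given; filter first if
#'   needed).
#' @param weighting `"mass"` (standard atomic masses) or `"geometric"`
#'   (unweighted mean of positions).
#' @return numeric length-3 position (Angstrom).
#' @export
#' @examples
#' h <- make_helix(20)
#' center_of_mass(heavy_atoms(h))
center_of_mass <- function(atoms, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (!nrow(atoms)) stop("empty atom set", call. = FALSE)
  w <- if (weighting == "mass") atomic_mass(atoms$element) else
    rep(1, nrow(atoms))
  as.numeric(t(coords(atoms)) %*% w / sum(w))
}

#' Principal axes of inertia of an atom set
#'
#' Builds the inertia tensor about the center of mass, diagonalises it, and
#' returns the eigenvalues in ascending order with their orthonormal axes.
#' The smallest-moment axis is the molecule's long axis. Eigenvectors are
#' signless, so each axis sign is fixed against an orientation reference:
#' by default the vector from the set's first Calpha to its last Calpha
#' (N-to-C direction), which makes obtuse inter-chain angles meaningful.
#'
#' @inheritParams center_of_mass
#' @param orientation_reference length-3 vector used to fix the sign of the
#'   long axis (`NULL`: first-to-last Calpha of the set).
#' @return list with class `principal_axes`: `center` (length 3), `moments`
#'   (ascending, u Angstrom^2), `axes` (3x3, columns are unit axes matched to
#'   `moments`), `orientation_reference`.
#' @export
principal_axes <- function(atoms, weighting = c("mass", "geometric"),
                           orientation_reference = NULL) {
  weighting <- match.arg(weighting)
  if (nrow(atoms) < 3) {
    stop("principal axes need at least 3 atoms", call. = FALSE)
  }
  com <- center_of_mass(atoms, weighting)
  w <- if (weighting == "mass") atomic_mass(atoms$element) else
    rep(1, nrow(atoms))
  r <- sweep(coords(atoms), 2, com)
  wr <- r * w
  r2 <- rowSums(r^2)
  I <- diag(c(sum(w * r2), sum(w * r2), sum(w * r2))) - t(wr) %*% r
  eg <- eigen((I + t(I)) / 2, symmetric = TRUE)
  ord <- order(eg$values)           # ascending moments
  moments <- eg$values[ord]
  axes <- eg$vectors[, ord, drop = FALSE]
  if (moments[1] < max(moments) * 1e-9) {
    stop("degenerate inertia tensor: atom set is collinear", call. = FALSE)
  }
  if (is.null(orientation_reference)) {
    ca <- atoms[atoms$atom == "CA", , drop = FALSE]
    if (nrow(ca) >= 2) {
      ca <- ca[order(ca$resno), , drop = FALSE]
      orientation_reference <-
        as.numeric(coords(ca[nrow(ca), ]) - coords(ca[1, ]))
    } else {
      orientation_reference <- axes[, 1]
    }
  }
  if (sum(axes[, 1] * orientation_reference) < 0) axes[, 1] <- -axes[, 1]
  if (axes[3, 2] < 0) axes[, 2] <- -axes[, 2]          # deterministic sign
  axes[, 3] <- vcross(axes[, 1], axes[, 2])            # right-handed triad
  structure(list(center = com, moments = moments, axes = axes,
                 orientation_reference = orientation_reference),
            class = "principal_axes")
}

#' Long axis (smallest-moment principal axis) of a chain
#' @noRd
long_axis <- function(atoms, weighting = "mass") {
  principal_axes(atoms, weighting)$axes[, 1]
}

#' Inter-chain angle between principal axes of inertia
#'
#' The angle between the long (smallest-moment) inertia axes of two chains,
#' each oriented N-terminus to C-terminus, in degrees within \[0, 180\].
#' This is the quantity that separates T-shaped (~100 degrees) from V-shaped
#' (~75 degrees) packing of ApoE N-terminal domain pairs.
#'
#' @param chain_a,chain_b atom tibbles of the two chains (heavy atoms).
#' @param weighting `"mass"` or `"geometric"`; a Calpha-only geometric mode
#'   can be had by filtering to `atom == "CA"` and passing `"geometric"`.
#' @return angle in degrees.
#' @export
#' @examples
#' d <- make_dimer_at_angle(make_helix(30), angle = 75)
#' interchain_angle(dplyr::filter(d, chain == "A"),
#'                  dplyr::filter(d, chain == "B"))
interchain_angle <- function(chain_a, chain_b, weighting = "mass") {
  vangle(long_axis(chain_a, weighting), long_axis(chain_b, weighting))
}

#' Classify packing as T-shaped or V-shaped
#'
#' @param angle inter-chain angle in degrees, within \[0, 180\].
#' @param params an [analysis_params()]; the boundary (default 90 degrees)
#'   is inclusive on the T side.
#' @return `"T"` or `"V"`, with the boundary recorded in attribute
#'   `"boundary"`.
#' @export
classify_packing <- function(angle, params = analysis_params()) {
  stopifnot(all(angle >= 0 & angle <= 180))
  out <- ifelse(angle >= params$t_v_boundary, "T", "V")
  attr(out, "boundary") <- params$t_v_boundary
  out
}

#' Find crystallographic dimeric units
#'
#' Applies every symmetry operator of the structure combined with lattice
#' translations within the configured shell (default +-1 cell in each
#' fractional direction) to generate symmetry mates, keeps mates with at
#' least one inter-chain heavy-atom pair within `contact_cutoff`, and
#' returns each as a dimeric unit with its inter-axis angle, T/V packing
#' label, interface arrangement label and contact count. For structures
#' without operators but with two or more chains in the asymmetric unit,
#' contacting chain pairs are returned as `"asymmetric-unit pair"` units.
#'
#' @param structure a [pdb_tbl()] with a cell and symmetry operators (or
#'   >= 2 chains).
#' @param params an [analysis_params()].
#' @param chain chain to expand (default the first chain of model 1).
#' @param weighting axis weighting passed to [interchain_angle()].
#' @return tibble with one row per dimeric unit: `operator`, `lattice`,
#'   `angle_deg`, `packing`, `arrangement`, `n_contacts`, and list-columns
#'   `chain_a`, `chain_b` holding the two atom sets. Rows are sorted by
#'   descending contact count (ties broken by operator label).
#' @export
find_crystal_dimers <- function(structure, params = analysis_params(),
                                chain = NULL, weighting = "mass") {
  cell <- pdb_cell(structure)
  ops <- symmetry_ops(structure)
  atoms <- heavy_atoms(structure)
  chains <- unique(atoms$chain)
  use_ops <- length(ops) > 0 && !is.null(cell)

  if (!use_ops) {
    if (length(chains) < 2) {
      stop("no mates derivable: structure has a single chain and no ",
           "cell/symmetry operators", call. = FALSE)
    }
    return(asymmetric_unit_pairs(atoms, chains, params, weighting))
  }

  ch <- chain %||% chains[1]
  a <- atoms[atoms$chain == ch, , drop = FALSE]
  xyz_a <- coords(a)
  com_a <- colMeans(xyz_a)
  rad_a <- sqrt(max(rowSums(sweep(xyz_a, 2, com_a)^2)))
  shell <- params$mate_search_translations
  shifts <- as.matrix(expand.grid(-shell:shell, -shell:shell, -shell:shell))

  rows <- list()
  for (op in ops) {
    for (k in seq_len(nrow(shifts))) {
      lat <- as.numeric(shifts[k, ])
      if (is_identity_op(op) && all(lat == 0)) next
      xyz_b <- apply_symmetry(xyz_a, op, cell, lattice = lat)
      com_b <- colMeans(xyz_b)
      if (vnorm(com_b - com_a) > 2 * rad_a + params$contact_cutoff) next
      d2 <- cross_dist2(xyz_a, xyz_b)
      n_contacts <- sum(d2 < params$contact_cutoff^2)
      if (n_contacts < 1) next
      b <- set_coords(a, xyz_b)
      b$chain <- "B"
      ang <- interchain_angle(a, b, weighting)
      rows[[length(rows) + 1]] <- tibble(
        operator = op$label,
        lattice = paste(lat, collapse = ","),
        angle_deg = ang,
        packing = as.character(classify_packing(ang, params)),
        arrangement = arrangement_label_impl(a, b, params, warn = FALSE),
        n_contacts = n_contacts,
        chain_a = list(a), chain_b = list(b)
      )
    }
  }
  if (!length(rows)) return(empty_dimer_tbl())
  bind_rows(rows) %>%
    arrange(desc(.data$n_contacts), .data$operator, .data$lattice)
}

asymmetric_unit_pairs <- function(atoms, chains, params, weighting) {
  rows <- list()
  combs <- utils::combn(chains, 2, simplify = FALSE)
  for (pr in combs) {
    a <- atoms[atoms$chain == pr[1], , drop = FALSE]
    b <- atoms[atoms$chain == pr[2], , drop = FALSE]
    d2 <- cross_dist2(coords(a), coords(b))
    n_contacts <- sum(d2 < params$contact_cutoff^2)
    if (n_contacts < 1) next
    ang <- interchain_angle(a, b, weighting)
    rows[[length(rows) + 1]] <- tibble(
      operator = "asymmetric-unit pair",
      lattice = paste(pr, collapse = "-"),
      angle_deg = ang,
      packing = as.character(classify_packing(ang, params)),
      arrangement = arrangement_label_impl(a, b, params, warn = FALSE),
      n_contacts = n_contacts,
      chain_a = list(a), chain_b = list(b)
    )
  }
  if (!length(rows)) return(empty_dimer_tbl())
  bind_rows(rows) %>%
    arrange(desc(.data$n_contacts), .data$operator, .data$lattice)
}

empty_dimer_tbl <- function() {
  tibble(operator = character(), lattice = character(),
         angle_deg = numeric(), packing = character(),
         arrangement = character(), n_contacts = integer(),
         chain_a = list(), chain_b = list())
}
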