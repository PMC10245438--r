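# Ground-truth generators: dimers at prescribed inter-axis angles, symmetry
# crystals whose single operator generates a contacting mate, multi-model
# ensembles with known state populations, HDX peptide sets from a known
# residue profile, and noisy sigmoidal aggregation traces. Every generator
# is deterministic under a fixed seed.

#' Build a two-chain dimer at a prescribed inter-axis angle
#'
#' Chain A is the monomer (long axis along +z); chain B is a copy rotated by
#' `angle` about an axis through the contact point (chain A's C-terminal-end
#' Calpha) perpendicular to A's long axis, then slid along its own axis so
#' the nearest heavy-atom pair sits at `contact_gap`. By construction the
#' measured inter-chain angle equals `angle`.
#'
#' @param monomer a single-chain [pdb_tbl()] with its long axis along z,
#'   e.g. from [make_helix()].
#' @param angle target inter-axis angle in degrees, within \[0, 180\].
#' @param contact_gap nearest heavy-atom distance between the chains
#'   (Angstrom, default 3.8).
#' @return two-chain [pdb_tbl()] (chains A and B).
#' @export
#' @examples
#' d <- make_dimer_at_angle(make_helix(30), 75)
#' interchain_angle(dplyr::filter(d, chain == "A"),
#'                  dplyr::filter(d, chain == "B"))
make_dimer_at_angle <- function(monomer, angle, contact_gap = 3.8) {
  if (angle < 0 || angle > 180) {
    stop("angle must lie in [0, 180] degrees", call. = FALSE)
  }
  tf <- dimer_transform(monomer, angle, contact_gap)
  a <- monomer
  a$chain <- "A"
  b <- monomer
  b$chain <- "B"
  xyz <- sweep(coords(b) %*% t(tf$R), 2, tf$t, "+")
  b <- set_coords(b, xyz)
  b$serial <- b$serial + max(a$serial)
  out <- pdb_tbl(bind_rows(as_tibble(a), as_tibble(b)),
                 source_id = sprintf("synthetic-dimer-%g", angle))
  out
}

# Rigid transform (R, t) taking the monomer onto its dimer mate: rotation by
# `angle` about +x through the C-terminal Calpha, then a slide along the
# rotated axis until the nearest heavy-atom distance equals contact_gap.
dimer_transform <- function(monomer, angle, contact_gap) {
  heavy <- heavy_atoms(monomer)
  ca <- heavy[heavy$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  pivot <- as.numeric(coords(ca[nrow(ca), ]))
  R <- rotation_about(c(1, 0, 0), angle)
  slide_dir <- as.numeric(R %*% c(0, 0, 1))
  xyz_a <- coords(heavy)
  base <- sweep(sweep(xyz_a, 2, pivot) %*% t(R), 2, pivot, "+")
  gap_at <- function(s) {
    min_pair_distance(xyz_a, sweep(base, 2, s * slide_dir, "+")) - contact_gap
  }
  lo <- 0
  hi <- 10
  while (gap_at(hi) < 0 && hi < 1000) hi <- hi * 2
  s <- stats::uniroot(gap_at, c(lo, hi), tol = 1e-6)$root
  t_total <- pivot - as.numeric(R %*% pivot) + s * slide_dir
  list(R = R, t = t_total)
}

#' Build a synthetic crystal: one chain, a cell, and one generating operator
#'
#' Writes the monomer as a single chain with a large orthorhombic cell and a
#' REMARK-290-style symmetry operator constructed so that the generated mate
#' contacts the original chain at the requested inter-axis angle (the same
#' construction as [make_dimer_at_angle()], encoded as a crystallographic
#' operator). An identity operator is included first, as in real files. The
#' cell is made large enough that lattice-translated copies stay out of
#' contact.
#'
#' @inheritParams make_dimer_at_angle
#' @param op_angle inter-axis angle generated by the operator (degrees).
#' @param cell_edge cubic cell edge in Angstrom (default 200).
#' @return single-chain [pdb_tbl()] with cell and symmetry operators; feed
#'   to [find_crystal_dimers()] or [write_pdb()].
#' @export
make_symmetry_crystal <- function(monomer, op_angle, contact_gap = 3.8,
                                  cell_edge = 200) {
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  # centre the chain in the cell so mates generated with zero lattice shift
  # stay inside; the operator is built in the orthogonal frame then stored
  # fractionally.
  shift <- c(cell_edge, cell_edge, cell_edge) / 2 -
    center_of_mass(heavy_atoms(monomer), "geometric")
  a <- monomer
  a <- set_coords(a, sweep(coords(a), 2, shift, "+"))
  a$chain <- "A"
  tf <- dimer_transform(a, op_angle, contact_gap)
  ops <- list(
    symmetry_operator(diag(3), c(0, 0, 0), label = "SMTRY 1"),
    op_orth_to_frac(tf$R, tf$t, cell, label = "SMTRY 2")
  )
  pdb_tbl(as_tibble(a), cell = cell, symmetry = ops,
          source_id = sprintf("synthetic-crystal-%g", op_angle))
}

#' Generate a multi-model ensemble with known state populations
#'
#' Frames sample a discrete set of conformational states with the given
#' weights, plus isotropic Gaussian coordinate jitter. Three perturbation
#' modes are supported:
#' \describe{
#'   \item{chi1_states}{`perturbation = list(chi1_states = c("180" = 0.7,
#'     "300" = 0.3), resno = 34)`: per frame, the chi1 of `resno` is set to
#'     a state drawn with the given weights.}
#'   \item{kink_states}{`perturbation = list(kink_states = c("170" = 0.5,
#'     "163" = 0.5), position = 106)`: per frame the helix is bent at
#'     `position` so the kink angle takes the drawn state (base must come
#'     from [make_helix()], straight).}
#'   \item{unfold}{`perturbation = list(unfold_residues = 120:124,
#'     unfold_fraction = 0.4)`: in the drawn fraction of frames the listed
#'     residues are rebuilt extended (phi = psi = 180), locally melting the
#'     helix (base must come from [make_helix()]).}
#' }
#'
#' @param base a [pdb_tbl()], for the kink/unfold modes one built by
#'   [make_helix()].
#' @param perturbation a list as described above; state names are degrees
#'   and values are weights summing to 1.
#' @param n_frames number of models to generate.
#' @param seed integer seed (generator is bit-reproducible).
#' @param jitter_sd Gaussian coordinate jitter sd in Angstrom (default
#'   0.05).
#' @return multi-model [pdb_tbl()]; attribute `"states"` records the drawn
#'   state per frame.
#' @export
make_ensemble <- function(base, perturbation, n_frames, seed,
                          jitter_sd = 0.05) {
  set.seed(as.integer(seed))
  spec <- attr(base, "helix_spec")
  mode <- intersect(c("chi1_states", "kink_states", "unfold_residues"),
                    names(perturbation))
  if (length(mode) != 1) {
    stop("perturbation must contain exactly one of chi1_states, ",
         "kink_states, unfold_residues", call. = FALSE)
  }

  if (mode == "unfold_residues") {
    frac <- perturbation$unfold_fraction
    stopifnot(frac >= 0, frac <= 1)
    states <- sample(c("unfolded", "folded"), n_frames, replace = TRUE,
                     prob = c(frac, 1 - frac))
    if (is.null(spec)) {
      stop("unfold mode needs a base built by make_helix()", call. = FALSE)
    }
    phi_u <- spec$phi
    psi_u <- spec$psi
    idx <- perturbation$unfold_residues
    phi_u[idx] <- 180
    psi_u[idx] <- 180
    unfolded <- make_helix(spec$n_residues, sequence = spec$sequence,
                           phi = phi_u, psi = psi_u, omega = spec$omega,
                           chi1 = spec$chi1, chain = spec$chain)
    frames <- lapply(seq_len(n_frames), function(i) {
      if (states[i] == "unfolded") unfolded else base
    })
  } else {
    weights <- unlist(perturbation[[mode]])
    if (abs(sum(weights) - 1) > 1e-6) {
      stop("state weights must sum to 1", call. = FALSE)
    }
    state_vals <- as.numeric(names(weights))
    states <- state_vals[sample.int(length(state_vals), n_frames,
                                    replace = TRUE, prob = weights)]
    frames <- lapply(seq_len(n_frames), function(i) {
      if (mode == "chi1_states") {
        set_chi1(base, perturbation$resno %||% 34, states[i],
                 chain = perturbation$chain)
      } else {
        if (is.null(spec)) {
          stop("kink mode needs a base built by make_helix()", call. = FALSE)
        }
        bend <- 180 - states[i]
        if (bend < 0.01) base else
          new_pdb_tbl(apply_kink(as_tibble(base),
                                 perturbation$position %||% 106, bend))
      }
    })
  }

  all_frames <- bind_rows(lapply(seq_len(n_frames), function(i) {
    f <- as_tibble(frames[[i]])
    f$model <- i
    if (jitter_sd > 0) {
      f$x <- f$x + stats::rnorm(nrow(f), 0, jitter_sd)
      f$y <- f$y + stats::rnorm(nrow(f), 0, jitter_sd)
      f$z <- f$z + stats::rnorm(nrow(f), 0, jitter_sd)
    }
    f
  }))
  out <- pdb_tbl(all_frames, source_id = "synthetic-ensemble")
  attr(out, "states") <- states
  out
}

#' Generate HDX peptides from a known residue-level profile
#'
#' Each layout entry becomes a peptide whose uptake at each timepoint is the
#' mean of the ground-truth profile over the peptide span, plus Gaussian
#' noise.
#'
#' @param ground_truth tibble with `residue`, `timepoint`, `uptake` (the
#'   per-residue % deuteration profile the peptides report on).
#' @param layout tibble with `start`, `end`, `confidence` for each peptide.
#' @param noise_sd Gaussian noise sd in % deuteration (default 0).
#' @param seed integer seed.
#' @param state state label stamped on all peptides.
#' @param protein_sequence optional 1-letter sequence covering the profile
#'   range (defaults to a fixed repeating 20-letter alphabet so overlapping
#'   peptides are mutually consistent).
#' @return long peptide tibble as from [read_hdx_peptides()].
#' @export
make_hdx_peptides <- function(ground_truth, layout, noise_sd = 0, seed = 1,
                              state = "synthetic",
                              protein_sequence = NULL) {
  set.seed(as.integer(seed))
  rng <- range(ground_truth$residue)
  if (any(layout$start < rng[1]) || any(layout$end > rng[2])) {
    stop("peptide layout extends beyond the ground-truth residue range",
         call. = FALSE)
  }
  n_res <- rng[2] - rng[1] + 1
  seq_full <- if (is.null(protein_sequence)) {
    paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
              length.out = n_res), collapse = "")
  } else protein_sequence
  if (nchar(seq_full) != n_res) {
    stop("protein_sequence must cover the ground-truth range (", n_res,
         " residues)", call. = FALSE)
  }
  tps <- sort(unique(ground_truth$timepoint))
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    s <- layout$start[i]; e <- layout$end[i]
    pep_seq <- substr(seq_full, s - rng[1] + 1, e - rng[1] + 1)
    for (tp in tps) {
      gt <- ground_truth[ground_truth$timepoint == tp &
                           ground_truth$residue >= s &
                           ground_truth$residue <= e, , drop = FALSE]
      val <- mean(gt$uptake) + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1]] <- tibble(
        sequence = pep_seq, start = s, end = e,
        confidence = layout$confidence[i], state = state,
        timepoint = tp, uptake = max(0, val))
    }
  }
  validate_hdx_peptides(bind_rows(rows))
}

#' Generate a sigmoidal aggregation trace with white noise
#'
#' Logistic sigmoid `amplitude / (1 + exp(-steepness * (t - midpoint)))`
#' plus Gaussian noise on a uniform time grid - the shape of a static-light-
#' scattering aggregation experiment.
#'
#' @param n_points number of samples (default 1000).
#' @param duration total time covered in seconds (default 54000 s = 15 h).
#' @param midpoint sigmoid midpoint in seconds (default half the duration).
#' @param steepness logistic growth rate (1/s, default 4e-4).
#' @param amplitude plateau intensity (arbitrary units, default 1).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @param replicate_id replicate label.
#' @return tibble with `time`, `intensity`, `clean` (noise-free signal) and
#'   `replicate_id`.
#' @export
make_sls_trace <- function(n_points = 1000, duration = 54000,
                           midpoint = duration / 2, steepness = 4e-4,
                           amplitude = 1, noise_sd = 0, seed = 1,
                           replicate_id = "r1") {
  stopifnot(n_points > 1, duration > 0, steepness > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  t <- seq(0, duration, length.out = n_points)
  clean <- amplitude / (1 + exp(-steepness * (t - midpoint)))
  tibble(time = t,
         intensity = clean + stats::rnorm(n_points, 0, noise_sd),
         clean = clean,
         replicate_id = replicate_id)
}
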