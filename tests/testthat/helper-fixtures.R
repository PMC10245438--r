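# Shared fixtures: tiny hand-written PDB text, constructed charged-residue
# geometries, and small samplers used by property tests.

# A minimal 3-atom alanine PDB, fixed columns, no cell.
minimal_ala_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C")
}

write_temp_pdb <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Two isolated residues (an arginine guanidinium N and a glutamate
# carboxylate O) separated by `gap` along x; the only charged-group pair at
# that distance.
charged_pair <- function(gap) {
  tibble::tibble(
    atom = c("NH1", "CB", "OE1", "CB"),
    resname = c("ARG", "ARG", "GLU", "GLU"),
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 2L, 2L),
    x = c(0, -1.5, gap, gap + 1.5),
    y = 0, z = 0,
    element = c("N", "C", "O", "C")
  ) |> packinglens::pdb_tbl()
}

# Random rigid-body transform applied to an atom table (fixed seed upstream).
random_rigid <- function(atoms) {
  axis <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 360)
  shift <- stats::rnorm(3, sd = 20)
  R <- rodrigues(axis, ang)
  xyz <- packinglens::coords(atoms) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# Independent Rodrigues rotation (kept in the test helpers so rigid-motion
# invariance checks do not reuse the package's own rotation code).
rodrigues <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# von Mises sampler (Best & Fisher rejection scheme); mean mu in degrees.
rvonmises_deg <- function(n, mu, kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  (mu + out * 180 / pi) %% 360
}

# Ground-truth HDX profile helper: linear ramp over residues.
ramp_truth <- function(residues, timepoints = c(60, 120, 600),
                       base = 20, slope = 2) {
  tidyr::crossing(residue = residues, timepoint = timepoints) |>
    dplyr::mutate(uptake = base + slope * residue)
}

# Histogram mass of an ensemble_metric within +-window of a centre (deg).
state_mass <- function(em, center, window = 45) {
  d <- (em$centers - center + 180) %% 360 - 180
  sum(em$density[abs(d) <= window])
}
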