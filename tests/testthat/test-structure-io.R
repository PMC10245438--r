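test_that("a minimal hand-written PDB parses into atoms without a cell", {
  path <- write_temp_pdb(minimal_ala_pdb())
  s <- read_pdb(path)
  expect_s3_class(s, "pdb_tbl")
  expect_equal(nrow(s), 3)
  expect_equal(n_models(s), 1)
  expect_null(pdb_cell(s))
  expect_equal(symmetry_ops(s), list())
  expect_equal(s$atom, c("N", "CA", "C"))
  expect_equal(s$resno, rep(1L, 3))
  expect_equal(s$b, rep(10, 3))
  expect_equal(s$x, c(0, 1.458, 2.009))
})

test_that("an identity CRYST1 gives unit lengths and an identity matrix", {
  path <- write_temp_pdb(c(
    "CRYST1    1.000    1.000    1.000  90.00  90.00  90.00 P 1           1",
    minimal_ala_pdb()))
  s <- read_pdb(path)
  cell <- pdb_cell(s)
  expect_equal(c(cell$a, cell$b, cell$c), c(1, 1, 1))
  expect_equal(symmetry_ops(s), list())
  m <- orthogonalization_matrices(cell)
  expect_equal(m$frac_to_orth, diag(3), tolerance = 1e-12)
})

test_that("malformed ATOM records fail naming the line", {
  bad <- minimal_ala_pdb()
  bad[2] <- substr(bad[2], 1, 40)
  path <- write_temp_pdb(bad)
  expect_error(read_pdb(path), "line 2")
  bad2 <- minimal_ala_pdb()
  substr(bad2[3], 31, 38) <- "   xx.yy"
  path2 <- write_temp_pdb(bad2)
  expect_error(read_pdb(path2), "line 3")
})

test_that("MODEL blocks with unequal atom counts are an ensemble error", {
  lines <- c("MODEL        1", minimal_ala_pdb(), "ENDMDL",
             "MODEL        2", minimal_ala_pdb()[1:2], "ENDMDL")
  path <- write_temp_pdb(lines)
  expect_error(read_pdb(path), "atom count|ordering")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.60 10.00           C")
  s <- read_pdb(write_temp_pdb(lines))
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$atom == "CA"], 1.6)
  # forced conformer selection overrides occupancy
  s_a <- read_pdb(write_temp_pdb(lines), altloc = "A")
  expect_equal(s_a$x[s_a$atom == "CA"], 1.458)
})

test_that("write-then-read round-trips coordinates, identifiers and ops", {
  cr <- make_symmetry_crystal(make_helix(20), op_angle = 75)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cr, path)
  back <- read_pdb(path)
  expect_lte(max(abs(coords(back) - coords(cr))), 1e-3)
  expect_identical(back$chain, cr$chain)
  expect_identical(back$resno, cr$resno)
  expect_identical(back$atom, cr$atom)
  ops0 <- symmetry_ops(cr)
  ops1 <- symmetry_ops(back)
  expect_length(ops1, length(ops0))
  for (i in seq_along(ops0)) {
    expect_lte(max(abs(ops1[[i]]$rotation - ops0[[i]]$rotation)), 1e-6)
    expect_lte(max(abs(ops1[[i]]$translation - ops0[[i]]$translation)), 1e-6)
  }
  # read -> write -> read is idempotent at column precision
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, path2)
  back2 <- read_pdb(path2)
  expect_identical(coords(back2), coords(back))
})

test_that("the in-package reader agrees with bio3d on a written file", {
  skip_if_not_installed("bio3d")
  d <- make_dimer_at_angle(make_helix(15, substitutions = c("6" = "R")), 100)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ref$atom), nrow(ours))
  expect_equal(cbind(ref$atom$x, ref$atom$y, ref$atom$z), coords(ours),
               ignore_attr = TRUE)
  expect_equal(ref$atom$elety, ours$atom)
  expect_equal(ref$atom$resno, ours$resno)
  expect_equal(ref$atom$chain, ours$chain)
})

test_that("orthogonalization follows the PDB convention and inverts", {
  m <- orthogonalization_matrices(unit_cell(10, 10, 10))
  expect_equal(m$frac_to_orth, 10 * diag(3), tolerance = 1e-12)

  m2 <- orthogonalization_matrices(unit_cell(5, 6, 7))
  expect_equal(as.numeric(m2$frac_to_orth %*% c(0.5, 0.5, 0.5)),
               c(2.5, 3.0, 3.5), tolerance = 1e-12)

  # a along x for any cell
  tric <- unit_cell(23.1, 31.7, 41.3, 77, 83, 96)
  m3 <- orthogonalization_matrices(tric)
  expect_equal(as.numeric(m3$frac_to_orth %*% c(1, 0, 0)),
               c(23.1, 0, 0), tolerance = 1e-9)

  # round trip of random points through a triclinic cell
  set.seed(11)
  pts <- matrix(stats::rnorm(300, sd = 30), ncol = 3)
  back <- pts %*% t(m3$orth_to_frac) %*% t(m3$frac_to_orth)
  expect_lte(max(abs(back - pts)), 1e-9)
})

test_that("frac/orth matrices invert for random cells (property)", {
  set.seed(42)
  for (i in 1:25) {
    cell <- unit_cell(stats::runif(1, 5, 200), stats::runif(1, 5, 200),
                      stats::runif(1, 5, 200), stats::runif(1, 60, 120),
                      stats::runif(1, 60, 120), stats::runif(1, 60, 120))
    m <- orthogonalization_matrices(cell)
    expect_lte(max(abs(m$frac_to_orth %*% m$orth_to_frac - diag(3))), 1e-9)
  }
})

test_that("degenerate cells are rejected", {
  expect_error(unit_cell(10, 10, 10, 1, 179, 90), "degenerate|volume")
  expect_error(unit_cell(-5, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, gamma = 180), "between 0 and 180")
})

test_that("symmetry operators are rigid motions and validate determinants", {
  # two-fold along c: a lattice-compatible operator needs alpha = beta = 90
  cell <- unit_cell(50, 60, 70, 90, 90, 100)
  op <- symmetry_operator(diag(c(-1, -1, 1)), c(0.5, 0, 0.25), "SMTRY 2")
  set.seed(3)
  xyz <- matrix(stats::rnorm(90, sd = 8), ncol = 3)
  moved <- apply_symmetry(xyz, op, cell, lattice = c(1, -1, 0))
  d0 <- as.matrix(stats::dist(xyz))
  d1 <- as.matrix(stats::dist(moved))
  expect_lte(max(abs(d0 - d1)), 1e-6)
  expect_error(symmetry_operator(2 * diag(3)), "determinant")
})

test_that("per-residue B-factor export writes values and the sentinel", {
  h <- make_helix(6)
  vals <- tibble::tibble(chain = "A", resno = 1L, value = 42.5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_with_residue_values(h, vals, path, missing_sentinel = 0)
  back <- read_pdb(path)
  expect_equal(unique(back$b[back$resno == 1]), 42.5)
  expect_equal(unique(back$b[back$resno != 1]), 0)

  # empty map -> all sentinel
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_with_residue_values(
    h, tibble::tibble(chain = character(), resno = integer(),
                      value = numeric()),
    path2, missing_sentinel = 7)
  expect_equal(unique(read_pdb(path2)$b), 7)

  # round trip of a full map within the 2-decimal column precision
  full <- tibble::tibble(chain = "A", resno = 1:6,
                         value = c(12.345, 0.004, 99.999, 55.5, 3.14, 871.2))
  path3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_with_residue_values(h, full, path3)
  got <- dplyr::distinct(read_pdb(path3)[, c("resno", "b")])
  expect_lte(max(abs(got$b[order(got$resno)] - full$value)), 0.005)

  expect_error(
    write_pdb_with_residue_values(
      h, tibble::tibble(chain = "A", resno = 1L, value = 1234.5), path),
    ">= 1000")
})
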