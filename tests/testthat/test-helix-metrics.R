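test_that("kink angle: collinear 180, right angle, missing residue error", {
  tri <- function(p1, p2, p3) {
    pdb_tbl(tibble::tibble(
      atom = "CA", resname = "ALA", chain = "A", resno = 95:97,
      x = c(p1[1], p2[1], p3[1]), y = c(p1[2], p2[2], p3[2]),
      z = c(p1[3], p2[3], p3[3]), element = "C"))
  }
  expect_equal(kink_angle(tri(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                          triplet = 95:97), 180)
  expect_equal(kink_angle(tri(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                          triplet = 95:97), 90)
  expect_error(kink_angle(tri(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                          triplet = c(95, 96, 99)), "residue 99")
})

test_that("a long ideal helix reads straight at the H3 triplet", {
  h <- make_helix(130)
  expect_lte(abs(kink_angle(h) - 180), 2)
  # a built-in 30-degree bend at residue 106 shows up as ~150
  hk <- make_helix(130, kink = list(position = 106, angle = 30))
  expect_lte(abs(kink_angle(hk) - 150), 3)
})

test_that("chi1: eclipsed zero, explicit placements, gamma atom table", {
  res <- function(dchi) {
    # N, CA, CB on a frame; G placed by rotating the eclipsed position
    # about the CA->CB axis with the independent Rodrigues helper
    n <- c(-0.5, 1.3, 0); ca <- c(0, 0, 0); cb <- c(1.53, 0, 0)
    g0 <- cb + c(0.6, 1.4, 0)       # eclipsed with N: chi1 = 0
    R <- rodrigues(cb - ca, dchi)
    g <- as.numeric(R %*% (g0 - cb)) + cb
    pdb_tbl(tibble::tibble(
      atom = c("N", "CA", "CB", "CG"), resname = "GLN", chain = "A",
      resno = 34L, x = c(n[1], ca[1], cb[1], g[1]),
      y = c(n[2], ca[2], cb[2], g[2]), z = c(n[3], ca[3], cb[3], g[3]),
      element = c("N", "C", "C", "C")))
  }
  expect_equal(chi1(res(0), resno = 34), 0, tolerance = 1e-6)
  got60 <- chi1(res(60), resno = 34)
  expect_true(abs(got60 - 60) < 1e-6 || abs(got60 - 300) < 1e-6)
  # mirror image negates the dihedral on the circle
  r <- res(60)
  mir <- r
  mir$z <- -r$z
  expect_equal(chi1(mir, resno = 34), 360 - got60, tolerance = 1e-6)

  # gamma atoms for Ser/Thr/Cys/Val are found; Gly/Ala refuse
  for (sub in list(c("10" = "S"), c("10" = "T"), c("10" = "C"),
                   c("10" = "V"))) {
    hh <- make_helix(15, substitutions = sub, chi1 = 300)
    expect_equal(chi1(hh, resno = 10), 300, tolerance = 1e-6)
  }
  expect_error(chi1(make_helix(15), resno = 10), "no chi1")
})

test_that("chi1 sign convention matches bio3d torsions", {
  skip_if_not_installed("bio3d")
  hw <- make_helix(40, substitutions = c("34" = "W"), chi1 = 300)
  res <- dplyr::filter(hw, resno == 34)
  xyz <- as.numeric(t(coords(res[match(c("N", "CA", "CB", "CG"),
                                       res$atom), ])))
  ref <- bio3d::torsion.xyz(xyz, atm.inc = 4)
  ref <- (ref[!is.na(ref)] + 360) %% 360
  expect_equal(as.numeric(ref), chi1(hw, resno = 34), tolerance = 1e-4)
})

test_that("kink and chi1 are rigid-motion invariant", {
  set.seed(13)
  h <- make_helix(130, substitutions = c("34" = "W"), chi1 = 187)
  k0 <- kink_angle(h)
  c0 <- chi1(h, resno = 34)
  for (i in 1:5) {
    hr <- random_rigid(h)
    expect_lte(abs(kink_angle(hr) - k0), 1e-6)
    expect_lte(abs(chi1(hr, resno = 34) - c0), 1e-6)
  }
})

test_that("ensemble histograms: identical frames, two states, von Mises", {
  hw <- make_helix(40, substitutions = c("34" = "W"))
  # identical frames at chi1 = 60: all mass in the 60 bin
  ens1 <- make_ensemble(hw, list(chi1_states = c("60" = 1), resno = 34),
                        n_frames = 40, seed = 4, jitter_sd = 0)
  em1 <- ensemble_metric(ens1, "chi1", resno = 34)
  expect_equal(sum(em1$density), 1, tolerance = 1e-9)
  expect_equal(em1$density[em1$centers == 65], 1)
  expect_equal(em1$mode, 65)
  expect_equal(length(em1$values), 40)

  # alternating 180/300 with equal weights: two equal masses
  ens2 <- make_ensemble(hw, list(chi1_states = c("180" = 0.5, "300" = 0.5),
                                 resno = 34),
                        n_frames = 400, seed = 8, jitter_sd = 0)
  em2 <- ensemble_metric(ens2, "chi1", resno = 34)
  m180 <- state_mass(em2, 180)
  m300 <- state_mass(em2, 300)
  expect_equal(m180 + m300, 1, tolerance = 1e-9)
  expect_lte(abs(m180 - 0.5), 3 * sqrt(0.25 / 400))

  # von Mises-distributed chi1 centred at 300: mode within one bin
  set.seed(17)
  draws <- rvonmises_deg(120, 300, kappa = 20)
  frames <- lapply(seq_along(draws), function(i) {
    f <- tibble::as_tibble(set_chi1(hw, 34, draws[i]))
    f$model <- i
    f
  })
  vm <- pdb_tbl(dplyr::bind_rows(frames))
  emv <- ensemble_metric(vm, "chi1", resno = 34)
  expect_lte(min(abs(c(emv$mode - 300, emv$mode - 300 + 360,
                       emv$mode - 300 - 360))), 10)
})

test_that("the mode tracks a constant offset (wrap-aware)", {
  hw <- make_helix(40, substitutions = c("34" = "W"))
  base_states <- c("350" = 1)
  ens <- make_ensemble(hw, list(chi1_states = base_states, resno = 34),
                       n_frames = 30, seed = 2, jitter_sd = 0)
  em <- ensemble_metric(ens, "chi1", resno = 34)
  expect_equal(em$mode, 355)
  # shift every angle by +20 across the 360 seam
  ens2 <- make_ensemble(hw, list(chi1_states = c("10" = 1), resno = 34),
                        n_frames = 30, seed = 2, jitter_sd = 0)
  em2 <- ensemble_metric(ens2, "chi1", resno = 34)
  expect_equal(em2$mode, (em$mode + 20) %% 360)
})

test_that("metric failures name the frame", {
  h <- make_helix(10)
  expect_error(ensemble_metric(h, "chi1", resno = 5), "frame 1")
})

test_that("tidy and glance expose frames and circular summaries", {
  hw <- make_helix(40, substitutions = c("34" = "W"))
  ens <- make_ensemble(hw, list(chi1_states = c("300" = 1), resno = 34),
                       n_frames = 25, seed = 3)
  em <- ensemble_metric(ens, "chi1", resno = 34)
  td <- tidy(em)
  expect_equal(nrow(td), 25)
  expect_named(td, c("frame", "value"))
  gl <- glance(em)
  expect_equal(gl$n_frames, 25)
  expect_lte(abs(gl$mean - 300), 5)
})
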