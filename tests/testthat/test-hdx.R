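test_that("uniform assignment over peptide spans and the overlap average", {
  # one high peptide 1-5 at 40%
  p <- tibble::tibble(sequence = "ACDEF", start = 1L, end = 5L,
                      confidence = "high", state = "s", timepoint = 60,
                      uptake = 40)
  m <- map_uptake(p, 60)
  expect_equal(m$uptake, rep(40, 5))
  expect_equal(m$n_peptides, rep(1L, 5))
  expect_equal(m$tier, rep("high", 5))

  # 1-10 @ 20 and 6-15 @ 40 -> shared span averages to 30
  seqs <- paste(rep(strsplit("ACDEFGHIKLMNPQR", "")[[1]], 1), collapse = "")
  p2 <- tibble::tibble(
    sequence = c(substr(seqs, 1, 10), substr(seqs, 6, 15)),
    start = c(1L, 6L), end = c(10L, 15L),
    confidence = "high", state = "s", timepoint = 60, uptake = c(20, 40))
  m2 <- map_uptake(p2, 60)
  expect_equal(m2$uptake[m2$residue %in% 1:5], rep(20, 5))
  expect_equal(m2$uptake[m2$residue %in% 6:10], rep(30, 5))
  expect_equal(m2$uptake[m2$residue %in% 11:15], rep(40, 5))
  expect_equal(m2$n_peptides[m2$residue == 8], 2L)
})

test_that("confidence tiers: high dominates, low never used", {
  mk <- function(conf, uptake, start = 5L, end = 9L) {
    tibble::tibble(sequence = strrep("A", end - start + 1L), start = start,
                   end = end, confidence = conf, state = "s",
                   timepoint = 60, uptake = uptake)
  }
  # medium-only coverage is used; a low peptide on top is rejected
  pep <- dplyr::bind_rows(mk("medium", 50), mk("low", 90))
  m <- map_uptake(pep, 60)
  expect_equal(unique(m$uptake[m$residue %in% 5:9]), 50)
  expect_equal(unique(m$tier[m$residue %in% 5:9]), "medium")

  # adding a medium peptide never changes residues covered by a high one
  high <- mk("high", 30)
  with_med <- dplyr::bind_rows(high, mk("medium", 80))
  m_high <- map_uptake(high, 60)
  m_both <- map_uptake(with_med, 60)
  expect_equal(m_both$uptake[m_both$residue %in% 5:9],
               m_high$uptake[m_high$residue %in% 5:9])
  expect_equal(unique(m_both$tier[m_both$residue %in% 5:9]), "high")

  # low-only coverage stays missing
  m_low <- map_uptake(dplyr::bind_rows(mk("high", 30, 1L, 3L),
                                       mk("low", 90, 5L, 9L)), 60)
  expect_true(all(is.na(m_low$uptake[m_low$residue %in% 5:9])))
  expect_equal(unique(m_low$tier[m_low$residue %in% 5:9]), "none")
  expect_equal(unique(m_low$n_peptides[m_low$residue %in% 5:9]), 0L)
})

test_that("inconsistent overlapping sequences are rejected by position", {
  pep <- tibble::tibble(
    sequence = c("AAAAA", "CCCCC"), start = c(1L, 3L), end = c(5L, 7L),
    confidence = "high", state = "s", timepoint = 60, uptake = 10)
  expect_error(map_uptake(pep, 60), "residue position")
})

test_that("mixing states or asking a missing timepoint errors", {
  p <- tibble::tibble(sequence = "AAA", start = 1L, end = 3L,
                      confidence = "high", state = c("a"), timepoint = 60,
                      uptake = 10)
  expect_error(map_uptake(dplyr::bind_rows(p, dplyr::mutate(p, state = "b")),
                          60), "states")
  expect_error(map_uptake(p, 120), "timepoint")
})

test_that("the residue mean is a convex combination of peptide values", {
  set.seed(23)
  gt <- ramp_truth(1:40)
  lay <- tibble::tibble(start = c(1L, 8L, 15L, 22L, 29L, 35L, 5L, 18L),
                        end = c(10L, 17L, 24L, 31L, 38L, 40L, 20L, 33L),
                        confidence = sample(c("high", "medium"), 8, TRUE))
  pep <- make_hdx_peptides(gt, lay, noise_sd = 5, seed = 77)
  m <- map_uptake(pep, 60)
  used <- dplyr::filter(pep, timepoint == 60, confidence != "low")
  for (r in m$residue[!is.na(m$uptake)]) {
    cover <- dplyr::filter(used, start <= r, end >= r)
    tier <- if (any(cover$confidence == "high")) "high" else "medium"
    cover <- dplyr::filter(cover, confidence == tier)
    expect_gte(m$uptake[m$residue == r], min(cover$uptake) - 1e-9)
    expect_lte(m$uptake[m$residue == r], max(cover$uptake) + 1e-9)
  }
})

test_that("single-residue noise-free peptides recover the truth exactly", {
  gt <- ramp_truth(1:25)
  lay <- tibble::tibble(start = 1:25, end = 1:25, confidence = "high")
  pep <- make_hdx_peptides(gt, lay, noise_sd = 0, seed = 1)
  for (tp in c(60, 120, 600)) {
    m <- map_uptake(pep, tp)
    truth <- dplyr::filter(gt, timepoint == tp)
    expect_equal(m$uptake, truth$uptake[match(m$residue, truth$residue)])
  }
})

test_that("residue RMSE shrinks as overlap redundancy grows", {
  # flat 50% truth isolates the noise-averaging effect: more overlapping
  # peptides per residue means a smaller residue-level error. Peptide noise
  # is shared along each span, so the RMSE of a single layout is itself
  # noisy; averaging over replicate datasets (seeds derived from one master
  # seed) exposes the monotone trend.
  gt <- ramp_truth(1:60, timepoints = 60, base = 50, slope = 0)
  rmse_one <- function(redundancy, seed) {
    lay <- dplyr::bind_rows(lapply(seq_len(redundancy), function(k) {
      starts <- seq(1L, 48L, by = 4L) + (k - 1L)
      tibble::tibble(start = starts, end = pmin(60L, starts + 11L),
                     confidence = "high")
    }))
    pep <- make_hdx_peptides(gt, lay, noise_sd = 8, seed = seed)
    m <- map_uptake(pep, 60)
    sqrt(mean((m$uptake - 50)^2, na.rm = TRUE))
  }
  rmse <- vapply(1:4, function(redundancy) {
    mean(vapply(1:30, function(s) rmse_one(redundancy, 1000 + s),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("cross-timepoint summary: hand arithmetic and edge rules", {
  mk_map <- function(vals) {
    out <- tibble::tibble(residue = seq_along(vals), uptake = vals,
                          n_peptides = 1L, tier = "high")
    class(out) <- c("uptake_map", class(out))
    out
  }
  cs <- cross_timepoint_summary(mk_map(c(30, 10, NA)),
                                mk_map(c(40, 10, NA)),
                                mk_map(c(50, 10, 25)))
  expect_equal(cs$mean_uptake, c(40, 10, 25))
  expect_equal(cs$sem[1], 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(cs$sem[2], 0)
  expect_true(is.na(cs$sem[3]))  # single timepoint: SEM undefined
  expect_equal(cs$n, c(3L, 3L, 1L))
  expect_error(cross_timepoint_summary(mk_map(1:3)), "at least two")
})

test_that("difference maps subtract residue-wise and propagate missing", {
  gt_a <- ramp_truth(1:20, timepoints = 60)
  gt_b <- dplyr::mutate(gt_a, uptake = uptake - ifelse(residue >= 10, 15, 0))
  lay <- tibble::tibble(start = 1:20, end = 1:20, confidence = "high")
  ma <- map_uptake(make_hdx_peptides(gt_a, lay, state = "a"), 60)
  mb <- map_uptake(make_hdx_peptides(gt_b, lay, state = "b"), 60)
  d <- difference_map(ma, mb)
  expect_equal(d$delta, ifelse(d$residue >= 10, 15, 0))

  # identical maps -> all zero
  expect_true(all(difference_map(ma, ma)$delta == 0))

  # missing on either side -> missing in the difference
  mb_gap <- mb
  mb_gap$uptake[mb_gap$residue == 5] <- NA
  expect_true(is.na(difference_map(ma, mb_gap)$delta[5]))
})

test_that("uptake maps export to the B-factor channel and read back", {
  h <- make_helix(10)
  gt <- ramp_truth(1:10, timepoints = 60)
  lay <- tibble::tibble(start = c(1L, 6L), end = c(5L, 8L),
                        confidence = "high")
  m <- map_uptake(make_hdx_peptides(gt, lay), 60)
  path <- withr::local_tempfile(fileext = ".pdb")
  export_to_structure(m, h, path)
  back <- read_pdb(path)
  got <- dplyr::distinct(back[, c("resno", "b")])
  expect_lte(max(abs(got$b[got$resno <= 8] -
                       m$uptake[m$residue <= 8])), 0.005)
  expect_equal(unique(got$b[got$resno > 8]), 0)  # sentinel
})

test_that("peptide tables round-trip through delimited text", {
  gt <- ramp_truth(1:15)
  lay <- tibble::tibble(start = c(1L, 6L), end = c(8L, 15L),
                        confidence = c("high", "medium"))
  pep <- make_hdx_peptides(gt, lay, noise_sd = 0, seed = 5, state = "apo")
  wide <- tidyr::pivot_wider(pep, names_from = timepoint,
                             values_from = uptake, names_prefix = "uptake_")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide, path)
  back <- read_hdx_peptides(path)
  expect_equal(dplyr::arrange(back, start, timepoint)$uptake,
               dplyr::arrange(pep, start, timepoint)$uptake)
})
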