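# Kabsch-Sander secondary-structure assignment, restricted to the helix and
# turn classes (H/G/I/T; everything else, including any strand, is coded C).
# The backbone amide hydrogen is rebuilt geometrically, the electrostatic
# H-bond energy is E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
# kcal/mol, and a bond is called when E < -0.5 kcal/mol.

KS_Q <- 0.084 * 332          # 27.888 kcal/mol * Angstrom
KS_ECUT <- -0.5
CHAIN_BREAK <- 4.5           # Angstrom between consecutive Calphas

#' Assign secondary structure (helix/turn classes) to one model
#'
#' Backbone-hydrogen-bond based assignment: for each acceptor residue i and
#' n in 3, 4, 5 a turn exists when residue i+n donates to i; two consecutive
#' n-turns define 3-10 (G), alpha (H) and pi (I) helices; isolated turns are
#' T; all other residues (including any strand) are C. Residues missing a
#' backbone O are unassignable and coded C; chains are split into segments
#' wherever consecutive Calphas are more than 4.5 Angstrom apart.
#'
#' @param structure a [pdb_tbl()] or atom tibble.
#' @param model model number (default first).
#' @return tibble with `chain`, `resno`, `code` (one of H, G, I, T, C).
#' @export
#' @examples
#' table(assign_ss(make_helix(30))$code)
assign_ss <- function(structure, model = NULL) {
  m <- model %||% min(structure$model)
  atoms <- structure[structure$model == m, , drop = FALSE]
  out <- lapply(unique(atoms$chain), function(ch) {
    assign_ss_chain(atoms[atoms$chain == ch, , drop = FALSE], ch)
  })
  bind_rows(out)
}

assign_ss_chain <- function(atoms, chain_id) {
  resnos <- sort(unique(atoms$resno))
  n <- length(resnos)
  get <- function(name) {
    idx <- match(paste(resnos, name), paste(atoms$resno, atoms$atom))
    xyz <- matrix(NA_real_, n, 3)
    ok <- !is.na(idx)
    xyz[ok, ] <- coords(atoms[idx[ok], , drop = FALSE])
    xyz
  }
  N <- get("N"); CA <- get("CA"); C <- get("C"); O <- get("O")

  # segment id advances at gaps in numbering or Calpha breaks
  seg <- cumsum(c(1, (diff(resnos) != 1) |
                    (sqrt(rowSums((CA[-1, , drop = FALSE] -
                                     CA[-n, , drop = FALSE])^2)) >
                       CHAIN_BREAK)))

  # rebuilt amide H: along the sum of the N-C(prev) and N-CA unit vectors
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (seg[i] != seg[i - 1]) next
    if (anyNA(C[i - 1, ]) || anyNA(N[i, ]) || anyNA(CA[i, ])) next
    d <- vhat(N[i, ] - C[i - 1, ]) + vhat(N[i, ] - CA[i, ])
    H[i, ] <- N[i, ] + 1.01 * vhat(d)
  }
  is_pro <- atoms$resname[match(resnos, atoms$resno)] == "PRO"

  hbond <- function(don, acc) {
    # donor N-H of residue `don` to acceptor C=O of residue `acc`
    if (don < 1 || don > n || acc < 1 || acc > n) return(FALSE)
    if (anyNA(H[don, ]) || anyNA(O[acc, ]) || anyNA(C[acc, ]) ||
        anyNA(N[don, ]) || is_pro[don]) {
      return(FALSE)
    }
    r_on <- vnorm(O[acc, ] - N[don, ])
    r_ch <- vnorm(C[acc, ] - H[don, ])
    r_oh <- vnorm(O[acc, ] - H[don, ])
    r_cn <- vnorm(C[acc, ] - N[don, ])
    if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(TRUE)  # near-contact cap
    e <- KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    e < KS_ECUT
  }

  turn <- list()
  for (nn in 3:5) {
    tt <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- i + nn
      if (j > n || seg[i] != seg[j]) next
      tt[i] <- hbond(j, i)
    }
    turn[[as.character(nn)]] <- tt
  }

  code <- rep("C", n)
  mark_helix <- function(tt, nn, letter) {
    for (i in seq_len(n)) {
      if (i >= 2 && tt[i - 1] && tt[i]) {
        span <- i:min(n, i + nn - 1)
        code[span][code[span] == "C"] <<- letter
      }
    }
  }
  mark_helix(turn[["4"]], 4, "H")
  mark_helix(turn[["3"]], 3, "G")
  mark_helix(turn[["5"]], 5, "I")
  for (nn in 3:5) {
    tt <- turn[[as.character(nn)]]
    for (i in which(tt)) {
      span <- (i + 1):min(n, i + nn - 1)
      code[span][code[span] == "C"] <- "T"
    }
  }
  tibble(chain = chain_id, resno = resnos, code = code)
}

#' Binned per-residue secondary-structure content over an ensemble
#'
#' Strided snapshots are split into `n_bins` contiguous equal groups (any
#' remainder joins the last bin). For every residue, bin and code, the mean
#' fraction of snapshots carrying that code and its standard error of the
#' mean (SEM) across the bin's snapshots are reported.
#'
#' @param structure multi-model [pdb_tbl()].
#' @param stride keep every `stride`-th model before binning (default 1).
#' @param n_bins number of contiguous bins (default from `params`, 10).
#' @param params an [analysis_params()].
#' @return object of class `ss_content`: a tibble with `chain`, `resno`,
#'   `bin`, `code`, `mean_fraction`, `sem`, `n_frames`.
#' @export
binned_ss_content <- function(structure, stride = 1, n_bins = NULL,
                              params = analysis_params()) {
  n_bins <- n_bins %||% params$n_bins
  models <- sort(unique(structure$model))
  kept <- models[seq(1, length(models), by = stride)]
  if (length(kept) < n_bins) {
    stop("fewer strided frames (", length(kept), ") than bins (", n_bins,
         ")", call. = FALSE)
  }
  base <- length(kept) %/% n_bins
  sizes <- rep(base, n_bins)
  sizes[n_bins] <- sizes[n_bins] + length(kept) - base * n_bins
  if (base == 1 && sizes[n_bins] == 1) {
    warning("degenerate bins: one frame per bin, SEM reported as 0",
            call. = FALSE)
  }
  bin_of <- rep(seq_len(n_bins), sizes)

  per_frame <- lapply(kept, function(m) assign_ss(structure, model = m))
  codes <- c("H", "G", "I", "T", "C")
  long <- bind_rows(lapply(seq_along(kept), function(i) {
    f <- per_frame[[i]]
    f$bin <- bin_of[i]
    f$frame <- i
    f
  }))
  out <- long %>%
    tidyr::expand_grid(code_level = codes) %>%
    mutate(hit = as.numeric(.data$code == .data$code_level)) %>%
    group_by(.data$chain, .data$resno, .data$bin, .data$code_level) %>%
    summarise(mean_fraction = mean(.data$hit),
              sem = if (dplyr::n() > 1) sd(.data$hit) / sqrt(dplyr::n())
                else 0,
              n_frames = dplyr::n(), .groups = "drop") %>%
    rename(code = "code_level")
  class(out) <- c("ss_content", class(out))
  out
}
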