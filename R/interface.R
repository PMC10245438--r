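# Self-association interface analysis: salt bridges, polar/heavy contacts,
# T-like vs V-like residue arrangement, and steric clashes.

BASIC_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

charged_subset <- function(atoms, table, extra_oxt = FALSE) {
  keep <- rep(FALSE, nrow(atoms))
  for (rn in names(table)) {
    keep <- keep | (atoms$resname == rn & atoms$atom %in% table[[rn]])
  }
  if (extra_oxt) keep <- keep | atoms$atom == "OXT"
  atoms[keep, , drop = FALSE]
}

# Residue-pair table of minimum distances between two atom subsets.
residue_pair_min_dist <- function(a, b, cutoff) {
  if (!nrow(a) || !nrow(b)) return(empty_contact_tbl())
  d2 <- cross_dist2(coords(a), coords(b))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_contact_tbl())
  tibble(
    chain_a = a$chain[hit[, 1]], res_a = a$resno[hit[, 1]],
    name_a = a$resname[hit[, 1]],
    chain_b = b$chain[hit[, 2]], res_b = b$resno[hit[, 2]],
    name_b = b$resname[hit[, 2]],
    dist = sqrt(d2[hit])
  ) %>%
    group_by(.data$chain_a, .data$res_a, .data$name_a,
             .data$chain_b, .data$res_b, .data$name_b) %>%
    summarise(min_dist = min(.data$dist), .groups = "drop") %>%
    arrange(.data$res_a, .data$res_b)
}

empty_contact_tbl <- function() {
  tibble(chain_a = character(), res_a = integer(), name_a = character(),
         chain_b = character(), res_b = integer(), name_b = character(),
         min_dist = numeric(), kind = character())
}

#' Detect salt bridges between (or within) chains
#'
#' A salt bridge is reported when a basic-group nitrogen (Arg NE/NH1/NH2,
#' Lys NZ, His ND1/NE2 - His included since protonation at crystal pH is
#' unknown) lies within `salt_bridge_cutoff` of an acidic-group oxygen
#' (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT). With `chain_b = NULL` the
#' search runs within `chain_a` (intra-chain mode, e.g. the R112-E109 bridge
#' that forms in ApoE4), excluding same-residue pairs.
#'
#' @param chain_a,chain_b atom tibbles (heavy atoms); disjoint sets for the
#'   inter-chain mode.
#' @param params an [analysis_params()].
#' @return tibble of contact pairs: `chain_a`, `res_a`, `name_a`, `chain_b`,
#'   `res_b`, `name_b`, `min_dist`, `kind = "salt_bridge"`.
#' @export
salt_bridges <- function(chain_a, chain_b = NULL,
                         params = analysis_params()) {
  intra <- is.null(chain_b)
  if (intra) chain_b <- chain_a
  bas_a <- charged_subset(chain_a, BASIC_ATOMS)
  aci_a <- charged_subset(chain_a, ACIDIC_ATOMS, extra_oxt = TRUE)
  bas_b <- charged_subset(chain_b, BASIC_ATOMS)
  aci_b <- charged_subset(chain_b, ACIDIC_ATOMS, extra_oxt = TRUE)
  out <- bind_rows(
    residue_pair_min_dist(bas_a, aci_b, params$salt_bridge_cutoff),
    swap_roles(residue_pair_min_dist(bas_b, aci_a, params$salt_bridge_cutoff))
  )
  if (intra && nrow(out)) {
    out <- out[out$res_a != out$res_b | out$chain_a != out$chain_b, ,
               drop = FALSE]
    # keep one orientation of each intra-chain pair
    key <- paste(pmin(out$res_a, out$res_b), pmax(out$res_a, out$res_b))
    out <- out[!duplicated(key), , drop = FALSE]
  }
  if (!nrow(out)) return(empty_contact_tbl())
  out <- out %>%
    group_by(.data$chain_a, .data$res_a, .data$name_a,
             .data$chain_b, .data$res_b, .data$name_b) %>%
    summarise(min_dist = min(.data$min_dist), .groups = "drop")
  out$kind <- "salt_bridge"
  arrange(out, .data$res_a, .data$res_b)
}

# For bridges found with roles basic(B)/acidic(A), restate them with the
# first argument's chain in the *_a columns.
swap_roles <- function(tbl) {
  if (!nrow(tbl)) return(tbl)
  tibble(chain_a = tbl$chain_b, res_a = tbl$res_b, name_a = tbl$name_b,
         chain_b = tbl$chain_a, res_b = tbl$res_a, name_b = tbl$name_a,
         min_dist = tbl$min_dist)
}

#' Generic heavy-atom and polar contacts between two chains
#'
#' Heavy-atom residue pairs within `contact_cutoff`; pairs where both
#' closest atoms are nitrogen/oxygen are labelled `polar_contact`, others
#' `heavy_contact`.
#'
#' @inheritParams salt_bridges
#' @return tibble of contact pairs with `kind` column.
#' @export
contact_pairs <- function(chain_a, chain_b, params = analysis_params()) {
  a <- chain_a
  b <- chain_b
  if (!nrow(a) || !nrow(b)) return(empty_contact_tbl())
  d2 <- cross_dist2(coords(a), coords(b))
  hit <- which(d2 < params$contact_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_contact_tbl())
  polar <- c("N", "O")
  tibble(
    chain_a = a$chain[hit[, 1]], res_a = a$resno[hit[, 1]],
    name_a = a$resname[hit[, 1]],
    chain_b = b$chain[hit[, 2]], res_b = b$resno[hit[, 2]],
    name_b = b$resname[hit[, 2]],
    dist = sqrt(d2[hit]),
    polar = a$element[hit[, 1]] %in% polar &
      b$element[hit[, 2]] %in% polar
  ) %>%
    group_by(.data$chain_a, .data$res_a, .data$name_a,
             .data$chain_b, .data$res_b, .data$name_b) %>%
    summarise(min_dist = min(.data$dist),
              kind = if (any(.data$polar[which.min(.data$dist)]))
                "polar_contact" else "heavy_contact",
              .groups = "drop") %>%
    arrange(.data$res_a, .data$res_b)
}

#' Steric clashes between two atom sets
#'
#' Heavy-atom pairs closer than `clash_cutoff` (default 2.4 Angstrom, about
#' 0.6 times the summed van der Waals radii of C/N/O), aggregated per
#' residue pair with the minimum distance.
#'
#' @param part_a,part_b disjoint heavy-atom tibbles.
#' @param params an [analysis_params()].
#' @return tibble of contact pairs with `kind = "clash"`.
#' @export
detect_clashes <- function(part_a, part_b, params = analysis_params()) {
  out <- residue_pair_min_dist(part_a, part_b, params$clash_cutoff)
  if (!nrow(out)) return(empty_contact_tbl())
  out$kind <- "clash"
  out
}

#' Interface arrangement label: T-like or V-like
#'
#' Sub-classifies the residue arrangement at the self-association interface
#' independently of the packing angle: the unit is `"T-like"` when any Q123
#' side-chain heavy atom lies within `contact_cutoff` of any W39 or T42
#' heavy atom across the interface (the upward Q123 orientation stabilised
#' by W39/T42 of the partner chain), else `"V-like"`. Both chain-role
#' assignments are evaluated; T-like wins if either passes. Some V-angle
#' crystals keep the T-like arrangement - the intermediate state between the
#' two packings.
#'
#' @param chain_a,chain_b atom tibbles of the two chains.
#' @param params an [analysis_params()].
#' @return `"T-like"`, `"V-like"`, or `"undetermined"` (with a warning) when
#'   the diagnostic residues are absent.
#' @export
arrangement_label <- function(chain_a, chain_b,
                              params = analysis_params()) {
  arrangement_label_impl(chain_a, chain_b, params, warn = TRUE)
}

arrangement_label_impl <- function(chain_a, chain_b, params, warn = TRUE) {
  one_way <- function(q_side, wt_side) {
    q <- q_side[q_side$resno == 123 & q_side$resname == "GLN" &
                  !q_side$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    wt <- wt_side[(wt_side$resno == 39 & wt_side$resname == "TRP") |
                    (wt_side$resno == 42 & wt_side$resname == "THR"), ,
                  drop = FALSE]
    if (!nrow(q) || !nrow(wt)) return(NA)
    min_pair_distance(coords(q), coords(wt)) <= params$contact_cutoff
  }
  hits <- c(one_way(chain_a, chain_b), one_way(chain_b, chain_a))
  if (all(is.na(hits))) {
    if (warn) {
      warning("arrangement undetermined: Q123 and/or W39/T42 absent",
              call. = FALSE)
    }
    return("undetermined")
  }
  if (isTRUE(any(hits, na.rm = TRUE))) "T-like" else "V-like"
}
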