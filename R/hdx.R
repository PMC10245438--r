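# HDX-MS peptide -> residue uptake mapping with confidence tiers.
# Tier rule: a residue takes the average uptake of all high-confidence
# peptides covering it; where no high-confidence peptide covers it, the
# average over medium-confidence peptides; low-confidence peptides are
# never used. Peptide uptake is assigned uniformly to every residue of the
# peptide span (configurable exclusion of the span's first residues is
# available, default 0).

HDX_TIERS <- c("high", "medium", "low")

#' Read an HDX peptide table
#'
#' Delimited text with header columns `sequence`, `start`, `end`,
#' `confidence` (high/medium/low), `state`, and one `uptake_<t>` column per
#' labelling timepoint in seconds (e.g. `uptake_60`, `uptake_120`,
#' `uptake_600`), each holding % deuteration.
#'
#' @param path file path (comma- or tab-delimited; inferred from content).
#' @return tibble in long format: `sequence`, `start`, `end`, `confidence`,
#'   `state`, `timepoint` (s), `uptake` (%).
#' @export
read_hdx_peptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_hdx_peptides(pivot_uptake_long(wide))
}

pivot_uptake_long <- function(wide) {
  upt <- grep("^uptake_", names(wide), value = TRUE)
  if (!length(upt)) {
    stop("no uptake_<seconds> columns found in peptide table", call. = FALSE)
  }
  tidyr::pivot_longer(wide, dplyr::all_of(upt), names_to = "timepoint",
                      names_prefix = "uptake_", names_transform = as.numeric,
                      values_to = "uptake")
}

validate_hdx_peptides <- function(pep) {
  need <- c("sequence", "start", "end", "confidence", "state", "timepoint",
            "uptake")
  miss <- setdiff(need, names(pep))
  if (length(miss)) {
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(pep$end < pep$start)) {
    stop("peptide with end < start", call. = FALSE)
  }
  bad <- nchar(pep$sequence) != pep$end - pep$start + 1
  if (any(bad)) {
    stop("peptide sequence length != span length for peptide(s) ",
         paste(unique(pep$sequence[bad]), collapse = ", "), call. = FALSE)
  }
  if (!all(pep$confidence %in% HDX_TIERS)) {
    stop("confidence must be one of: ", paste(HDX_TIERS, collapse = ", "),
         call. = FALSE)
  }
  if (any(pep$uptake < 0, na.rm = TRUE)) {
    stop("negative % deuteration", call. = FALSE)
  }
  pep
}

# Overlapping peptides must agree on the residue letter at shared positions.
check_sequence_consistency <- function(pep) {
  expanded <- pep %>%
    distinct(.data$sequence, .data$start, .data$end) %>%
    mutate(residue = purrr::map2(.data$start, .data$end, seq),
           letter = purrr::map(.data$sequence,
                               ~ strsplit(.x, "")[[1]])) %>%
    tidyr::unnest(c("residue", "letter"))
  conflict <- expanded %>%
    distinct(.data$residue, .data$letter) %>%
    dplyr::count(.data$residue) %>%
    filter(.data$n > 1)
  if (nrow(conflict)) {
    stop("inconsistent peptide sequences at residue position(s) ",
         paste(head(conflict$residue, 5), collapse = ", "), call. = FALSE)
  }
  invisible(pep)
}

#' Map peptide-level uptake to residues at one timepoint
#'
#' @param peptides long peptide tibble (see [read_hdx_peptides()]); all rows
#'   must share one `state`.
#' @param timepoint labelling time in seconds; must be present for the
#'   peptides used.
#' @param n_term_exclusion number of residues at the start of each peptide
#'   span excluded from assignment (0, 1 or 2; default 0).
#' @return tibble of class `uptake_map`: `residue`, `uptake` (% deuteration,
#'   NA where uncovered), `n_peptides`, `tier` (high/medium/none).
#' @export
map_uptake <- function(peptides, timepoint, n_term_exclusion = 0) {
  stopifnot(n_term_exclusion %in% 0:2)
  if (length(unique(peptides$state)) > 1) {
    stop("peptides mix states: ",
         paste(unique(peptides$state), collapse = ", "),
         "; filter to one state first", call. = FALSE)
  }
  check_sequence_consistency(peptides)
  pep <- filter(peptides, .data$timepoint == !!timepoint,
                !is.na(.data$uptake))
  if (!nrow(pep)) {
    stop("timepoint ", timepoint, " s not present in peptide table",
         call. = FALSE)
  }
  span <- range(c(peptides$start, peptides$end))
  grid <- tibble(residue = seq(span[1], span[2]))

  per_res <- pep %>%
    filter(.data$confidence != "low") %>%
    mutate(first_used = .data$start + n_term_exclusion) %>%
    filter(.data$first_used <= .data$end) %>%
    mutate(residue = purrr::map2(.data$first_used, .data$end, seq)) %>%
    tidyr::unnest("residue") %>%
    group_by(.data$residue, .data$confidence) %>%
    summarise(uptake = mean(.data$uptake), n_peptides = dplyr::n(),
              .groups = "drop")

  high <- filter(per_res, .data$confidence == "high")
  med <- filter(per_res, .data$confidence == "medium",
                !.data$residue %in% high$residue)
  used <- bind_rows(mutate(high, tier = "high"),
                    mutate(med, tier = "medium")) %>%
    select("residue", "uptake", "n_peptides", "tier")
  out <- grid %>%
    left_join(used, by = "residue") %>%
    mutate(n_peptides = ifelse(is.na(.data$n_peptides), 0L,
                               .data$n_peptides),
           tier = ifelse(is.na(.data$tier), "none", .data$tier))
  attr(out, "timepoint") <- timepoint
  attr(out, "state") <- peptides$state[1]
  class(out) <- c("uptake_map", class(out))
  out
}

#' Cross-timepoint per-residue mean and SEM
#'
#' Combines residue maps from several labelling timepoints (conventionally
#' 60, 120 and 600 s) into a per-residue mean % deuteration with its
#' standard error of the mean. Residues missing at some timepoints use the
#' available ones (with `n` recording how many); SEM is NA when n = 1.
#'
#' @param ... two or more `uptake_map` objects from [map_uptake()].
#' @return tibble: `residue`, `mean_uptake`, `sem`, `n`.
#' @export
cross_timepoint_summary <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) &&
      !inherits(maps[[1]], "data.frame")) {
    maps <- maps[[1]]
  }
  if (length(maps) < 2) {
    stop("need at least two timepoint maps", call. = FALSE)
  }
  ranges <- purrr::map(maps, ~ range(.x$residue))
  if (length(unique(purrr::map_chr(ranges, paste, collapse = "-"))) != 1) {
    stop("timepoint maps cover different residue ranges", call. = FALSE)
  }
  long <- bind_rows(lapply(seq_along(maps), function(i) {
    tibble(residue = maps[[i]]$residue, uptake = maps[[i]]$uptake)
  }))
  long %>%
    group_by(.data$residue) %>%
    summarise(
      mean_uptake = if (all(is.na(.data$uptake))) NA_real_
        else mean(.data$uptake, na.rm = TRUE),
      n = sum(!is.na(.data$uptake)),
      sem = if (sum(!is.na(.data$uptake)) > 1)
        sd(.data$uptake, na.rm = TRUE) / sqrt(sum(!is.na(.data$uptake)))
        else NA_real_,
      .groups = "drop") %>%
    select("residue", "mean_uptake", "sem", "n")
}

#' Per-residue uptake difference between two states
#'
#' Delta = `state_a` - `state_b` per residue; residues missing in either map
#' are missing in the difference.
#'
#' @param state_a,state_b `uptake_map` objects on the same residue range.
#' @return tibble: `residue`, `delta` (% deuteration, positive = more uptake
#'   in `state_a`).
#' @export
difference_map <- function(state_a, state_b) {
  if (!identical(range(state_a$residue), range(state_b$residue))) {
    stop("uptake maps cover different residue ranges", call. = FALSE)
  }
  out <- tibble(residue = state_a$residue,
                delta = state_a$uptake -
                  state_b$uptake[match(state_a$residue, state_b$residue)])
  attr(out, "sign_convention") <- "state_a - state_b"
  out
}

#' Export a residue uptake map to a structure's B-factor column
#'
#' Writes the structure with each residue's mean % deuteration in the
#' B-factor field (the conventional channel for colouring structures by
#' uptake); residues without coverage receive the sentinel and are listed in
#' the returned attribute `"missing_residues"`.
#'
#' @param map an `uptake_map` from [map_uptake()] (or any tibble with
#'   `residue` and a value column).
#' @param structure a [pdb_tbl()]; residue numbering must match the map.
#' @param path output PDB path.
#' @param chain chain id the map refers to (default all chains).
#' @param value_col column of `map` holding the value (default `uptake`).
#' @param missing_sentinel B-factor for uncovered residues (default 0).
#' @return `path` invisibly, with attribute `"missing_residues"`.
#' @export
export_to_structure <- function(map, structure, path, chain = NULL,
                                value_col = "uptake", missing_sentinel = 0) {
  chains <- chain %||% unique(structure$chain)
  values <- tidyr::crossing(chain = chains,
                            tibble(resno = map$residue,
                                   value = map[[value_col]]))
  write_pdb_with_residue_values(structure, values, path,
                                missing_sentinel = missing_sentinel)
}
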