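# Numeric conventions used across the package, gathered in one object so
# every cutoff, triplet and filter setting is configurable and reported.

PARAM_DEFAULTS <- list(
  kink_triplet = c(95L, 106L, 117L),
  chi1_residue = 34L,
  n_bins = 10L,
  salt_bridge_cutoff = 4.0,
  contact_cutoff = 4.5,
  clash_cutoff = 2.4,
  t_v_boundary = 90,
  mate_search_translations = 1L,
  passband = 0.03183,
  hdx_timepoints = c(60, 120, 600)
)

#' Analysis parameters
#'
#' Collects every numeric convention the analyses use: the helix-kink Calpha
#' triplet (95, 106, 117 on helix H3), the chi1 reporter residue (W34), the
#' number of ensemble bins (10), the salt-bridge / contact / clash distance
#' cutoffs (4.0 / 4.5 / 2.4 Angstrom between heavy atoms), the T-vs-V
#' packing boundary (90 degrees on the inter-axis angle), the lattice
#' translation shell searched for symmetry mates (+-1 cell), the normalized
#' low-pass passband (0.03183, fraction of Nyquist) and the HDX labelling
#' timepoints (60, 120, 600 s).
#'
#' @param ... named overrides of the defaults listed above.
#' @return list with class `analysis_params`.
#' @export
#' @examples
#' analysis_params()
#' analysis_params(t_v_boundary = 92)
analysis_params <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PARAM_DEFAULTS))
  if (length(unknown)) stop_unknown_param(unknown)
  p <- utils::modifyList(PARAM_DEFAULTS, over)
  validate_params(p)
  structure(p, class = "analysis_params")
}

validate_params <- function(p) {
  cuts <- c(p$salt_bridge_cutoff, p$contact_cutoff, p$clash_cutoff)
  if (any(cuts <= 0)) stop("distance cutoffs must be positive", call. = FALSE)
  if (p$n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  if (p$t_v_boundary <= 75 || p$t_v_boundary >= 100) {
    stop("t_v_boundary must lie in (75, 100) degrees", call. = FALSE)
  }
  if (length(p$kink_triplet) != 3) {
    stop("kink_triplet must name exactly three residues", call. = FALSE)
  }
  if (p$passband <= 0 || p$passband >= 1) {
    stop("passband must lie in (0, 1) as a fraction of Nyquist",
         call. = FALSE)
  }
  invisible(p)
}

stop_unknown_param <- function(unknown) {
  hints <- vapply(unknown, function(k) {
    near <- agrep(k, names(PARAM_DEFAULTS), max.distance = 0.3, value = TRUE)
    if (length(near)) paste0(" (did you mean '", near[1], "'?)") else ""
  }, character(1))
  stop("unknown parameter(s): ",
       paste0("'", unknown, "'", hints, collapse = ", "),
       "; valid keys: ", paste(names(PARAM_DEFAULTS), collapse = ", "),
       call. = FALSE)
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  for (k in names(x)) {
    cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Resolve analysis parameters from defaults, a config file and overrides
#'
#' Precedence is `overrides` > `config_file` > built-in defaults. The config
#' file is plain text with one `key = value` pair per line; `#` starts a
#' comment and vector values are comma-separated
#' (e.g. `kink_triplet = 95, 106, 117`). Unknown keys are rejected with the
#' list of valid keys and a nearest-match hint.
#'
#' @param config_file optional path to a key-value config file.
#' @param overrides named list of direct overrides (highest precedence).
#' @return an [analysis_params()] object.
#' @export
resolve_params <- function(config_file = NULL, overrides = list()) {
  p <- as.list(PARAM_DEFAULTS)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    p <- utils::modifyList(p, parse_config(config_file))
  }
  unknown <- setdiff(names(overrides), names(PARAM_DEFAULTS))
  if (length(unknown)) stop_unknown_param(unknown)
  p <- utils::modifyList(p, overrides)
  do.call(analysis_params, p)
}

parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line is not 'key = value': '", ln, "'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(PARAM_DEFAULTS)) stop_unknown_param(key)
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) {
      stop("cannot parse value for '", key, "': '", val, "'", call. = FALSE)
    }
    out[[key]] <- num
  }
  out
}
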