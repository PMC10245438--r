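# Per-structure and per-ensemble helix geometry: kink angle at a Calpha
# triplet, side-chain chi1 dihedrals, and histograms over multi-model
# ensembles.

get_atom_xyz <- function(atoms, resno, name) {
  hit <- atoms[atoms$resno == resno & atoms$atom == name, , drop = FALSE]
  if (!nrow(hit)) {
    stop("atom ", name, " of residue ", resno, " not found", call. = FALSE)
  }
  as.numeric(coords(hit[1, ]))
}

#' Helix kink angle at a Calpha triplet
#'
#' The planar angle at the middle Calpha of three residues (degrees in
#' \[0, 180\]; 180 = straight helix). The default triplet (95, 106, 117)
#' spans helix H3 of the ApoE N-terminal domain, whose bending distinguishes
#' the isoforms.
#'
#' @param structure a [pdb_tbl()] or atom tibble.
#' @param chain chain id (default first chain present).
#' @param triplet three residue numbers (default from [analysis_params()]).
#' @param model model number (default first).
#' @param params an [analysis_params()] supplying the default triplet.
#' @return angle in degrees.
#' @export
#' @examples
#' kink_angle(make_helix(30), triplet = c(5, 15, 25))
kink_angle <- function(structure, chain = NULL, triplet = NULL,
                       model = NULL, params = analysis_params()) {
  triplet <- triplet %||% params$kink_triplet
  stopifnot(length(triplet) == 3)
  m <- model %||% min(structure$model)
  ch <- chain %||% structure$chain[1]
  atoms <- structure[structure$model == m & structure$chain == ch, ,
                     drop = FALSE]
  p <- lapply(triplet, function(r) get_atom_xyz(atoms, r, "CA"))
  planar_angle(p[[1]], p[[2]], p[[3]])
}

CHI1_GAMMA <- c(SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1",
                ILE = "CG1")

#' Side-chain chi1 dihedral
#'
#' The N-CA-CB-gamma dihedral of a residue, mapped to \[0, 360) degrees
#' (so the two rotamer populations of W34 read ~180 = "flip-in" and
#' ~300 = "flip-out"). The gamma atom is CG except Ser (OG), Thr (OG1),
#' Cys (SG) and Val/Ile (CG1).
#'
#' @inheritParams kink_angle
#' @param resno residue number (default the chi1 reporter residue from
#'   `params`, W34).
#' @return dihedral in degrees, \[0, 360).
#' @export
chi1 <- function(structure, chain = NULL, resno = NULL, model = NULL,
                 params = analysis_params()) {
  resno <- resno %||% params$chi1_residue
  m <- model %||% min(structure$model)
  ch <- chain %||% structure$chain[1]
  atoms <- structure[structure$model == m & structure$chain == ch &
                       structure$resno == resno, , drop = FALSE]
  if (!nrow(atoms)) {
    stop("residue ", resno, " not found in chain ", ch, call. = FALSE)
  }
  chi1_impl(atoms)
}

chi1_impl <- function(res_atoms) {
  rn <- res_atoms$resname[1]
  if (rn %in% c("GLY", "ALA")) {
    stop(rn, " has no chi1 dihedral", call. = FALSE)
  }
  gamma <- CHI1_GAMMA[rn]
  if (is.na(gamma)) gamma <- "CG"
  p <- lapply(c("N", "CA", "CB", gamma), function(a) {
    hit <- res_atoms[res_atoms$atom == a, , drop = FALSE]
    if (!nrow(hit)) {
      stop("chi1 atom ", a, " missing for residue ", res_atoms$resno[1],
           call. = FALSE)
    }
    as.numeric(coords(hit[1, ]))
  })
  wrap360(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]))
}

#' Per-frame metric series over a multi-model ensemble
#'
#' Evaluates a scalar geometric metric on every model of an ensemble and
#' summarises it as a normalized histogram. Angular metrics are binned on
#' the circle (bins anchored at 0), and the reported mode is the centre of
#' the most populated bin.
#'
#' @param structure multi-model [pdb_tbl()].
#' @param metric `"chi1"`, `"kink"`, or `"interchain_angle"`.
#' @param bin_width histogram bin width in degrees (default 10).
#' @param chain,resno,triplet forwarded to the metric (see [chi1()] and
#'   [kink_angle()]); for `"interchain_angle"`, `chains` names the two
#'   chains.
#' @param chains length-2 chain ids for `metric = "interchain_angle"`.
#' @param params an [analysis_params()].
#' @return object of class `ensemble_metric`: list with `metric`, `values`
#'   (per-frame degrees), `breaks`, `density` (normalized counts summing to
#'   1), `mode` (degrees).
#' @export
ensemble_metric <- function(structure,
                            metric = c("chi1", "kink", "interchain_angle"),
                            bin_width = 10, chain = NULL, resno = NULL,
                            triplet = NULL, chains = NULL,
                            params = analysis_params()) {
  metric <- match.arg(metric)
  models <- sort(unique(structure$model))
  values <- vapply(seq_along(models), function(i) {
    m <- models[i]
    res <- tryCatch(
      switch(metric,
             chi1 = chi1(structure, chain, resno, model = m, params = params),
             kink = kink_angle(structure, chain, triplet, model = m,
                               params = params),
             interchain_angle = {
               at <- structure[structure$model == m, , drop = FALSE]
               chs <- chains %||% unique(at$chain)[1:2]
               interchain_angle(at[at$chain == chs[1], ],
                                at[at$chain == chs[2], ])
             }),
      error = function(e) {
        stop("metric '", metric, "' failed on frame ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
    res
  }, numeric(1))

  circular <- metric == "chi1"
  top <- if (circular) 360 else 180
  breaks <- seq(0, top, by = bin_width)
  if (tail(breaks, 1) < top) breaks <- c(breaks, top)
  # snap to a 1e-6 degree grid so values sitting exactly on a bin edge are
  # assigned deterministically
  binned <- cut(round(wrap_values(values, circular), 6), breaks,
                right = FALSE, include.lowest = TRUE)
  counts <- as.numeric(table(binned))
  density <- counts / sum(counts)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  structure2 <- list(metric = metric, values = values, breaks = breaks,
                     centers = centers, density = density,
                     mode = centers[which.max(counts)],
                     n_frames = length(values), circular = circular)
  class(structure2) <- "ensemble_metric"
  structure2
}

wrap_values <- function(v, circular) {
  if (circular) wrap360(v) else pmin(180, pmax(0, v))
}

#' @export
print.ensemble_metric <- function(x, ...) {
  cat(sprintf("<ensemble_metric: %s over %d frames, mode %.1f deg>\n",
              x$metric, x$n_frames, x$mode))
  invisible(x)
}

#' Circular mean of angles in degrees
#' @param angles numeric vector of angles in degrees.
#' @return mean direction in \[0, 360).
#' @export
circular_mean <- function(angles) {
  a <- angles * DEG
  wrap360(atan2(mean(sin(a)), mean(cos(a))) / DEG)
}

#' @export
tidy.ensemble_metric <- function(x, ...) {
  tibble(frame = seq_along(x$values), value = x$values)
}

#' @export
glance.ensemble_metric <- function(x, ...) {
  tibble(metric = x$metric, n_frames = x$n_frames, mode = x$mode,
         mean = if (x$circular) circular_mean(x$values) else mean(x$values),
         sd = sd(x$values))
}
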