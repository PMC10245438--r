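# broom-style views of the analysis objects.

#' @export
tidy.principal_axes <- function(x, ...) {
  tibble(axis = 1:3,
         moment = x$moments,
         x = x$axes[1, ], y = x$axes[2, ], z = x$axes[3, ])
}

#' @export
glance.principal_axes <- function(x, ...) {
  tibble(com_x = x$center[1], com_y = x$center[2], com_z = x$center[3],
         moment_min = x$moments[1], moment_max = x$moments[3],
         anisotropy = x$moments[3] / max(x$moments[1], .Machine$double.eps))
}

#' @export
glance.ss_content <- function(x, ...) {
  h <- x[x$code == "H", , drop = FALSE]
  tibble(n_residues = length(unique(x$resno)),
         n_bins = length(unique(x$bin)),
         mean_helicity = mean(h$mean_fraction))
}
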