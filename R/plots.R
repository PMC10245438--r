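# ggplot2 views of the result types.

#' @export
autoplot.ensemble_metric <- function(object, ...) {
  df <- tibble(center = object$centers, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$breaks)[1] * 0.95,
                      fill = "grey35") +
    ggplot2::labs(x = sprintf("%s (degrees)", object$metric),
                  y = "fraction of frames",
                  title = sprintf("%s over %d frames (mode %.0f deg)",
                                  object$metric, object$n_frames,
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.uptake_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$residue, y = .data$uptake,
                               colour = .data$tier)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "residue", y = "% deuteration",
                  colour = "confidence tier",
                  title = sprintf("residue uptake, %s at %g s",
                                  attr(object, "state") %||% "",
                                  attr(object, "timepoint") %||% NA)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ss_content <- function(object, code = "H", ...) {
  df <- object[object$code == code, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno,
                                   y = .data$mean_fraction,
                                   group = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fraction - .data$sem,
                                      ymax = .data$mean_fraction + .data$sem),
                         alpha = 0.2) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "residue", y = sprintf("mean %s fraction", code)) +
    ggplot2::theme_minimal()
}

#' Plot SLS traces (raw and/or filtered)
#'
#' @param ... named trace tibbles (`time`, `intensity`); each name becomes a
#'   legend entry.
#' @return a ggplot.
#' @export
plot_sls_traces <- function(...) {
  traces <- list(...)
  nm <- names(traces) %||% paste0("trace", seq_along(traces))
  df <- bind_rows(lapply(seq_along(traces), function(i) {
    tibble(time = traces[[i]]$time, intensity = traces[[i]]$intensity,
           trace = nm[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$intensity,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "scattering intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot dimeric units as angle vs contact count
#'
#' @param dimers tibble from [find_crystal_dimers()].
#' @return a ggplot.
#' @export
plot_dimers <- function(dimers) {
  ggplot2::ggplot(dimers,
                  ggplot2::aes(x = .data$angle_deg, y = .data$n_contacts,
                               colour = .data$packing,
                               shape = .data$arrangement)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "inter-axis angle (degrees)",
                  y = "interface contacts", colour = "packing") +
    ggplot2::xlim(0, 180) +
    ggplot2::theme_minimal()
}
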