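# Static-light-scattering trace processing: zero-phase low-pass smoothing
# (8th-order Butterworth at a normalized passband, applied forward-backward
# so the DC gain is 1 and no phase lag is added) and replicate averaging.
# The Butterworth sections are designed analytically and applied in-package
# for numerically exact DC behaviour.

#' Validate and normalise an SLS trace table
#' @noRd
check_trace <- function(trace, jitter_tol = 0.01) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  if (any(diff(trace$time) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  dt <- diff(trace$time)
  if ((max(dt) - min(dt)) / stats::median(dt) > jitter_tol) {
    stop("trace sampling is non-uniform beyond ", jitter_tol * 100,
         "% jitter; resample onto a uniform grid first", call. = FALSE)
  }
  invisible(trace)
}

#' Zero-phase low-pass filtering of an aggregation trace
#'
#' Applies an 8th-order Butterworth low-pass at the given normalized
#' passband (fraction of the Nyquist frequency; default 0.03183) in a
#' forward-backward pass, which doubles the attenuation and cancels the
#' phase delay: the smoothed sigmoid is not shifted in time and constant
#' traces pass through unchanged.
#'
#' @param trace tibble with `time` (s, uniform grid) and `intensity`
#'   columns; extra columns are preserved.
#' @param passband normalized passband frequency in (0, 1) (default from
#'   `params`).
#' @param order filter order of the underlying one-way Butterworth design
#'   (default 8).
#' @param params an [analysis_params()].
#' @return the trace with `intensity` replaced by the filtered signal.
#' @export
#' @examples
#' tr <- make_sls_trace(n_points = 500, noise_sd = 0.05, seed = 1)
#' sm <- lowpass(tr)
lowpass <- function(trace, passband = NULL, order = 8,
                    params = analysis_params()) {
  passband <- passband %||% params$passband
  if (passband <= 0 || passband >= 1) {
    stop("passband must lie in (0, 1) as a fraction of Nyquist",
         call. = FALSE)
  }
  check_trace(trace)
  sos <- butter_lowpass_sos(order, passband)
  x <- trace$intensity
  # edge padding by odd reflection to suppress end transients
  npad <- min(length(x) - 1, 300)
  left <- 2 * x[1] - x[seq(npad + 1, 2)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  y <- c(left, x, right)
  for (sec in sos) {
    y <- rev(apply_biquad(sec, rev(apply_biquad(sec, y))))
  }
  trace$intensity <- y[(npad + 1):(npad + length(x))]
  trace
}

# One forward pass of a unit-DC biquad in transposed direct form II, with
# the filter state initialised to steady state for x[1] so constant signals
# pass through without any startup transient.
apply_biquad <- function(sec, x) {
  b <- sec$b; a <- sec$a
  z2 <- (b[3] - a[3]) * x[1]
  z1 <- (b[2] - a[2]) * x[1] + z2
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * yi + z2
    z2 <- b[3] * x[i] - a[3] * yi
    y[i] <- yi
  }
  y
}

# Butterworth low-pass as cascaded biquads (second-order sections): the
# analog prototype poles are paired, bilinear-transformed, and each section
# is normalised to exact unit DC gain. The cascade is numerically stable at
# low cutoffs where the single transfer-function form is not.
butter_lowpass_sos <- function(order, W) {
  if (order %% 2 != 0) stop("order must be even", call. = FALSE)
  wa <- tan(pi * W / 2)
  lapply(seq_len(order / 2), function(k) {
    theta <- pi / 2 + (2 * k - 1) * pi / (2 * order)
    p <- wa * complex(modulus = 1, argument = theta)
    a1 <- -2 * Re(p)
    a0 <- Mod(p)^2
    den0 <- 1 + a1 + a0
    a <- c(1, (2 * a0 - 2) / den0, (1 - a1 + a0) / den0)
    b <- wa^2 / den0 * c(1, 2, 1)
    b <- b * sum(a) / sum(b)          # exact unit DC gain
    list(b = b, a = a)
  })
}

#' Average replicate traces point-wise
#'
#' @param traces either a single tibble with a `replicate_id` column or a
#'   list of trace tibbles on identical time grids.
#' @param interpolate if `TRUE`, traces are linearly interpolated onto the
#'   first trace's grid before averaging; otherwise mismatched grids are an
#'   error.
#' @return tibble with `time`, `intensity` (point-wise mean), `sd`
#'   (point-wise standard deviation) and `n_replicates`.
#' @export
average_replicates <- function(traces, interpolate = FALSE) {
  if (is.data.frame(traces)) {
    if (!"replicate_id" %in% names(traces)) {
      stop("single-table input needs a replicate_id column", call. = FALSE)
    }
    traces <- split(traces, traces$replicate_id)
    traces <- lapply(traces, function(t) t[order(t$time), , drop = FALSE])
  }
  if (length(traces) < 1) stop("no traces to average", call. = FALSE)
  grid <- traces[[1]]$time
  ys <- lapply(traces, function(tr) {
    if (length(tr$time) == length(grid) &&
        max(abs(tr$time - grid)) < 1e-9) {
      return(tr$intensity)
    }
    if (!interpolate) {
      stop("trace time grids differ; pass interpolate = TRUE to resample",
           call. = FALSE)
    }
    approx(tr$time, tr$intensity, xout = grid, rule = 2)$y
  })
  ym <- do.call(cbind, ys)
  tibble(time = grid,
         intensity = rowMeans(ym),
         sd = apply(ym, 1, sd),
         n_replicates = length(ys))
}

#' Read SLS traces from delimited text
#'
#' Expects columns `time_s` (or `time`), `intensity` and optionally
#' `replicate_id` and `sample_label`.
#'
#' @param path file path (comma- or tab-delimited).
#' @return tibble with `time`, `intensity` and any extra columns.
#' @export
read_sls_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tr <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if ("time_s" %in% names(tr)) tr <- rename(tr, time = "time_s")
  stopifnot(all(c("time", "intensity") %in% names(tr)))
  tr
}
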