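# Run manifests: every report written by the command-line layer is
# accompanied by a record of the tool version, input digests and resolved
# parameters, so a result can be traced to its exact inputs and settings.

#' Build a run manifest
#'
#' @param subcommand name of the operation performed.
#' @param args named list of arguments as given.
#' @param params the resolved [analysis_params()].
#' @param inputs character vector of input file paths (digested with MD5).
#' @return list with class `run_manifest`.
#' @export
run_manifest <- function(subcommand, args = list(),
                         params = analysis_params(), inputs = character()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    setNames(as.character(d), inputs)
  } else list()
  out <- list(
    tool = "packinglens",
    version = as.character(utils::packageVersion("packinglens")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subcommand = subcommand,
    arguments = args,
    input_digests = as.list(digests),
    params = unclass(params)
  )
  class(out) <- "run_manifest"
  out
}

#' Write a manifest next to a report file
#'
#' @param manifest a [run_manifest()].
#' @param report_path the report the manifest describes; the manifest lands
#'   at `<report_path>.manifest.json`.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(manifest, report_path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing manifests requires the jsonlite package", call. = FALSE)
  }
  path <- paste0(report_path, ".manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest: %s v%s, %s at %s>\n", x$tool, x$version,
              x$subcommand, x$timestamp))
  invisible(x)
}
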