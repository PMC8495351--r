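# Run manifests: every CLI artifact is written next to a JSON manifest
# recording the command, arguments, input digests, seed and package
# version, so runs are reproducible from (seed, config, inputs).

#' Write a run manifest
#'
#' @param path manifest file path (JSON).
#' @param command subcommand name.
#' @param args named list of the arguments used.
#' @param inputs character vector of input file paths (MD5-digested).
#' @param seed seed used, or `NULL`.
#' @param outputs character vector of artifact paths the manifest covers.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, args = list(),
                               inputs = character(0), seed = NULL,
                               outputs = character(0)) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    command = command,
    args = args,
    input_digests = digests,
    seed = seed,
    package = "kfsdmi",
    version = as.character(utils::packageVersion("kfsdmi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}
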