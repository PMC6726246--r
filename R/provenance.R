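#' Run manifest for reproducible outputs
#'
#' Records the package version, the resolved parameter set, input file
#' digests and the seed(s) of a run. Re-running with the manifest's
#' parameters and seeds reproduces every output byte-for-byte (the
#' timestamp line aside).
#'
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (digested with md5).
#' @param seed integer seed(s) used.
#' @return list of class \code{run_manifest}.
#' @export
run_manifest <- function(params = list(), inputs = character(), seed = NULL) {
  digests <- if (length(inputs)) tools::md5sum(inputs) else character()
  structure(list(tool = "sexscan",
                 version = as.character(utils::packageVersion("sexscan")),
                 params = params,
                 inputs = as.list(digests),
                 seed = seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE), "\n")
  invisible(x)
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param file output path.
#' @export
write_manifest <- function(manifest, file) {
  jsonlite::write_json(unclass(manifest), file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

# Short stable hash of a parameter list for provenance headers.
param_hash <- function(params) {
  j <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  substr(unname(tools::md5sum(tf)), 1, 8)
}

#' Provenance header line for data outputs
#'
#' Every TSV/BED emitted by the pipeline begins with a single
#' '#'-prefixed comment naming the tool version and a hash of the
#' resolved parameters.
#'
#' @param params named list of parameters entering the output.
#' @return a single header string.
#' @export
provenance_header <- function(params = list()) {
  sprintf("#sexscan v%s params=%s",
          as.character(utils::packageVersion("sexscan")),
          param_hash(params))
}

#' Write a data.frame as a provenance-stamped TSV
#'
#' Tab-delimited, one '#'-prefixed provenance line followed by the
#' column-name row. Read back with \code{comment.char = "#"} ... or with
#' [read_output_tsv()].
#'
#' @param x data frame.
#' @param file output path.
#' @param params parameters recorded in the header.
#' @export
write_output_tsv <- function(x, file, params = list()) {
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a provenance-stamped TSV
#'
#' @param file path written by [write_output_tsv()].
#' @return \code{data.table}.
#' @export
read_output_tsv <- function(file) {
  data.table::fread(file, sep = "\t", skip = 1L, header = TRUE)
}
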