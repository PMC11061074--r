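#' Write a run manifest
#'
#' Records everything needed to re-run a pipeline invocation bit-identically
#' for its deterministic stages: a configuration snapshot, the seeds used,
#' MD5 digests of the input files, the package version and a timestamp.
#'
#' @param path Output JSON path.
#' @param config Configuration list (as from [load_config()]) or any
#'   serializable snapshot.
#' @param seeds Named list or vector of the seeds used.
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = NULL, seeds = NULL,
                               inputs = character()) {
  digests <- if (length(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) stop("manifest input(s) not found: ", paste(missing, collapse = ", "))
    as.list(tools::md5sum(inputs))
  } else NULL
  manifest <- list(
    package = "tdmnet",
    version = as.character(utils::packageVersion("tdmnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    inputs = digests,
    config = .manifest_sanitize(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

# Strip non-serializable pieces (grid tibbles serialize fine; drop functions).
.manifest_sanitize <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, .manifest_sanitize)
    x[!vapply(x, is.null, logical(1L))]
  } else x
}

#' Read a run manifest
#' @param path Manifest JSON path.
#' @return The manifest as a list.
#' @export
read_run_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
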