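#' Write a run summary as JSON
#'
#' Serializes a list of results together with a configuration echo
#' (parameters and seeds) so that a run can be reproduced exactly.
#' Numbers are written at full precision.
#'
#' @param x a named list (results, config echo, seeds).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
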