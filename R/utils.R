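#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish error categories.
stop_cladebench <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cladebench_error", "error")))
}

stop_lookup     <- function(msg) stop_cladebench(msg, "cladebench_lookup_error")
stop_structural <- function(msg) stop_cladebench(msg, "cladebench_structural_error")
stop_format     <- function(msg) stop_cladebench(msg, "cladebench_format_error")
stop_parameter  <- function(msg) stop_cladebench(msg, "cladebench_parameter_error")
stop_data       <- function(msg) stop_cladebench(msg, "cladebench_data_error")
stop_usage      <- function(msg) stop_cladebench(msg, "cladebench_usage_error")
stop_spec       <- function(msg) stop_cladebench(msg, "cladebench_specification_error")
stop_consistency <- function(msg) stop_cladebench(msg, "cladebench_consistency_error")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
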