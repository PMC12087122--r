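# Condition constructors used across the package. Every error inherits
# "taxoprofile_error" plus a specific class so callers (and the CLI) can map
# failures to exit codes without string matching.

stop_taxoprofile <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "taxoprofile_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

stop_parse <- function(message, ...) {
  stop_taxoprofile("taxoprofile_parse_error", message, ...)
}

stop_format <- function(message, ...) {
  stop_taxoprofile("taxoprofile_format_error", message, ...)
}

stop_structure <- function(message, ...) {
  stop_taxoprofile("taxoprofile_structure_error", message, ...)
}

stop_lookup <- function(message, taxid = NULL, ...) {
  stop_taxoprofile("taxoprofile_lookup_error", message, taxid = taxid, ...)
}

stop_validation <- function(message, ...) {
  stop_taxoprofile("taxoprofile_validation_error", message, ...)
}

stop_config <- function(message, ...) {
  stop_taxoprofile("taxoprofile_config_error", message, ...)
}

stop_data <- function(message, ...) {
  stop_taxoprofile("taxoprofile_data_error", message, ...)
}

stop_environment <- function(message, ...) {
  stop_taxoprofile("taxoprofile_environment_error", message, ...)
}

stop_filesystem <- function(message, ...) {
  stop_taxoprofile("taxoprofile_filesystem_error", message, ...)
}

stop_dependency <- function(message, ...) {
  stop_taxoprofile("taxoprofile_dependency_error", message, ...)
}
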