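# Internal helpers shared across modules.

# Condition constructor: every package error is a classed condition so
# callers (and the CLI) can map failure modes to exit codes.
gfd_error <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "gfdnet_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

# Read a text file line-wise; gzfile() transparently handles both plain
# and gzip-compressed input, which all readers accept.
read_text_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    gfd_error("gfdnet_io_error",
              sprintf("file not found or unreadable: %s", as.character(path)[1L]))
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_go_accession <- function(x) grepl("^GO:[0-9]{7}$", x)
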