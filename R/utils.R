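#' @keywords internal
"_PACKAGE"

# clamp with optional reporting of how many values hit the bounds
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
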