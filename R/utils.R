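## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
canon_u <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement in the U alphabet
#' @noRd
revcomp_u <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  rev_chars <- rev(strsplit(canon_u(x), "", fixed = TRUE)[[1L]])
  paste(chartr("ACGU", "UGCA", rev_chars), collapse = "")
}

## Polynomial rolling hash over a deparsed object; enough to
## fingerprint a run config in output headers without a hashing
## dependency. Modulus keeps the state inside exact double arithmetic.
#' @noRd
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

## Write a TSV with a single '#'-prefixed provenance comment line on top.
#' @noRd
write_commented_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_commented_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
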