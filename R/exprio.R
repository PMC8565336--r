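## Readers/writers for the plain-text formats the pipeline touches:
## FASTA for UTR sets, TSV/CSV for differential-expression tables,
## melting curves and plate tables. Delimiters are sniffed from the
## file extension (.tsv -> tab, .csv -> comma) with an explicit
## override; decimal points only.

#' @noRd
sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a 3'-UTR FASTA file
#'
#' Light validation happens line by line so malformed input is reported
#' with its line number: a first non-empty line that is not a header, a
#' header immediately followed by another header, or a trailing header
#' with no sequence all raise errors.
#'
#' @param path FASTA file path.
#' @param canonicalize Convert T->U (default TRUE). Sequences are always
#'   uppercased.
#' @return Data frame with columns `id` (first whitespace-delimited
#'   header token), `description` (remainder of the header) and
#'   `sequence`, in file order.
#' @export
read_utr_fasta <- function(path, canonicalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header", nonempty[1L]))
  headers <- which(startsWith(trimws(lines), ">"))
  nxt <- c(headers[-1L], length(lines) + 1L)
  for (k in seq_along(headers)) {
    body <- lines[setdiff(seq(headers[k] + 1L, length.out = nxt[k] - headers[k] - 1L),
                          integer(0))]
    if (sum(nchar(trimws(body))) == 0L)
      stop(sprintf("malformed FASTA at line %d: record with empty sequence",
                   headers[k]))
  }
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(set))
  if (canonicalize) seqs <- chartr("T", "U", seqs)
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a UTR set as FASTA
#'
#' @param utrs Data frame with `id`, `sequence` and optionally
#'   `description`, or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @export
write_utr_fasta <- function(utrs, path, width = 70L) {
  if (is.character(utrs))
    utrs <- data.frame(id = names(utrs), sequence = unname(utrs),
                       stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(utrs))) {
    hdr <- utrs$id[i]
    if (!is.null(utrs$description) && nzchar(utrs$description[i]))
      hdr <- paste(hdr, utrs$description[i])
    writeLines(paste0(">", hdr), con)
    s <- utrs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Default column map for differential-expression tables
#' @export
de_column_map <- function() {
  c(gene_id = "gene_id", base_mean = "base_mean",
    log2fc = "log2fc", padj = "padj")
}

#' Read a differential-expression result table
#'
#' The pipeline consumes, never produces, DE tables: one row per gene
#' with a mean expression, a log2 fold-change versus control and an
#' adjusted p-value. Rows whose log2 fold-change is not numeric (e.g.
#' `"NA"`) are dropped with a message reporting the count.
#'
#' @param path TSV or CSV path.
#' @param col_map Named character vector mapping the canonical names
#'   `gene_id`, `base_mean`, `log2fc`, `padj` to the columns present in
#'   the file; see [de_column_map()].
#' @param sep Field separator override (default: sniffed from the
#'   extension).
#' @return Data frame with canonical columns `gene_id`, `base_mean`,
#'   `log2fc`, `padj`.
#' @export
read_de_table <- function(path, col_map = de_column_map(), sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sniff_sep(path, sep),
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(unname(col_map), names(raw))
  if (length(miss))
    stop("DE table is missing mapped column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(gene_id = as.character(raw[[col_map[["gene_id"]]]]),
                    base_mean = suppressWarnings(as.numeric(raw[[col_map[["base_mean"]]]])),
                    log2fc = suppressWarnings(as.numeric(raw[[col_map[["log2fc"]]]])),
                    padj = suppressWarnings(as.numeric(raw[[col_map[["padj"]]]])),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$log2fc)
  if (any(bad)) {
    message(sum(bad), " row(s) dropped: non-numeric log2 fold-change")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a differential-expression table
#'
#' @param de Data frame with the canonical DE columns.
#' @param path Output path (`.tsv` or `.csv`).
#' @param sep Separator override.
#' @export
write_de_table <- function(de, path, sep = NULL) {
  utils::write.table(de, path, sep = sniff_sep(path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read melting curves from CSV
#'
#' Accepts either a two-column file (`temperature_C`, `absorbance`) for
#' one trace, or a long-format file with an additional `label` column
#' holding several traces.
#'
#' @param path CSV path.
#' @return A list of [melt_curve()] objects (length one for a single
#'   trace).
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("temperature_C", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("melting-curve file is missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$label)) df$label <- "trace"
  lapply(split(df, df$label), function(d)
    melt_curve(d$temperature_C, d$absorbance, label = d$label[[1L]]))
}

#' Write one or more melting curves to CSV
#' @param curves A `melt_curve` or list of them.
#' @param path Output CSV path.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(label = cv$label, temperature_C = cv$temperature,
               absorbance = cv$absorbance, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate table (qPCR or reporter) from CSV
#'
#' Thin wrapper that renames columns through a map so plate exports
#' with arbitrary headers can feed [ddct_relative_expression()] and
#' [luciferase_normalize()].
#'
#' @param path CSV/TSV path.
#' @param col_map Named character vector `canonical = file_column`; the
#'   canonical names are whatever the downstream function expects.
#' @param sep Separator override.
#' @export
read_plate_csv <- function(path, col_map = NULL, sep = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path, sep),
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    miss <- setdiff(unname(col_map), names(df))
    if (length(miss))
      stop("plate table is missing mapped column(s): ",
           paste(miss, collapse = ", "))
    df <- df[unname(col_map)]
    names(df) <- names(col_map)
  }
  df
}
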