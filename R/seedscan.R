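## Seed-match site discovery and per-transcript classification.

#' Site classes in decreasing strength order
#'
#' The canonical seed-match taxonomy: `mer8` (match to g2-g8 plus an A
#' opposite g1) > `mer7m8` (match to g2-g8) > `mer7A1` (match to g2-g7
#' plus A1) > `none`.
#'
#' @return Character vector of class names, strongest first.
#' @export
site_class_levels <- function() c("mer8", "mer7m8", "mer7A1", "none")

#' @noRd
strongest_class <- function(classes) {
  lv <- site_class_levels()
  present <- lv[lv %in% classes]
  if (length(present) == 0L) "none" else present[[1L]]
}

#' @noRd
check_utr_alphabet <- function(seq, id = NULL) {
  iupac <- "ACGUTRYSWKMBDHVN"
  bad <- grepl(sprintf("[^%s%s]", iupac, tolower(iupac)), seq)
  if (any(bad))
    stop("non-nucleotide characters in UTR sequence",
         if (!is.null(id)) paste0(" '", id[bad][1L], "'") else "")
  invisible(TRUE)
}

#' Scan one UTR for seed-match sites
#'
#' Finds all occurrences (overlapping occurrences included) of each of
#' the three canonical site strings in a 3'-UTR sequence. The sequence
#' is uppercased and T->U canonicalized before scanning; only the given
#' sense strand is scanned. A locus matching `mer8` is reported once as
#' `mer8`: the `mer7m8` prefix and `mer7A1` suffix embedded at that
#' locus are suppressed so class counts are per-locus counts of the
#' maximal class.
#'
#' @param utr A single UTR sequence (IUPAC alphabet; ambiguity codes are
#'   permitted but never matched).
#' @param sites Named site strings as from [seed_sites()], or a seed
#'   7-mer from which they are derived.
#' @param transcript_id Optional id recorded on the annotations.
#' @return Data frame with columns `transcript_id`, `class`, `start`
#'   (0-based offset of the half-open interval), `end` (exclusive),
#'   `match`. Zero rows when nothing matches or the UTR is empty.
#' @examples
#' scan_utr("GGCUCUAUAAGG", seed_sites("UAUAGAG"))
#' @export
scan_utr <- function(utr, sites, transcript_id = NA_character_) {
  stopifnot(is.character(utr), length(utr) == 1L)
  if (is.null(names(sites))) sites <- seed_sites(sites)
  stopifnot(all(c("mer8", "mer7m8", "mer7A1") %in% names(sites)))
  if (!nzchar(utr))
    return(data.frame(transcript_id = character(0), class = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  check_utr_alphabet(utr)
  u <- canon_u(utr)
  subject <- Biostrings::BString(u)
  hits <- lapply(c("mer8", "mer7m8", "mer7A1"), function(cl) {
    m <- Biostrings::matchPattern(sites[[cl]], subject, fixed = TRUE)
    data.frame(class = rep(cl, length(m)), start1 = Biostrings::start(m),
               width = Biostrings::width(m), stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  s8 <- hits$start1[hits$class == "mer8"]
  keep <- !((hits$class == "mer7m8" & hits$start1 %in% s8) |
            (hits$class == "mer7A1" & hits$start1 %in% (s8 + 1L)))
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start1,
                     match(hits$class, site_class_levels())), , drop = FALSE]
  data.frame(transcript_id = rep(transcript_id, nrow(hits)),
             class = hits$class,
             start = hits$start1 - 1L,
             end = hits$start1 - 1L + hits$width,
             match = unname(sites[hits$class]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse site annotations to a per-transcript call
#'
#' @param annotations Data frame as returned by [scan_utr()] for a
#'   single transcript.
#' @return One-row data frame: `transcript_id`, `strongest_class`,
#'   `n_mer8`, `n_mer7m8`, `n_mer7A1`.
#' @export
classify_transcript <- function(annotations) {
  ids <- unique(annotations$transcript_id)
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L)
    stop("annotations span multiple transcripts: ",
         paste(ids, collapse = ", "))
  counts <- vapply(c("mer8", "mer7m8", "mer7A1"),
                   function(cl) sum(annotations$class == cl), integer(1))
  data.frame(transcript_id = if (length(ids)) ids else NA_character_,
             strongest_class = strongest_class(annotations$class),
             n_mer8 = counts[["mer8"]], n_mer7m8 = counts[["mer7m8"]],
             n_mer7A1 = counts[["mer7A1"]], stringsAsFactors = FALSE)
}

#' Annotate a whole UTR set with seed-match calls
#'
#' Scans every record of a UTR collection for the three canonical site
#' types of a guide seed and assigns each transcript its strongest
#' class. Each FASTA record is treated as one unit; gene-level
#' collapsing, if wanted, is the caller's responsibility.
#'
#' @param utrs A FASTA path, a named character vector of sequences, or a
#'   data frame with columns `id` and `sequence` (as from
#'   [read_utr_fasta()]).
#' @param sites A seed 7-mer or named site vector (see [scan_utr()]).
#' @return Data frame with one row per transcript, in input order:
#'   `transcript_id`, `strongest_class`, `n_mer8`, `n_mer7m8`,
#'   `n_mer7A1`.
#' @export
annotate_transcriptome <- function(utrs, sites) {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- read_utr_fasta(utrs)
  if (is.character(utrs))
    utrs <- data.frame(id = names(utrs), sequence = unname(utrs),
                       stringsAsFactors = FALSE)
  stopifnot(is.data.frame(utrs), all(c("id", "sequence") %in% names(utrs)))
  dup <- utrs$id[duplicated(utrs$id)]
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(names(sites))) sites <- seed_sites(sites)
  check_utr_alphabet(utrs$sequence, utrs$id)

  set <- Biostrings::BStringSet(canon_u(utrs$sequence))
  starts <- lapply(c("mer8", "mer7m8", "mer7A1"), function(cl) {
    m <- Biostrings::vmatchPattern(sites[[cl]], set, fixed = TRUE)
    Biostrings::startIndex(m)
  })
  names(starts) <- c("mer8", "mer7m8", "mer7A1")
  n <- nrow(utrs)
  n8 <- integer(n); n7m8 <- integer(n); n7a1 <- integer(n)
  for (i in seq_len(n)) {
    s8 <- starts$mer8[[i]] %||% integer(0)
    s7m8 <- setdiff(starts$mer7m8[[i]] %||% integer(0), s8)
    s7a1 <- setdiff(starts$mer7A1[[i]] %||% integer(0), s8 + 1L)
    n8[i] <- length(s8); n7m8[i] <- length(s7m8); n7a1[i] <- length(s7a1)
  }
  strongest <- rep("none", n)
  strongest[n7a1 > 0L] <- "mer7A1"
  strongest[n7m8 > 0L] <- "mer7m8"
  strongest[n8 > 0L] <- "mer8"
  data.frame(transcript_id = utrs$id, strongest_class = strongest,
             n_mer8 = n8, n_mer7m8 = n7m8, n_mer7A1 = n7a1,
             stringsAsFactors = FALSE)
}
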