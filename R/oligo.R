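## Chemically annotated siRNA strands and duplexes.
##
## The ASCII dialect used throughout the package:
##   a c g u            2'-OMe residues
##   Af Cf Gf Uf        2'-F residues
##   A C G U            unmodified RNA residues
##   dA dC dG dT        DNA residues
##   (Agn) (Cgn) (Ggn) (Tgn)   (S)-GNA residues
##   (iCgn) (iGgn)      (S)-GNA isonucleotides (isoC, isoG)
##   s                  phosphorothioate linkage between two residues
##   L96                terminal triantennary GalNAc ligand
## Linkages not marked with "s" are phosphodiesters (PO).

.GNA_TOKENS <- c(Agn = "A", Cgn = "C", Ggn = "G", Tgn = "T",
                 iCgn = "isoC", iGgn = "isoG")

.CHEM_LEVELS <- c("2'-OMe", "2'-F", "GNA", "RNA", "DNA")

#' Parse a chemically annotated strand
#'
#' Parses the ASCII dialect described in the package overview into an
#' `oligo_strand` object: per-residue base and chemistry, per-linkage
#' PO/PS assignment, and an optional terminal GalNAc ligand (`L96`).
#' Residues are stored 5'->3' regardless of the orientation of the
#' source text; `declared_orientation` records the source convention
#' (guide strands are conventionally written 3'->5' in tabulated
#' duplexes).
#'
#' @param text Annotated strand string, e.g. `"gsuscuuacAf(Cgn)u"`.
#' @param orientation Orientation of `text`, `"5'->3'"` (default) or
#'   `"3'->5'"`.
#' @return An object of class `oligo_strand` with elements `residues`
#'   (data frame with columns `base`, `chemistry`), `linkages`
#'   (character vector of `"PO"`/`"PS"`, length `n - 1`), `ligand`
#'   (logical), `ligand_end` (`"5'"`, `"3'"` or `NA`),
#'   `declared_orientation` and `text`.
#' @examples
#' s <- parse_strand("asuscug")
#' strand_length(s)
#' s$linkages
#' @seealso [strand_to_text()], [guide_seed()], [locate_modification()]
#' @export
parse_strand <- function(text, orientation = c("5'->3'", "3'->5'")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("parse error: empty strand text")

  ligand <- FALSE
  body <- text
  if (grepl("L96$", body)) {
    ligand <- TRUE
    body <- sub("L96$", "", body)
    if (!nzchar(body)) stop("parse error: ligand with no residues")
  }
  if (grepl("L96", body, fixed = TRUE))
    stop("parse error: ligand token 'L96' only allowed at the end of the strand")

  chars <- strsplit(body, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  bases <- character(0)
  chems <- character(0)
  linkages <- character(0)
  pending_ps <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "s") {
      if (length(bases) == 0L)
        stop(sprintf("parse error at position %d: linkage token at strand start", i))
      if (pending_ps)
        stop(sprintf("parse error at position %d: consecutive linkage tokens", i))
      pending_ps <- TRUE
      i <- i + 1L
      next
    }
    if (ch == "(") {
      close <- i + 1L
      while (close <= n && chars[close] != ")") close <- close + 1L
      if (close > n)
        stop(sprintf("parse error at position %d: unterminated '('", i))
      tok <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!tok %in% names(.GNA_TOKENS))
        stop(sprintf("parse error at position %d: unknown token '(%s)'", i, tok))
      base <- .GNA_TOKENS[[tok]]
      chem <- "GNA"
      i <- close + 1L
    } else if (ch == "d") {
      if (i == n || !chars[i + 1L] %in% c("A", "C", "G", "T"))
        stop(sprintf("parse error at position %d: unknown token 'd%s'",
                     i, if (i < n) chars[i + 1L] else ""))
      base <- chars[i + 1L]
      chem <- "DNA"
      i <- i + 2L
    } else if (ch %in% c("A", "C", "G", "U")) {
      if (i < n && chars[i + 1L] == "f") {
        base <- ch
        chem <- "2'-F"
        i <- i + 2L
      } else {
        base <- ch
        chem <- "RNA"
        i <- i + 1L
      }
    } else if (ch %in% c("a", "c", "g", "u")) {
      base <- toupper(ch)
      chem <- "2'-OMe"
      i <- i + 1L
    } else {
      stop(sprintf("parse error at position %d: unknown token '%s'", i, ch))
    }
    if (length(bases) > 0L) {
      linkages <- c(linkages, if (pending_ps) "PS" else "PO")
      pending_ps <- FALSE
    }
    bases <- c(bases, base)
    chems <- c(chems, chem)
  }
  if (pending_ps)
    stop("parse error: linkage token at strand end")
  if (length(bases) == 0L)
    stop("parse error: no residues found")

  res <- data.frame(base = bases, chemistry = chems, stringsAsFactors = FALSE)
  ## store 5'->3'
  ligand_end <- NA_character_
  if (orientation == "3'->5'") {
    res <- res[rev(seq_len(nrow(res))), , drop = FALSE]
    rownames(res) <- NULL
    linkages <- rev(linkages)
    if (ligand) ligand_end <- "5'"
  } else if (ligand) {
    ligand_end <- "3'"
  }
  out <- structure(
    list(residues = res, linkages = linkages, ligand = ligand,
         ligand_end = ligand_end, declared_orientation = orientation,
         text = text),
    class = "oligo_strand")
  validate_strand(out)
  out
}

#' @noRd
validate_strand <- function(s) {
  res <- s$residues
  if (length(s$linkages) != nrow(res) - 1L)
    stop("invalid strand: linkage count must be residue count - 1")
  bad_iso <- res$base %in% c("isoC", "isoG") & res$chemistry != "GNA"
  if (any(bad_iso))
    stop("invalid strand: isoC/isoG bases require GNA chemistry")
  bad_t <- res$base == "T" & !res$chemistry %in% c("GNA", "DNA")
  if (any(bad_t))
    stop("invalid strand: base T requires GNA or DNA chemistry")
  invisible(s)
}

#' Serialize a strand back to dialect text
#'
#' Inverse of [parse_strand()]: `strand_to_text(parse_strand(x))` is the
#' identity on canonical dialect strings.
#'
#' @param strand An `oligo_strand`.
#' @param orientation Orientation to emit; defaults to the strand's
#'   declared (source) orientation.
#' @return A single string.
#' @export
strand_to_text <- function(strand,
                           orientation = strand$declared_orientation) {
  stopifnot(inherits(strand, "oligo_strand"))
  res <- strand$residues
  linkages <- strand$linkages
  if (orientation == "3'->5'") {
    res <- res[rev(seq_len(nrow(res))), , drop = FALSE]
    linkages <- rev(linkages)
  }
  tok <- character(nrow(res))
  for (k in seq_len(nrow(res))) {
    b <- res$base[k]
    chem <- res$chemistry[k]
    tok[k] <- switch(chem,
      "2'-OMe" = tolower(b),
      "2'-F"   = paste0(b, "f"),
      "RNA"    = b,
      "DNA"    = paste0("d", b),
      "GNA"    = paste0("(", names(.GNA_TOKENS)[match(b, .GNA_TOKENS)], ")"),
      stop("unknown chemistry: ", chem))
  }
  sep <- c(ifelse(linkages == "PS", "s", ""), "")
  out <- paste0(paste0(tok, sep), collapse = "")
  if (isTRUE(strand$ligand)) {
    ## the ligand is written at the end of the text in either orientation
    at_text_end <- (orientation == "5'->3'" && strand$ligand_end == "3'") ||
                   (orientation == "3'->5'" && strand$ligand_end == "5'")
    out <- if (at_text_end) paste0(out, "L96") else paste0("L96", out)
  }
  out
}

#' @export
as.character.oligo_strand <- function(x, ...) strand_to_text(x)

#' @export
print.oligo_strand <- function(x, ...) {
  n <- strand_length(x)
  cat(sprintf("<oligo_strand> %d residues (%d PS linkage%s%s), source %s\n",
              n, sum(x$linkages == "PS"),
              if (sum(x$linkages == "PS") == 1L) "" else "s",
              if (isTRUE(x$ligand)) paste0(", GalNAc at ", x$ligand_end) else "",
              x$declared_orientation))
  cat(" ", strand_to_text(x), "\n")
  invisible(x)
}

#' Number of residues in a strand
#' @param strand An `oligo_strand`.
#' @export
strand_length <- function(strand) {
  stopifnot(inherits(strand, "oligo_strand"))
  nrow(strand$residues)
}

#' Canonical base sequence of a strand
#'
#' Bases 5'->3' with chemistry stripped. With `canonical = TRUE`
#' (default) T is mapped to U and the isonucleotides to their pairing
#' parents (isoC -> C, isoG -> G), which is the alphabet used for all
#' seed and site arithmetic.
#'
#' @param strand An `oligo_strand`.
#' @param canonical Canonicalize to the U alphabet?
#' @param collapse Return a single string (default) or a vector.
#' @export
strand_bases <- function(strand, canonical = TRUE, collapse = TRUE) {
  stopifnot(inherits(strand, "oligo_strand"))
  b <- strand$residues$base
  if (canonical) {
    b[b == "isoC"] <- "C"
    b[b == "isoG"] <- "G"
    b[b == "T"] <- "U"
  }
  if (collapse) paste(b, collapse = "") else b
}

#' Positions of residues with a given chemistry
#'
#' Returns the 1-based positions, counted from the 5' end of the guide
#' (g1, g2, ...), of all residues carrying the requested chemistry.
#'
#' @param strand An `oligo_strand`.
#' @param chemistry One of `"2'-OMe"`, `"2'-F"`, `"GNA"`, `"RNA"`,
#'   `"DNA"`. Default `"GNA"`.
#' @return Integer vector of positions (empty if none).
#' @export
locate_modification <- function(strand, chemistry = "GNA") {
  stopifnot(inherits(strand, "oligo_strand"))
  chemistry <- match.arg(chemistry, .CHEM_LEVELS)
  which(strand$residues$chemistry == chemistry)
}

#' Extract the guide-strand seed
#'
#' The seed is the block of guide positions `g_start`..`g_end`
#' (defaults 2..8, i.e. g2-g8), numbered 1-based from the 5' end, with
#' chemistry stripped and bases canonicalized to the U alphabet.
#'
#' @param guide An `oligo_strand` (stored 5'->3').
#' @param g_start,g_end Seed window, `1 <= g_start <= g_end <= length`
#'   (a degenerate `g_start == g_end` window gives a single base).
#' @return Uppercase base string of length `g_end - g_start + 1`.
#' @examples
#' guide <- parse_strand("gsuscuuacAfcUfuucaGfUfaGfcugsUfsu",
#'                       orientation = "3'->5'")
#' guide_seed(guide)  # "UGUCGAU"
#' @export
guide_seed <- function(guide, g_start = 2L, g_end = 8L) {
  stopifnot(inherits(guide, "oligo_strand"))
  n <- strand_length(guide)
  if (!(g_start >= 1L && g_start <= g_end))
    stop("invalid seed window: need 1 <= g_start <= g_end")
  if (g_end > n)
    stop(sprintf("guide too short for seed window: length %d < g_end %d", n, g_end))
  b <- strand_bases(guide, canonical = TRUE, collapse = FALSE)
  paste(b[g_start:g_end], collapse = "")
}

#' Canonical target-site sequences for a seed
#'
#' Given the g2-g8 seed 7-mer, derives the three canonical target-site
#' strings on the mRNA sense strand, 5'->3':
#' * `mer7m8`: reverse complement of g2-g8;
#' * `mer8`: `mer7m8` followed by `A` (the A1 convention: an adenosine
#'   opposite g1 regardless of the g1 identity);
#' * `mer7A1`: reverse complement of g2-g7 followed by `A`.
#'
#' By construction `mer8` minus its first base equals `mer7A1` and the
#' first 7 bases of `mer8` equal `mer7m8`.
#'
#' @param seed Seed 7-mer (U alphabet; T accepted and canonicalized).
#' @return Named character vector with elements `mer8`, `mer7m8`,
#'   `mer7A1`.
#' @examples
#' seed_sites("UAUAGAG")
#' @export
seed_sites <- function(seed) {
  stopifnot(is.character(seed), length(seed) == 1L)
  seed <- canon_u(seed)
  if (nchar(seed) != 7L)
    stop("seed must be the g2-g8 7-mer (got length ", nchar(seed), ")")
  if (grepl("[^ACGU]", seed))
    stop("seed contains non-ACGU characters")
  mer7m8 <- revcomp_u(seed)
  c(mer8   = paste0(mer7m8, "A"),
    mer7m8 = mer7m8,
    mer7A1 = paste0(revcomp_u(substr(seed, 1L, 6L)), "A"))
}

#' Build an siRNA duplex
#'
#' Pairs a passenger and a guide strand. Complementarity over the paired
#' region (guide position i against passenger position `L_p - i + 1`,
#' for i up to the passenger length) is checked in the canonical U
#' alphabet; a mismatch fraction above `mismatch_tol` raises a warning,
#' not an error, since modified duplexes may deliberately carry
#' non-canonical pairs.
#'
#' @param passenger,guide `oligo_strand` objects.
#' @param name Duplex label, e.g. `"D1"`.
#' @param target Target gene label.
#' @param mismatch_tol Warning threshold on the mismatch fraction.
#' @return An object of class `oligo_duplex`.
#' @export
duplex <- function(passenger, guide, name = "", target = "",
                   mismatch_tol = 0.2) {
  stopifnot(inherits(passenger, "oligo_strand"),
            inherits(guide, "oligo_strand"))
  pb <- strand_bases(passenger, collapse = FALSE)
  gb <- strand_bases(guide, collapse = FALSE)
  np <- length(pb)
  k <- min(np, length(gb))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mism <- sum(comp[gb[seq_len(k)]] != pb[np - seq_len(k) + 1L]) / k
  if (mism > mismatch_tol)
    warning(sprintf("duplex %s: %.0f%% mismatches over the paired region",
                    name, 100 * mism))
  structure(list(passenger = passenger, guide = guide, name = name,
                 target = target, mismatch_fraction = mism),
            class = "oligo_duplex")
}

#' @export
print.oligo_duplex <- function(x, ...) {
  cat(sprintf("<oligo_duplex> %s (target %s)\n", x$name, x$target))
  cat("  passenger:", strand_to_text(x$passenger), "\n")
  cat("  guide    :", strand_to_text(x$guide), "\n")
  invisible(x)
}

#' Read a duplex fixture table
#'
#' Reads a TSV with columns `duplex_id`, `target`, `passenger_5to3`,
#' `guide_3to5` (strands in the ASCII dialect, guides written 3'->5')
#' and parses each row into an [duplex()] object.
#'
#' @param path Path to the TSV file.
#' @return Named list of `oligo_duplex` objects, in file order.
#' @export
read_duplex_table <- function(path) {
  df <- read_commented_tsv(path)
  need <- c("duplex_id", "target", "passenger_5to3", "guide_3to5")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("duplex table is missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    duplex(parse_strand(df$passenger_5to3[i], orientation = "5'->3'"),
           parse_strand(df$guide_3to5[i], orientation = "3'->5'"),
           name = df$duplex_id[i], target = df$target[i])
  })
  names(out) <- df$duplex_id
  out
}

#' Bundled GalNAc-siRNA duplex fixtures (D1-D12)
#'
#' Transcriptions of the twelve GalNAc-siRNA conjugate duplexes used
#' throughout the package examples and tests: four parent sequences
#' (D1, D4, D7, D10) targeting Hao1, Ttr, F12 and Ttr, each with a
#' GNA-modified sibling (D2, D5, D8, D11) and a GNA-isonucleotide
#' sibling (D3, D6, D9, D12) at the same seed position.
#'
#' @return Named list of `oligo_duplex` objects.
#' @export
galnac_duplexes <- function() {
  read_duplex_table(system.file("extdata", "galnac_duplexes.tsv",
                                package = "seedshift", mustWork = TRUE))
}

#' Bundled melting-temperature fixture for D1-D12
#'
#' Measured duplex melting temperatures (mean of two independent UV
#' melts at 1 uM duplex in 0.1x PBS) together with the parent and
#' reference maps used by [delta_tm_table()]: each modified duplex
#' points to its unmodified parent, and each isonucleotide duplex
#' references its native-GNA sibling.
#'
#' @return Data frame with columns `duplex_id`, `target`, `tm_c`,
#'   `tm_sd`, `parent_id`, `reference_id`.
#' @export
galnac_duplex_tm <- function() {
  read_commented_tsv(system.file("extdata", "galnac_duplex_tm.tsv",
                                 package = "seedshift", mustWork = TRUE))
}
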