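## Theoretical metabolite ladders and mass accounting for modified
## guide strands.
##
## Masses are computed from elemental compositions. A strand with n
## residues, hydroxyl termini and n-1 phosphodiester bridges has
## formula sum(nucleosides) + (n-1) (HPO3 - H2O); each phosphorothioate
## substitutes one sulfur for one oxygen on its bridge. The
## isonucleotides isoC/isoG are constitutional isomers of C/G and share
## their formulas.

## atomic masses (CODATA/IUPAC)
.ATOM_MONO <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                F = 18.99840322)
.ATOM_AVG <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
               P = 30.973762, S = 32.065, F = 18.9984032)

## formulas as atom-count vectors
#' @noRd
.formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0, F = 0)
  c(C = C, H = H, N = N, O = O, P = P, S = S, F = F)

#' @noRd
.formula_mass <- function(f, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  tbl <- if (kind == "monoisotopic") .ATOM_MONO else .ATOM_AVG
  sum(f * tbl[names(f)])
}

## nucleobase and sugar building blocks; nucleoside = base + sugar - H2O
.BASES <- list(
  A = .formula(C = 5, H = 5, N = 5),
  G = .formula(C = 5, H = 5, N = 5, O = 1),
  C = .formula(C = 4, H = 5, N = 3, O = 1),
  U = .formula(C = 4, H = 4, N = 2, O = 2),
  T = .formula(C = 5, H = 6, N = 2, O = 2),
  isoC = .formula(C = 4, H = 5, N = 3, O = 1),
  isoG = .formula(C = 5, H = 5, N = 5, O = 1))
.SUGARS <- list(
  "RNA"    = .formula(C = 5, H = 10, O = 5),          # ribose
  "2'-OMe" = .formula(C = 6, H = 12, O = 5),
  "2'-F"   = .formula(C = 5, H = 9, O = 4, F = 1),
  "DNA"    = .formula(C = 5, H = 10, O = 4),
  "GNA"    = .formula(C = 3, H = 8, O = 3))           # propylene glycol
.H2O <- .formula(H = 2, O = 1)
.HPO3 <- .formula(H = 1, P = 1, O = 3)

## Approximate mass of the triantennary GalNAc (L96) ligand including
## its phosphodiester attachment; configurable through the table.
.GALNAC_MONO <- 2004.9
.GALNAC_AVG <- 2006.2

#' Residue mass table
#'
#' Masses of every (base, chemistry) residue the dialect parser can
#' emit, computed from elemental compositions (nucleoside = base +
#' sugar - H2O), along with the phosphodiester bridge (`HPO3 - H2O`),
#' the sulfur-for-oxygen phosphorothioate increment, and the terminal
#' GalNAc ligand contribution (approximate, overridable).
#'
#' @param galnac_mono,galnac_avg Ligand mass override (Da).
#' @return List with `residues` (data frame: `base`, `chemistry`,
#'   `monoisotopic`, `average`), `po_bridge_mono`, `po_bridge_avg`,
#'   `ps_delta_mono`, `ps_delta_avg`, `galnac_mono`, `galnac_avg`.
#' @export
residue_mass_table <- function(galnac_mono = .GALNAC_MONO,
                               galnac_avg = .GALNAC_AVG) {
  valid <- list(
    c("A", "RNA"), c("C", "RNA"), c("G", "RNA"), c("U", "RNA"),
    c("A", "2'-OMe"), c("C", "2'-OMe"), c("G", "2'-OMe"), c("U", "2'-OMe"),
    c("A", "2'-F"), c("C", "2'-F"), c("G", "2'-F"), c("U", "2'-F"),
    c("A", "DNA"), c("C", "DNA"), c("G", "DNA"), c("T", "DNA"),
    c("A", "GNA"), c("C", "GNA"), c("G", "GNA"), c("T", "GNA"),
    c("isoC", "GNA"), c("isoG", "GNA"))
  rows <- lapply(valid, function(v) {
    f <- .BASES[[v[1]]] + .SUGARS[[v[2]]] - .H2O
    data.frame(base = v[1], chemistry = v[2],
               monoisotopic = .formula_mass(f, "monoisotopic"),
               average = .formula_mass(f, "average"),
               stringsAsFactors = FALSE)
  })
  bridge <- .HPO3 - .H2O
  list(residues = do.call(rbind, rows),
       po_bridge_mono = .formula_mass(bridge, "monoisotopic"),
       po_bridge_avg = .formula_mass(bridge, "average"),
       ps_delta_mono = .ATOM_MONO[["S"]] - .ATOM_MONO[["O"]],
       ps_delta_avg = .ATOM_AVG[["S"]] - .ATOM_AVG[["O"]],
       galnac_mono = galnac_mono, galnac_avg = galnac_avg)
}

#' Mass of a strand
#'
#' Sum of nucleoside masses, phosphodiester bridges, phosphorothioate
#' sulfur increments and, if present and requested, the terminal GalNAc
#' ligand. Termini are hydroxyl.
#'
#' @param strand An `oligo_strand`.
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @param table A [residue_mass_table()].
#' @param include_ligand Include the GalNAc contribution when the
#'   strand carries one?
#' @return Mass in Da.
#' @export
strand_mass <- function(strand, kind = c("monoisotopic", "average"),
                        table = residue_mass_table(),
                        include_ligand = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(strand, "oligo_strand"))
  res <- strand$residues
  if (nrow(res) == 0L) stop("strand_mass: empty strand")
  key <- paste(res$base, res$chemistry)
  tabkey <- paste(table$residues$base, table$residues$chemistry)
  hit <- match(key, tabkey)
  if (anyNA(hit))
    stop("strand_mass: mass table does not cover residue ",
         key[which(is.na(hit))[1L]])
  col <- if (kind == "monoisotopic") "monoisotopic" else "average"
  bridge <- if (kind == "monoisotopic") table$po_bridge_mono else table$po_bridge_avg
  psd <- if (kind == "monoisotopic") table$ps_delta_mono else table$ps_delta_avg
  m <- sum(table$residues[[col]][hit]) +
    (nrow(res) - 1L) * bridge + sum(strand$linkages == "PS") * psd
  if (include_ligand && isTRUE(strand$ligand))
    m <- m + if (kind == "monoisotopic") table$galnac_mono else table$galnac_avg
  m
}

#' @noRd
substrand <- function(strand, from, to) {
  res <- strand$residues[from:to, , drop = FALSE]
  rownames(res) <- NULL
  linkages <- if (to > from) strand$linkages[from:(to - 1L)] else character(0)
  n <- strand_length(strand)
  keep_ligand <- isTRUE(strand$ligand) &&
    ((identical(strand$ligand_end, "3'") && to == n) ||
     (identical(strand$ligand_end, "5'") && from == 1L))
  structure(list(residues = res, linkages = linkages,
                 ligand = keep_ligand,
                 ligand_end = if (keep_ligand) strand$ligand_end else NA_character_,
                 declared_orientation = "5'->3'",
                 text = NA_character_),
            class = "oligo_strand")
}

#' Theoretical single-sided truncation ladder
#'
#' All exonucleolytic single-sided truncation products of a strand:
#' the full-length species plus every `3'N-k` (k residues lost from the
#' 3' end) and `5'N-k` species, `k = 1 .. n-1`, for `2(n-1) + 1`
#' entries in deterministic order. Residue spans are 1-based inclusive
#' on the parent; each entry carries its theoretical mass. A terminal
#' GalNAc ligand is retained only while its end is intact.
#'
#' @param strand An `oligo_strand` of length >= 2.
#' @param kind Mass kind, see [strand_mass()].
#' @param table A [residue_mass_table()].
#' @return Data frame with columns `kind`, `span_start`, `span_end`,
#'   `length`, `mass`.
#' @export
truncation_ladder <- function(strand, kind = c("monoisotopic", "average"),
                              table = residue_mass_table()) {
  kind <- match.arg(kind)
  stopifnot(inherits(strand, "oligo_strand"))
  n <- strand_length(strand)
  if (n < 2L) stop("truncation_ladder: strand must have >= 2 residues")
  entry <- function(lab, from, to)
    data.frame(kind = lab, span_start = from, span_end = to,
               length = to - from + 1L,
               mass = strand_mass(substrand(strand, from, to), kind = kind,
                                  table = table),
               stringsAsFactors = FALSE)
  rows <- list(entry("full_length", 1L, n))
  for (k in seq_len(n - 1L))
    rows[[length(rows) + 1L]] <- entry(sprintf("3'N-%d", k), 1L, n - k)
  for (k in seq_len(n - 1L))
    rows[[length(rows) + 1L]] <- entry(sprintf("5'N-%d", k), k + 1L, n)
  do.call(rbind, rows)
}

#' Active guide-strand fraction
#'
#' The active fraction of a detected guide-strand metabolite pool:
#' by default the full-length plus 3'N-1 species (loss of a single 3'
#' residue leaves a loadable guide), as a percentage of the total
#' abundance. Invariant under rescaling all abundances by a positive
#' constant.
#'
#' @param abundances Named numeric vector (or data frame with columns
#'   `metabolite_kind`, `abundance`) of relative abundances; names are
#'   metabolite kinds as in [truncation_ladder()].
#' @param active_kinds Metabolite kinds counted as active.
#' @return Percent active, in `[0, 100]`.
#' @examples
#' active_fraction(c(full_length = 0.50, `3'N-1` = 0.18, `5'N-8` = 0.32))
#' @export
active_fraction <- function(abundances,
                            active_kinds = c("full_length", "3'N-1")) {
  if (is.data.frame(abundances)) {
    stopifnot(all(c("metabolite_kind", "abundance") %in% names(abundances)))
    abundances <- stats::setNames(abundances$abundance,
                                  abundances$metabolite_kind)
  }
  stopifnot(is.numeric(abundances), !is.null(names(abundances)))
  if (any(abundances < 0)) stop("active_fraction: negative abundance")
  total <- sum(abundances)
  if (total <= 0) stop("active_fraction: total abundance is zero")
  100 * sum(abundances[names(abundances) %in% active_kinds]) / total
}
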