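## Independent oracles used across the suite. These deliberately avoid
## the package's own code paths.

## --- Exhaustive permutation oracle for the two-sample KS test ---------
## p = fraction of all C(N, n1) relabelings whose D statistic is >= the
## observed one. Valid for continuous (untied) samples.
perm_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  Dstat <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  d0 <- Dstat(x, y)
  idx <- utils::combn(length(pooled), n1)
  ds <- apply(idx, 2, function(i) Dstat(pooled[i], pooled[-i]))
  mean(ds >= d0 - 1e-12)
}

## --- Elemental-composition oracle for strand masses -------------------
## Builds the atom inventory of a strand from scratch (base + sugar -
## H2O per nucleoside, HPO3 - H2O per bridge, S-for-O per
## phosphorothioate) and sums atomic masses. Compositions and masses
## are typed here independently of the package's table.
oracle_atoms <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                  O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                  Fl = 18.99840322)
oracle_base_atoms <- list(
  A    = c(C = 5, H = 5, N = 5, O = 0),
  G    = c(C = 5, H = 5, N = 5, O = 1),
  C    = c(C = 4, H = 5, N = 3, O = 1),
  U    = c(C = 4, H = 4, N = 2, O = 2),
  T    = c(C = 5, H = 6, N = 2, O = 2),
  isoC = c(C = 4, H = 5, N = 3, O = 1),
  isoG = c(C = 5, H = 5, N = 5, O = 1))
oracle_sugar_atoms <- list(
  "RNA"    = c(C = 5, H = 10, O = 5),
  "2'-OMe" = c(C = 6, H = 12, O = 5),
  "2'-F"   = c(C = 5, H = 9, O = 4, Fl = 1),
  "DNA"    = c(C = 5, H = 10, O = 4),
  "GNA"    = c(C = 3, H = 8, O = 3))

oracle_strand_mass <- function(strand) {
  atoms <- c(H = 0, C = 0, N = 0, O = 0, P = 0, S = 0, Fl = 0)
  add <- function(a, v, k = 1) {
    a[names(v)] <- a[names(v)] + k * v
    a
  }
  res <- strand$residues
  for (i in seq_len(nrow(res))) {
    atoms <- add(atoms, oracle_base_atoms[[res$base[i]]])
    atoms <- add(atoms, oracle_sugar_atoms[[res$chemistry[i]]])
    atoms <- add(atoms, c(H = 2, O = 1), k = -1)        # glycosidic bond
  }
  nb <- nrow(res) - 1L
  atoms <- add(atoms, c(H = 1, P = 1, O = 3), k = nb)   # bridges
  atoms <- add(atoms, c(H = 2, O = 1), k = -nb)         # condensation
  nps <- sum(strand$linkages == "PS")
  atoms <- add(atoms, c(S = 1), k = nps)
  atoms <- add(atoms, c(O = 1), k = -nps)
  sum(atoms * oracle_atoms[names(atoms)])
}

## --- Random canonical dialect strings for round-trip properties -------
random_strand_text <- function(min_len = 2L, max_len = 25L,
                               p_ligand = 0.3) {
  tokens <- c("a", "c", "g", "u", "A", "C", "G", "U",
              "Af", "Cf", "Gf", "Uf", "dA", "dC", "dG", "dT",
              "(Agn)", "(Cgn)", "(Ggn)", "(Tgn)", "(iCgn)", "(iGgn)")
  n <- sample(min_len:max_len, 1L)
  tok <- sample(tokens, n, replace = TRUE)
  sep <- sample(c("", "s"), n - 1L, replace = TRUE, prob = c(0.7, 0.3))
  paste0(paste0(tok[-n], sep, collapse = ""), tok[n],
         if (stats::runif(1) < p_ligand) "L96" else "")
}

## Simple overlapping substring scan used as an independent check on
## the Biostrings-backed scanner.
naive_site_scan <- function(utr, site) {
  u <- chartr("Tt", "Uu", toupper(utr))
  k <- nchar(site)
  if (nchar(u) < k) return(integer(0))
  starts <- which(vapply(seq_len(nchar(u) - k + 1L),
                         function(i) substr(u, i, i + k - 1L) == site,
                         logical(1)))
  starts
}
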