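# seedshift

Seed-match specificity and pharmacology analysis for chemically
modified, GalNAc-conjugated siRNAs.

## The problem

siRNAs silence their intended target through full-length pairing, but
guide-strand positions 2–8 (the *seed*, g2–g8) can also pair with
3′-UTR sites of unrelated transcripts and repress them through a
miRNA-like mechanism. Placing a single thermally destabilizing glycol
nucleic acid (GNA) residue — or one of its isonucleotides isoC/isoG,
which restore pairing in GNA's rotated, reverse-Watson–Crick base
orientation — in the seed mitigates these off-targets at some cost in
duplex stability and metabolic behaviour. Assessing such designs needs
four kinds of quantitative bookkeeping, which this package provides
for computational chemists and RNAi pharmacologists:

1. **Off-target arm** — parse annotated duplexes, derive the seed and
   its canonical target-site classes (`mer8` = match to g2–g8 plus an
   A opposite g1 > `mer7m8` = match to g2–g8 > `mer7A1` = match to
   g2–g7 plus A1), scan a UTR set, and quantify repression as the
   signed maximal vertical ECDF difference (*CDF-shift delta*) of
   log2 fold-changes for each site class versus the no-site
   background, with KS and rank-sum tests and a
   delta-versus-knockdown dose profile.
2. **Thermal arm** — first-derivative melting temperatures from UV
   melting curves (local-polynomial smoothing, central differences,
   quadratic peak refinement), plus ΔTm (modified − parent) and ΔΔTm
   (iso − native) tables.
3. **Pharmacodynamic arm** — ΔΔCt relative expression
   (`2^−ΔΔCt`), dual-luciferase Renilla/Firefly normalization, percent
   silencing.
4. **Metabolite arm** — theoretical truncation ladders with
   elemental-composition masses and the active-guide fraction
   (full-length + 3′N−1 over total).

A deterministic synthetic-data generator (`sim_config()`,
`generate_utr_set()`, `simulate_study()`) produces study-shaped inputs
for every arm — planted seed sites, Hill-type on-target dose response,
two-state van't Hoff melting curves, qPCR and reporter plates — so the
whole pipeline runs and is tested without external data. Twelve
transcribed GalNAc-siRNA duplexes (D1–D12, targeting Hao1, Ttr and
F12) ship as fixtures.

## Worked example

```r
library(seedshift)

dups  <- galnac_duplexes()        # bundled duplex fixtures D1-D12
guide <- dups$D1$guide            # parent siRNA guide, stored 5'->3'
guide_seed(guide)                 # "UGUCGAU"
seed_sites(guide_seed(guide))
#>       mer8     mer7m8     mer7A1
#> "AUCGACAA"  "AUCGACA"  "UCGACAA"
locate_modification(dups$D2$guide)   # GNA-C sits at g5 in D2

## Delta-Tm bookkeeping from measured Tm values
delta_tm_table(galnac_duplex_tm())[1:3, c("duplex_id","tm_c","delta_tm_r","ddelta_tm_r")]
#>   duplex_id tm_c delta_tm_r ddelta_tm_r
#> 1        D1 66.5         NA          NA
#> 2        D2 58.6       -7.9          NA
#> 3        D3 61.1       -5.4         2.5

## Off-target analysis on a synthetic transcriptome
cfg <- sim_config(seed = 42L, n_transcripts = 2000L)
sim <- generate_utr_set(cfg, guide_seed(guide))
de  <- setNames(lapply(cfg$doses, \(d) simulate_de_table(sim, d)), cfg$doses)
run <- run_specificity(guide, sim$utrs, de)
run$shifts[["10"]]
#> Stratified CDF shifts vs background (n_bg = 1247 genes without seed match)
#>   class n_fg n_bg  delta      ks_p ranksum_p mean_diff flag
#>    mer8  362 1247 0.5497 0.000e+00 3.861e-89   -0.3582
#>  mer7m8  207 1247 0.3690 0.000e+00 3.100e-27   -0.2247
#>  mer7A1  184 1247 0.2610 6.494e-10 3.436e-13   -0.1441
run$profile
#> CDF shift vs on-target knockdown profile
#>  dose   delta knockdown
#>   0.1 0.06278   0.08276
#>   1.0 0.34454   0.26240
#>  10.0 0.54966   0.76457
#>  50.0 0.55758   0.85075
#> Spearman rho = 1.000 (n = 4 doses)
```

Read: at the 10 nM dose, transcripts whose strongest 3′-UTR site is a
mer8 have their log2 fold-change ECDF shifted toward repression by
0.55 relative to background (mer8 > mer7m8 > mer7A1, as the planted
effect sizes dictate), and the mer8 shift rises monotonically with
on-target knockdown across the dose series — the signature of a
parent-like, seed-active siRNA. Setting the generator's effect sizes
to zero (a seed-destabilized design) flattens the profile near zero.

`percent_silencing(0.13)` returns 87; `active_fraction(c(full_length
= 0.50, "3'N-1" = 0.18, "5'N-10" = 0.32))` returns 68. A thin CLI over
the same functions lives in `inst/scripts/seedshift.R` (subcommands
`simulate`, `specificity`, `tm-table`).

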