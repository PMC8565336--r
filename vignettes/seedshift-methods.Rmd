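---
title: "Methods and models behind seedshift"
author: "seedshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind seedshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
```

seedshift analyses the off-target specificity and pharmacology of
chemically modified, GalNAc-conjugated siRNAs. This vignette explains
the models the package implements, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the
numerical and design choices a maintainer would want written down.

## Strand notation and seed arithmetic

Fully modified GalNAc-siRNAs mix 2'-OMe and 2'-F ribose chemistry,
phosphorothioate (PS) linkages at the strand ends, and optionally a
single glycol nucleic acid (GNA) residue in the guide seed. Publication
typography (italics, bold, bullet symbols) cannot survive plain text,
so the package defines an ASCII dialect: lowercase `acgu` for 2'-OMe,
`Af Cf Gf Uf` for 2'-F, parenthesised tokens `(Cgn)`, `(iGgn)`, ... for
(S)-GNA residues and the isonucleotides, `s` for a PS linkage, and a
trailing `L96` for the triantennary GalNAc ligand. Plain uppercase and
`dN` tokens for unmodified RNA/DNA are accepted as an extension. Twelve
duplex transcriptions (D1-D12: four parent sequences against Hao1,
Ttr and F12, each with a native-GNA and an iso-GNA sibling) ship in
`inst/extdata/` and are returned by `galnac_duplexes()`.

Guides in tabulated duplexes are conventionally written 3'&rarr;5';
`parse_strand(orientation = "3'->5'")` stores them 5'&rarr;3' and all
position reporting is 1-based from the 5' end (g1, g2, ...). For
sequence arithmetic, bases are canonicalized to the U alphabet with
the isonucleotides mapped to their pairing parents (isoC&rarr;C,
isoG&rarr;G), since isoC pairs G and isoG pairs C in the
reverse-Watson-Crick mode that motivates them.

The seed is guide positions g2-g8. The three canonical target-site
classes on the mRNA sense strand are

* `mer7m8` = reverse complement of g2-g8,
* `mer8` = `mer7m8` + `A`,
* `mer7A1` = reverse complement of g2-g7 + `A`,

with the A1 convention that position 1 of the site is adenosine
regardless of the g1 identity. Note that the bundled D10-D12 duplexes
illustrate why the convention matters: their target carries U, not A,
opposite g1, so their on-target site is a `mer7m8`, and the mer8 string
derived from the guide seed genuinely does not occur in the printed
passenger.

## UTR scanning and the strongest-match call

`scan_utr()`/`annotate_transcriptome()` find every occurrence
(overlaps included) of the three site strings in T&rarr;U-canonicalized
UTRs; only the given sense strand is scanned. A locus that matches
`mer8` inevitably also contains a `mer7m8` prefix and a `mer7A1`
suffix; these embedded matches are suppressed so each locus is counted
once at its maximal class, matching strongest-match semantics and
avoiding double counting. Each FASTA record is one analysis unit;
collapsing transcripts to genes is deliberately left to the caller.
Six-mer and wobble site classes are out of scope.

## The CDF-shift delta

Seed-mediated repression shows up as a left shift of the log2
fold-change distribution of seed-match genes relative to background
genes with no site. The package quantifies it as a signed
Kolmogorov-Smirnov-type statistic: with `D+ = max_x (F_fg - F_bg)` and
`D- = max_x (F_bg - F_fg)`,

delta = `D+` if `D+ >= D-`, else `-D-`.

Repressed foregrounds give positive delta; `|delta|` is the KS D
statistic; identical samples give 0 and swapping the samples negates
the value. Because it is an ECDF functional, delta is invariant under
any strictly increasing transform of the fold-changes. Significance is
reported two ways, a two-sided two-sample KS test and a Wilcoxon
rank-sum test, because no single test is canonical for this design;
both p-values are printed and Benjamini-Hochberg adjustment across
classes is available but off by default. For small untied samples
`stats::ks.test()` computes the exact conditional null distribution,
which coincides with exhaustive permutation enumeration; the test
suite verifies this for every design with `n_fg + n_bg <= 10`.

The background is defined as genes whose strongest class is `none`
after expression filtering. The on-target gene is excluded from the
strata: its engineered repression is not an off-target signal. Its
fold-change instead supplies the knockdown axis
(`knockdown = 1 - 2^log2FC`) of the dose profile, where the mer8 delta
is plotted against on-target knockdown per dose and summarised by a
Spearman rank correlation. With fewer than three doses the correlation
is reported as `NA`.

## Two-state melting and the Tm estimator

Simulated UV melts use the bimolecular two-state model. For a
non-self-complementary duplex at total strand concentration `C_T`, the
single-strand fraction alpha solves
`Ka = 2(1 - alpha) / (alpha^2 C_T)`, giving the closed-form midpoint
`Tm = dH / (dS + R ln(C_T/4))` at which `alpha = 1/2` (for
self-complementary strands the `C_T/4` becomes `C_T`). Absorbance is
`L(T) + alpha(T) (U(T) - L(T))` with linear baselines. Defaults:
`dH = -670` kJ/mol (the order of nearest-neighbour enthalpy sums for a
~21-bp RNA duplex), midpoint 65 degC, `C_T = 1` uM, a 15-90 degC grid
in 0.5 degC steps mirroring a 1 degC/min heating ramp.

Tm is estimated by the first-derivative method: local-quadratic
smoothing (default window 11 points; the smoother shrinks its window
at the curve ends, so window 1 is exactly the identity), central
differences, and a three-point quadratic refinement of the discrete
derivative maximum. A maximum on the grid boundary raises "transition
not captured"; ties between equal maxima resolve to the lower
temperature with a message. The estimator is invariant under affine
transforms of the absorbance and under adding a shared linear baseline.
The smoother is written in-package because its endpoint contract
(window shrinkage, window-1 identity) differs from stock
Savitzky-Golay filters.

**Derivative maximum versus thermodynamic midpoint.** For a
bimolecular transition the melting curve is skewed and the maximum of
dA/dT sits *above* the `alpha = 1/2` midpoint by approximately
`R Tm^2 / |dH|` times a constant near 0.5 — about 0.65 degC at the
default enthalpy, growing to ~1.6 degC for a shallow `dH = -300`
kJ/mol transition. This is physics, not estimator error: the test
suite shows the estimator recovers the true derivative maximum to
better than 0.05 degC. Consequently absolute Tm values carry the
derivative-maximum convention, exactly as instrument software reports
them, while Delta-Tm differences between duplexes cancel the offset
(verified to ~0.02 degC in the tests). Comparisons of the estimator
against the closed-form midpoint inherit this systematic ~0.65 degC
gap; the acceptance suite reports it honestly rather than recalibrating
the generator toward agreement.

`delta_tm_table()` does the bookkeeping mirroring the fixture table:
`delta_tm = Tm - Tm(parent)` for each modified duplex and
`ddelta_tm = delta_tm - delta_tm(reference)` for each isonucleotide
duplex referenced to its native-GNA sibling; display columns are
rounded to 0.1 degC, full precision is retained. Buffer identity is
metadata only; no ionic-strength correction is applied.

## ddCt, reporter normalization, metabolite accounting

Relative expression follows the standard delta-delta-Ct closed form:
`dCt = Ct_target - Ct_ref` per well, `ddCt = dCt - agg(dCt, controls)`
(mean by default, median by option; the source protocols do not state
which), `rel = 2^-ddCt`, and percent silencing `100 (1 - rel)` floored
at zero for display with the raw value retained. Adding a machine
offset to every Ct changes nothing, and the geometric mean of control
relative expression is exactly 1. No amplification-efficiency
correction is attempted (no standard curves in scope).

Dual-luciferase wells are normalized within-well (Renilla/Firefly)
and then to the mean ratio of the reference condition, whose mean
activity is therefore exactly 1 by construction.

Metabolite masses are computed from elemental compositions: nucleoside
= base + sugar - H2O (sugars: ribose, 2'-OMe, 2'-F, 2'-deoxy, and
propylene glycol for GNA; the isonucleotides are constitutional
isomers and hence isobaric), plus `HPO3 - H2O` per phosphodiester
bridge and an S-for-O increment per phosphorothioate. Termini are
hydroxyl. The GalNAc (L96) contribution is an approximate constant
(~2005 Da, configurable) because no elemental formula is asserted for
the ligand; the independent elemental-composition oracle in the test
suite therefore covers ligand-free strands, to better than 1e-3 Da.
The truncation ladder enumerates the full-length species and every
single-sided `3'N-k`/`5'N-k` product (`2(n-1) + 1` entries), and the
active fraction is the full-length plus `3'N-1` share of total
abundance — the definition used for guide-strand metabolite
accounting — with the active set configurable.

## What the generator emulates, and what it does not

`sim_config()` fixes the study conditions in one place. Choices and
their rationale:

* **Transcriptome**: 2000 UTRs, log-normal lengths (median 800 nt,
  sdlog 0.6, floor 60 nt), slightly AU-rich composition (0.3/0.2).
  Desk-scale stand-in for the ~10^4 expressed genes of a hepatocyte
  line; large enough for stable ECDFs, small enough for fast tests.
* **Planting**: one site of one class per selected transcript at a
  uniform position, 10% probability per class. Truth records both the
  intent and a re-scan, because chance matches (including upgrades of
  a planted 7-mer to mer8 by a lucky flanking base) are legitimate
  signal.
* **Expression model**: `log2FC = -beta_class f(dose) + noise`,
  strongest class only (no additivity across site types, matching the
  strongest-match stratification), `noise ~ N(0, 0.25^2)` log2 units;
  betas 0.4/0.25/0.15 for mer8/mer7m8/mer7A1 — modest, ordered effects
  of the size seed-mediated repression produces.
* **Dose response**: doses 0.1/1/10/50 nM with Hill occupancy
  `f = dose^h / (dose^h + EC50^h)`, EC50 1 nM, h 1, maximal knockdown
  0.9; the on-target gene follows `log2(1 - 0.9 f)`.
* **padj is a placeholder**: a z-score against the known noise model,
  BH-adjusted. Differential-expression fitting is out of scope; the
  column exists so tables have their full canonical shape and must
  not be interpreted as a DESeq2-style moderated statistic.
* **Plates and melts**: Ct noise 0.15 cycles, reporter CV 2%, melt
  noise 0.2% of amplitude, 4 wells, two melt replicates.

Determinism: every generator derives its stream from the config seed
(doses offset the seed so each table is reproducible in isolation);
equal seeds give byte-identical FASTA output.

What passing tests on this generator do **not** show about real data:
UTRs are i.i.d. base soups with no compositional context, conservation
or expression-site correlation; repression is homoscedastic and
class-pure; there is no count noise, no dispersion shrinkage, no
batch structure; melting is ideally two-state. The generator validates
the *machinery* (recall, calibration, ordering, closed forms), not
biological effect sizes.

## Numerical choices and degenerate inputs

* ECDF deltas are computed on the pooled unique grid; exact ties
  between `D+` and `D-` resolve to the positive sign.
* Empty foreground classes are flagged "not computable", never
  dropped; foregrounds below `min_n` (default 10) are flagged "low n".
* The seed window allows the degenerate `g_start == g_end` single-base
  case.
* Non-IUPAC characters in UTRs are an error, not silently skipped;
  IUPAC ambiguity codes are accepted but never matched.
* The two-state solver clamps `ln Ka` at 600 to avoid overflow deep
  below the transition and switches to a series expansion where the
  quadratic formula cancels catastrophically.
* Problem sizes in tests (2000-transcript simulations, 10-50
  replicates, 200 null resamples) were chosen as the smallest sizes at
  which the statistical assertions have comfortable margins.

## Known limitations

* Only the three canonical site classes; no context scoring, no
  conservation, no gene-level collapsing.
* No thermodynamic prediction of Tm from sequence and no fitting of
  dH/dS from experimental curves; the two-state model is
  simulation-side only.
* The ligand mass is approximate by design; supply your own value via
  `residue_mass_table()` for exact conjugate masses.
* The pipeline consumes DE tables; it never estimates them.
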