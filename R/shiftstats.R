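## Stratified CDF-shift statistics for seed-match classes.
##
## The central quantity is the signed maximal vertical difference
## between the empirical CDFs of foreground (seed-match) and background
## (no-seed-match) log2 fold-changes. Repression moves mass of the
## foreground distribution to the left, i.e. its ECDF above the
## background's, so the delta is positive when the foreground is shifted
## toward repression. The delta is distribution-free: it is invariant
## under any strictly increasing transform applied to all values.

#' Filter a DE table on mean expression
#'
#' @param de DE data frame (canonical columns, see [read_de_table()]).
#' @param min_base_mean Keep rows with `base_mean >= min_base_mean`.
#' @return The filtered table; a message reports how many rows were
#'   kept, and a warning is raised if nothing survives.
#' @export
expression_filter <- function(de, min_base_mean = 0) {
  stopifnot(min_base_mean >= 0)
  keep <- de$base_mean >= min_base_mean
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("expression filter: kept %d of %d genes (base_mean >= %g)",
                  nrow(out), nrow(de), min_base_mean))
  if (nrow(out) == 0L)
    warning("expression filter removed every gene")
  out
}

#' Signed ECDF-shift between foreground and background
#'
#' Computes the signed maximal vertical ECDF difference between two
#' samples of log2 fold-changes, together with the two-sided two-sample
#' Kolmogorov-Smirnov p-value, the Wilcoxon rank-sum p-value, and the
#' difference in means. Let `D+ = max_x (F_fg(x) - F_bg(x))` and
#' `D- = max_x (F_bg(x) - F_fg(x))`; the returned `delta` is `D+` when
#' `D+ >= D-` and `-D-` otherwise, so identical samples give 0, a fully
#' repressed foreground gives +1, and swapping the samples negates the
#' value (up to exact ties). `abs(delta)` equals the KS D statistic.
#'
#' For small untied samples the KS p-value is the exact (permutation)
#' probability as computed by [stats::ks.test()].
#'
#' @param fg,bg Numeric vectors of log2 fold-changes (non-empty).
#' @param exact Passed to [stats::ks.test()]; default lets `ks.test`
#'   decide (exact for small untied samples).
#' @return Object of class `cdf_shift`: list with `n_fg`, `n_bg`,
#'   `delta`, `ks_p`, `ranksum_p`, `mean_diff`.
#' @examples
#' cdf_shift(c(-1, -1, -1), c(0, 0, 0))$delta  # +1: full repression
#' @export
cdf_shift <- function(fg, bg, exact = NULL) {
  fg <- as.numeric(fg); bg <- as.numeric(bg)
  if (length(fg) == 0L || length(bg) == 0L)
    stop("cdf_shift: both samples must be non-empty")
  if (any(!is.finite(fg)) || any(!is.finite(bg)))
    stop("cdf_shift: non-finite values; filter the table first")
  grid <- sort(unique(c(fg, bg)))
  d <- stats::ecdf(fg)(grid) - stats::ecdf(bg)(grid)
  dpos <- max(d); dneg <- max(-d)
  delta <- if (dpos >= dneg) dpos else -dneg
  ks <- suppressWarnings(stats::ks.test(fg, bg, exact = exact))
  rs <- suppressWarnings(stats::wilcox.test(fg, bg))
  structure(list(n_fg = length(fg), n_bg = length(bg), delta = delta,
                 ks_p = unname(ks$p.value), ranksum_p = unname(rs$p.value),
                 mean_diff = mean(fg) - mean(bg)),
            class = "cdf_shift")
}

#' @export
print.cdf_shift <- function(x, ...) {
  cat(sprintf("<cdf_shift> delta = %+.4f (n_fg = %d, n_bg = %d)\n",
              x$delta, x$n_fg, x$n_bg))
  cat(sprintf("  KS p = %.3g, rank-sum p = %.3g, mean log2FC diff = %+.3f\n",
              x$ks_p, x$ranksum_p, x$mean_diff))
  invisible(x)
}

#' Stratified CDF shifts by strongest seed-match class
#'
#' Splits a class-annotated DE table into foregrounds (strongest class
#' mer8 / mer7m8 / mer7A1) against the shared background of genes with
#' no seed match, and computes one [cdf_shift()] per class. Classes with
#' fewer foreground genes than `min_n` are flagged (`flag` column), not
#' dropped; empty classes are flagged `"not computable"` with `NA`
#' statistics.
#'
#' @param de DE data frame carrying a `strongest_class` column (e.g.
#'   a DE table merged with [annotate_transcriptome()] output).
#' @param min_n Minimum foreground size before a `low n` flag.
#' @param p_adjust `"none"` (default) or `"BH"`: Benjamini-Hochberg
#'   adjustment of the KS and rank-sum p-values across the three
#'   classes.
#' @return Data frame of class `seed_shift_table`: one row per class
#'   with `class`, `n_fg`, `n_bg`, `delta`, `ks_p`, `ranksum_p`,
#'   `mean_diff`, `flag`. The foreground/background values are attached
#'   as attributes for plotting.
#' @export
stratified_shifts <- function(de, min_n = 10L, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot("strongest_class" %in% names(de), "log2fc" %in% names(de))
  bg <- de$log2fc[de$strongest_class == "none"]
  if (length(bg) == 0L)
    stop("stratified_shifts: no background genes (strongest_class == 'none')")
  classes <- c("mer8", "mer7m8", "mer7A1")
  rows <- lapply(classes, function(cl) {
    fg <- de$log2fc[de$strongest_class == cl]
    if (length(fg) == 0L)
      return(data.frame(class = cl, n_fg = 0L, n_bg = length(bg),
                        delta = NA_real_, ks_p = NA_real_,
                        ranksum_p = NA_real_, mean_diff = NA_real_,
                        flag = "not computable", stringsAsFactors = FALSE))
    s <- cdf_shift(fg, bg)
    data.frame(class = cl, n_fg = s$n_fg, n_bg = s$n_bg, delta = s$delta,
               ks_p = s$ks_p, ranksum_p = s$ranksum_p,
               mean_diff = s$mean_diff,
               flag = if (s$n_fg < min_n) "low n" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$ks_p <- stats::p.adjust(out$ks_p, method = "BH")
    out$ranksum_p <- stats::p.adjust(out$ranksum_p, method = "BH")
  }
  attr(out, "fg_values") <- lapply(classes, function(cl)
    de$log2fc[de$strongest_class == cl])
  names(attr(out, "fg_values")) <- classes
  attr(out, "bg_values") <- bg
  class(out) <- c("seed_shift_table", "data.frame")
  out
}

#' @export
print.seed_shift_table <- function(x, ...) {
  cat("Stratified CDF shifts vs background (n_bg =",
      x$n_bg[[1L]], "genes without seed match)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot stratified ECDFs
#'
#' Step ECDF curves of log2 fold-changes for each seed-match class over
#' the no-site background, the visual from which the shift deltas are
#' read.
#'
#' @param x A `seed_shift_table`.
#' @param xlim Optional x range.
#' @param ... Passed to [graphics::plot()].
#' @method plot seed_shift_table
#' @export
plot.seed_shift_table <- function(x, xlim = NULL, ...) {
  fg <- attr(x, "fg_values"); bg <- attr(x, "bg_values")
  cols <- c(mer8 = "red3", mer7m8 = "blue3", mer7A1 = "goldenrod2")
  if (is.null(xlim)) {
    rng <- range(c(unlist(fg), bg), finite = TRUE)
    xlim <- rng + c(-1, 1) * 0.05 * diff(rng)
  }
  graphics::plot(stats::ecdf(bg), do.points = FALSE, verticals = TRUE,
                 col = "black", xlim = xlim, main = "CDF shift by seed-match class",
                 xlab = expression(log[2] ~ "fold-change"),
                 ylab = "cumulative fraction", ...)
  for (cl in names(cols))
    if (length(fg[[cl]]) > 0L)
      graphics::lines(stats::ecdf(fg[[cl]]), do.points = FALSE,
                      verticals = TRUE, col = cols[[cl]])
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", cols),
                   legend = c("background", names(cols)))
  invisible(x)
}

#' Dose profile of CDF shift versus on-target knockdown
#'
#' Joins per-dose mer8 shift deltas with per-dose on-target knockdown
#' fractions and reports the Spearman rank correlation between them.
#' With fewer than 3 doses the correlation is undefined (`NA`) but the
#' points are still emitted.
#'
#' @param shifts Data frame with columns `dose` and `delta` (the mer8
#'   CDF shift at that dose).
#' @param knockdown Data frame with columns `dose` and `knockdown`
#'   (on-target knockdown fraction in `[0, 1]`).
#' @return Object of class `dose_profile`: list with `points` (sorted
#'   by dose), `spearman_rho`, `n`.
#' @export
shift_dose_profile <- function(shifts, knockdown) {
  stopifnot(all(c("dose", "delta") %in% names(shifts)),
            all(c("dose", "knockdown") %in% names(knockdown)))
  if (!setequal(shifts$dose, knockdown$dose))
    stop("shift_dose_profile: dose sets differ between shifts and knockdown")
  pts <- merge(shifts[c("dose", "delta")],
               knockdown[c("dose", "knockdown")], by = "dose")
  pts <- pts[order(pts$dose), , drop = FALSE]
  rownames(pts) <- NULL
  if (any(pts$knockdown < -0.05 | pts$knockdown > 1))
    warning("knockdown fractions outside [0, 1]")
  rho <- if (nrow(pts) >= 3L)
    suppressWarnings(stats::cor(pts$knockdown, pts$delta, method = "spearman"))
  else NA_real_
  structure(list(points = pts, spearman_rho = rho, n = nrow(pts)),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat("CDF shift vs on-target knockdown profile\n")
  print.data.frame(x$points, digits = 4, row.names = FALSE)
  cat(sprintf("Spearman rho = %s (n = %d doses)\n",
              ifelse(is.na(x$spearman_rho), "NA",
                     sprintf("%.3f", x$spearman_rho)), x$n))
  invisible(x)
}

#' @method plot dose_profile
#' @export
plot.dose_profile <- function(x, ...) {
  graphics::plot(x$points$knockdown, x$points$delta, type = "b", pch = 19,
                 xlab = "on-target knockdown fraction",
                 ylab = "mer8 CDF shift (delta)",
                 main = "Off-target shift vs on-target activity", ...)
  invisible(x)
}
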