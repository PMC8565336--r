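## End-to-end orchestration: seed derivation -> UTR scan -> per-dose
## stratified shifts -> dose profile, plus the Tm table runner. Every
## persisted table carries a '# seed=... config=...' provenance line.

#' Run the off-target specificity analysis
#'
#' Derives the guide seed and canonical sites, annotates the UTR set,
#' joins each dose's DE table to the per-transcript strongest-class
#' calls, computes stratified CDF shifts against the no-site
#' background, and assembles the mer8 shift-versus-knockdown dose
#' profile. The on-target gene is excluded from the shift strata (its
#' intended repression is not an off-target signal); its log2
#' fold-change provides the knockdown axis (`1 - 2^log2FC`) unless an
#' external `knockdown` table is supplied.
#'
#' @param guide An `oligo_strand`, or dialect text for one (assumed
#'   5'->3'; parse explicitly for 3'->5' sources).
#' @param utrs UTR set: FASTA path, named character vector or data
#'   frame (see [annotate_transcriptome()]).
#' @param de_tables Named list of DE data frames (or file paths), names
#'   = doses in nM.
#' @param min_base_mean Expression filter threshold.
#' @param min_n Minimum foreground size per class before flagging.
#' @param p_adjust Passed to [stratified_shifts()].
#' @param on_target_id Gene id treated as the on-target transcript.
#' @param knockdown Optional data frame `dose`, `knockdown` overriding
#'   the DE-derived on-target knockdown.
#' @param out_dir If non-NULL, persist calls, per-dose shift tables and
#'   the dose profile as commented TSVs.
#' @param seed Seed recorded in output headers (provenance only; the
#'   analysis itself is deterministic).
#' @return Object of class `specificity_run`: list with `calls`,
#'   `shifts` (named list of `seed_shift_table` per dose), `profile`
#'   (a `dose_profile`), `doses`, `n_genes_used`.
#' @export
run_specificity <- function(guide, utrs, de_tables,
                            min_base_mean = 0, min_n = 10L,
                            p_adjust = c("none", "BH"),
                            on_target_id = "on_target",
                            knockdown = NULL,
                            out_dir = NULL, seed = NA) {
  p_adjust <- match.arg(p_adjust)
  if (is.character(guide)) guide <- parse_strand(guide)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed7 <- stage("oligo", guide_seed(guide))
  sites <- stage("oligo", seed_sites(seed7))
  calls <- stage("seedscan", annotate_transcriptome(utrs, sites))
  if (length(de_tables) == 0L) stop("[shiftstats] no DE tables supplied")
  doses <- as.numeric(names(de_tables))
  if (anyNA(doses))
    stop("[shiftstats] de_tables must be named by numeric dose")
  shifts <- list()
  kd_rows <- list()
  n_used <- integer(0)
  for (i in seq_along(de_tables)) {
    de <- de_tables[[i]]
    if (is.character(de)) de <- stage("exprio", read_de_table(de))
    de <- stage("shiftstats", {
      if (nrow(de) == 0L) stop("empty DE table at dose ", doses[i])
      suppressMessages(expression_filter(de, min_base_mean))
    })
    merged <- merge(de, calls, by.x = "gene_id", by.y = "transcript_id")
    dropped <- nrow(de) - nrow(merged)
    if (dropped > 0L)
      message(dropped, " DE gene(s) without a UTR record excluded at dose ",
              doses[i])
    ot <- merged[merged$gene_id == on_target_id, , drop = FALSE]
    body <- merged[merged$gene_id != on_target_id, , drop = FALSE]
    shifts[[as.character(doses[i])]] <-
      stage("shiftstats", stratified_shifts(body, min_n = min_n,
                                            p_adjust = p_adjust))
    n_used <- c(n_used, nrow(body))
    kd_rows[[i]] <- data.frame(
      dose = doses[i],
      knockdown = if (nrow(ot) == 1L) 1 - 2^ot$log2fc else NA_real_)
  }
  kd <- if (is.null(knockdown)) do.call(rbind, kd_rows) else knockdown
  mer8 <- data.frame(
    dose = doses,
    delta = vapply(shifts, function(s) s$delta[s$class == "mer8"], numeric(1)))
  profile <- if (all(is.finite(kd$knockdown)))
    stage("shiftstats", shift_dose_profile(mer8, kd))
  else NULL
  out <- structure(list(guide_seed = seed7, sites = sites, calls = calls,
                        shifts = shifts, profile = profile, doses = doses,
                        knockdown = kd, n_genes_used = n_used, seed = seed),
                   class = "specificity_run")
  if (!is.null(out_dir)) write_specificity_run(out, out_dir)
  out
}

#' @noRd
write_specificity_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmt <- paste0("seed=", run$seed, " config=", config_hash(
    list(run$guide_seed, run$doses)))
  write_commented_tsv(run$calls, file.path(out_dir, "transcript_calls.tsv"),
                      comment = cmt)
  for (d in names(run$shifts))
    write_commented_tsv(as.data.frame(run$shifts[[d]]),
                        file.path(out_dir, sprintf("shifts_dose%s.tsv", d)),
                        comment = cmt)
  if (!is.null(run$profile))
    write_commented_tsv(cbind(run$profile$points,
                              spearman_rho = run$profile$spearman_rho),
                        file.path(out_dir, "dose_profile.tsv"), comment = cmt)
  invisible(out_dir)
}

#' @export
print.specificity_run <- function(x, ...) {
  cat(sprintf("<specificity_run> guide seed %s, %d dose(s)\n",
              x$guide_seed, length(x$doses)))
  cat("Transcript calls:\n")
  print(table(x$calls$strongest_class))
  for (d in names(x$shifts)) {
    cat(sprintf("\n-- dose %s nM --\n", d))
    print(x$shifts[[d]])
  }
  if (!is.null(x$profile)) {
    cat("\n")
    print(x$profile)
  }
  invisible(x)
}

#' @method summary specificity_run
#' @export
summary.specificity_run <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$shifts), function(d) {
    s <- as.data.frame(object$shifts[[d]])
    s$dose <- as.numeric(d)
    s
  }))
  rows <- merge(rows, object$knockdown, by = "dose", all.x = TRUE)
  rows[order(rows$dose, match(rows$class, site_class_levels())), ]
}

#' @method plot specificity_run
#' @export
plot.specificity_run <- function(x, dose = max(x$doses), ...) {
  plot(x$shifts[[as.character(dose)]],
       sub = sprintf("dose %g nM", dose), ...)
  invisible(x)
}

#' Run the Delta-Tm table stage
#'
#' Fixture mode (`tm` supplied): passes measured Tm values straight to
#' [delta_tm_table()]. Curve mode (`curves` supplied): estimates each
#' duplex's Tm from its replicate melting curves first, then builds the
#' same table.
#'
#' @param tm Data frame `duplex_id`, `tm_c` (+ optional `parent_id`,
#'   `reference_id` columns), e.g. [galnac_duplex_tm()].
#' @param curves Named list (by duplex id) of lists of [melt_curve()]
#'   replicates.
#' @param parent_map,reference_map See [delta_tm_table()].
#' @param window,degree Smoothing settings for curve mode.
#' @param out_dir Optional output directory.
#' @param seed Provenance seed for the output header.
#' @return The [delta_tm_table()] data frame.
#' @export
run_tm_table <- function(tm = NULL, curves = NULL,
                         parent_map = NULL, reference_map = NULL,
                         window = 11L, degree = 2L,
                         out_dir = NULL, seed = NA) {
  if (is.null(tm)) {
    if (is.null(curves)) stop("run_tm_table: supply `tm` or `curves`")
    tm <- data.frame(
      duplex_id = names(curves),
      tm_c = vapply(curves, function(cv)
        tm_replicates(cv, window = window, degree = degree)$tm, numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- delta_tm_table(tm, parent_map = parent_map,
                        reference_map = reference_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_commented_tsv(out, file.path(out_dir, "tm_table.tsv"),
                        comment = paste0("seed=", seed, " config=",
                                         config_hash(list(out$duplex_id))))
  }
  out
}
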