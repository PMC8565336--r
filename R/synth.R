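## Synthetic-data generator. Emulates the statistical structure every
## pipeline stage assumes -- a transcriptome of 3'-UTRs with planted
## seed-match sites, background log2 fold-change noise around zero with
## site-class- and dose-dependent repression, an on-target gene with a
## Hill-type dose response, two-state melting curves with additive
## noise, and qPCR/reporter plates with a reference channel -- so the
## full pipeline runs and is tested without any external data.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator in one validated list.
#' Defaults describe the study conditions the pipeline is exercised
#' under: a desk-scale transcriptome of 2000 UTRs (log-normal lengths,
#' slightly AU-rich composition), 10% planting probability per site
#' class, repression effect sizes ordered mer8 > mer7m8 > mer7A1 in
#' log2 units, per-gene noise of 0.25 log2 units, the four-point dose
#' series 0.1/1/10/50 nM with a Hill-type on-target response (EC50 1
#' nM, coefficient 1, maximal knockdown 0.9), a two-state melt model,
#' and 4-replicate plates.
#'
#' @param seed Integer RNG seed; every generator derives its stream
#'   from it.
#' @param n_transcripts Number of background UTR records.
#' @param utr_meanlog,utr_sdlog,utr_min_length Log-normal UTR length
#'   distribution (nt) and lower clamp.
#' @param base_probs Named base composition (A, C, G, U), summing to 1.
#' @param p_plant Named planting probabilities per site class
#'   (`mer8`, `mer7m8`, `mer7A1`), summing to at most 1.
#' @param beta Named repression effect sizes per class, log2 units
#'   (applied as `-beta * f(dose)` to a transcript's expected log2FC).
#' @param sigma Per-gene log2FC noise standard deviation (> 0).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal abundance model.
#' @param doses Dose series, nM (> 0).
#' @param ec50,hill,kmax On-target Hill parameters: EC50 (nM),
#'   coefficient, maximal knockdown fraction.
#' @param on_target_id Gene id of the on-target transcript.
#' @param qpcr_ct_sd Ct replicate noise (cycles).
#' @param reporter_cv Multiplicative noise CV of luciferase signals.
#' @param n_wells Wells per group/condition on simulated plates.
#' @param melt A [melt_params()] object for simulated melts.
#' @param melt_noise_sd Melt noise, as a fraction of curve amplitude.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 2000L,
                       utr_meanlog = log(800), utr_sdlog = 0.6,
                       utr_min_length = 60L,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                       p_plant = c(mer8 = 0.1, mer7m8 = 0.1, mer7A1 = 0.1),
                       beta = c(mer8 = 0.4, mer7m8 = 0.25, mer7A1 = 0.15),
                       sigma = 0.25,
                       base_mean_meanlog = log(500), base_mean_sdlog = 1.5,
                       doses = c(0.1, 1, 10, 50),
                       ec50 = 1, hill = 1, kmax = 0.9,
                       on_target_id = "on_target",
                       qpcr_ct_sd = 0.15,
                       reporter_cv = 0.02,
                       n_wells = 4L,
                       melt = melt_params(),
                       melt_noise_sd = 0.002) {
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == round(seed)),
            is_count(n_transcripts), n_transcripts > 0,
            all(c("A", "C", "G", "U") %in% names(base_probs)),
            abs(sum(base_probs) - 1) < 1e-8,
            all(c("mer8", "mer7m8", "mer7A1") %in% names(p_plant)),
            all(p_plant >= 0 & p_plant <= 1), sum(p_plant) <= 1,
            all(c("mer8", "mer7m8", "mer7A1") %in% names(beta)),
            sigma > 0, all(doses > 0), ec50 > 0, hill > 0,
            kmax >= 0, kmax <= 1,
            inherits(melt, "melt_params"))
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 utr_meanlog = utr_meanlog, utr_sdlog = utr_sdlog,
                 utr_min_length = utr_min_length, base_probs = base_probs,
                 p_plant = p_plant, beta = beta, sigma = sigma,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 doses = doses, ec50 = ec50, hill = hill, kmax = kmax,
                 on_target_id = on_target_id, qpcr_ct_sd = qpcr_ct_sd,
                 reporter_cv = reporter_cv, n_wells = n_wells,
                 melt = melt, melt_noise_sd = melt_noise_sd),
            class = "sim_config")
}

#' Hill occupancy at a dose
#'
#' `f(dose) = dose^h / (dose^h + EC50^h)`; the fractional effect that
#' scales both on-target knockdown and seed-mediated repression.
#'
#' @param config A [sim_config()].
#' @param dose Dose in nM.
#' @export
hill_fraction <- function(config, dose) {
  dose^config$hill / (dose^config$hill + config$ec50^config$hill)
}

#' Generate a synthetic UTR set with planted seed sites
#'
#' Draws `n_transcripts` background UTRs from the configured length and
#' composition model, plants at most one site (of the class drawn from
#' `p_plant`) per transcript at a uniform position, and appends the
#' on-target transcript carrying the mer8 site. The truth table records
#' the planting intent *and* the classes actually found by re-scanning
#' with [annotate_transcriptome()] -- chance background matches are
#' permitted and recorded, so tests compare against truth, not intent.
#'
#' @param config A [sim_config()].
#' @param sites A guide seed 7-mer or named site vector ([seed_sites()]).
#' @return List of class `utr_simulation`: `utrs` (data frame `id`,
#'   `description`, `sequence`), `truth` (planted class, re-scan
#'   strongest class and counts, expected log2FC per dose as
#'   `mu_<dose>` columns), `sites`, `config`.
#' @export
generate_utr_set <- function(config, sites) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(sites))) sites <- seed_sites(sites)
  set.seed(config$seed)
  n <- config$n_transcripts
  classes <- c("mer8", "mer7m8", "mer7A1")
  planted <- sample(c(classes, "none"), n, replace = TRUE,
                    prob = c(config$p_plant[classes],
                             1 - sum(config$p_plant[classes])))
  bases <- names(config$base_probs)
  draw_len <- function() {
    for (try in 1:20) {
      len <- max(config$utr_min_length, round(stats::rlnorm(
        1, config$utr_meanlog, config$utr_sdlog)))
      if (len >= max(nchar(sites))) return(len)
    }
    stop("generate_utr_set: cannot draw a UTR long enough for the site")
  }
  seqs <- character(n + 1L)
  ids <- c(sprintf("tx%04d", seq_len(n)), config$on_target_id)
  plant_site <- function(seq, site) {
    len <- nchar(seq)
    pos <- sample.int(len - nchar(site) + 1L, 1L)
    paste0(substr(seq, 1L, pos - 1L), site,
           substr(seq, pos + nchar(site), len))
  }
  for (i in seq_len(n)) {
    len <- draw_len()
    s <- paste(sample(bases, len, replace = TRUE,
                      prob = config$base_probs), collapse = "")
    if (planted[i] != "none") s <- plant_site(s, sites[[planted[i]]])
    seqs[i] <- s
  }
  ## on-target transcript: carries the full mer8 site of the guide
  len <- draw_len()
  s <- paste(sample(bases, len, replace = TRUE,
                    prob = config$base_probs), collapse = "")
  seqs[n + 1L] <- plant_site(s, sites[["mer8"]])
  planted <- c(planted, "mer8")

  utrs <- data.frame(id = ids,
                     description = paste0("planted=", planted),
                     sequence = seqs, stringsAsFactors = FALSE)
  calls <- annotate_transcriptome(utrs, sites)
  truth <- cbind(data.frame(transcript_id = ids, planted_class = planted,
                            stringsAsFactors = FALSE),
                 calls[match(ids, calls$transcript_id),
                       c("strongest_class", "n_mer8", "n_mer7m8", "n_mer7A1")])
  rownames(truth) <- NULL
  for (d in config$doses) {
    f <- hill_fraction(config, d)
    mu <- ifelse(truth$strongest_class == "none", 0,
                 -config$beta[truth$strongest_class] * f)
    mu[truth$transcript_id == config$on_target_id] <-
      log2(1 - config$kmax * f)
    truth[[sprintf("mu_%g", d)]] <- unname(mu)
  }
  structure(list(utrs = utrs, truth = truth, sites = sites, config = config),
            class = "utr_simulation")
}

#' @export
print.utr_simulation <- function(x, ...) {
  cat(sprintf("<utr_simulation> %d transcripts (+ on-target), seed %d\n",
              nrow(x$utrs) - 1L, x$config$seed))
  print(table(x$truth$strongest_class))
  invisible(x)
}

#' Simulate a differential-expression table at one dose
#'
#' Per gene, `log2FC = -beta_class f(dose) + eps`, `eps ~ N(0, sigma^2)`
#' with the class taken as the strongest re-scanned class (strongest-
#' match-only effect model, no additivity across site types); the
#' on-target gene follows `log2(1 - Kmax f(dose)) + eps`. Abundances
#' are log-normal. The adjusted p-value is a z-score placeholder
#' against the known noise model (`p = 2 Phi(-|log2FC|/sigma)`,
#' BH-adjusted): differential-expression fitting is out of scope and
#' this column exists only so the table has the full canonical shape.
#'
#' @param sim A `utr_simulation` from [generate_utr_set()].
#' @param dose One of `config$doses`.
#' @param seed RNG seed for the noise draw; the default derives it from
#'   the config seed and the dose index, so a given simulation and dose
#'   always yield the same table.
#' @return Canonical DE data frame (`gene_id`, `base_mean`, `log2fc`,
#'   `padj`).
#' @export
simulate_de_table <- function(sim, dose, seed = NULL) {
  stopifnot(inherits(sim, "utr_simulation"))
  config <- sim$config
  di <- match(dose, config$doses)
  if (is.na(di)) stop("simulate_de_table: unknown dose ", dose)
  set.seed(seed %||% (config$seed + 1000L * di))
  truth <- sim$truth
  mu <- truth[[sprintf("mu_%g", dose)]]
  n <- nrow(truth)
  log2fc <- mu + stats::rnorm(n, 0, config$sigma)
  p <- 2 * stats::pnorm(-abs(log2fc) / config$sigma)
  data.frame(gene_id = truth$transcript_id,
             base_mean = stats::rlnorm(n, config$base_mean_meanlog,
                                       config$base_mean_sdlog),
             log2fc = log2fc,
             padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Simulate replicate melting curves
#'
#' Noiseless two-state curves from the configured melt model plus
#' Gaussian noise with standard deviation `melt_noise_sd` times the
#' curve amplitude.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of traces.
#' @param params Melt model override.
#' @param temperature Grid, deg C.
#' @param seed RNG seed (default derived from the config seed).
#' @return List of [melt_curve()] objects.
#' @export
simulate_melt_replicates <- function(config, n_replicates = 2L,
                                     params = config$melt,
                                     temperature = seq(15, 90, by = 0.5),
                                     seed = config$seed + 303L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  clean <- simulate_melt_curve(params, temperature)
  amp <- diff(range(clean$absorbance))
  lapply(seq_len(n_replicates), function(i)
    melt_curve(temperature,
               clean$absorbance + stats::rnorm(length(temperature), 0,
                                               config$melt_noise_sd * amp),
               label = sprintf("rep%d", i)))
}

#' Simulate a qPCR plate with known knockdown
#'
#' Control and treated wells with target and reference-gene Ct values;
#' the treated target Ct is shifted by `-log2(1 - knockdown)` cycles so
#' the delta-delta-Ct pipeline should recover `1 - knockdown` as the
#' relative expression, up to Ct noise.
#'
#' @param config A [sim_config()].
#' @param knockdown True knockdown fraction in `[0, 1)`.
#' @param n_per_group Wells per group.
#' @param seed RNG seed.
#' @return Data frame consumable by [ddct_relative_expression()], with
#'   the truth recorded in attribute `truth_knockdown`.
#' @export
simulate_qpcr_plate <- function(config, knockdown = 0.87,
                                n_per_group = config$n_wells,
                                seed = config$seed + 101L) {
  stopifnot(inherits(config, "sim_config"), knockdown >= 0, knockdown < 1)
  set.seed(seed)
  sdv <- config$qpcr_ct_sd
  shift <- -log2(1 - knockdown)
  wells <- rbind(
    data.frame(sample_id = sprintf("ctrl%d", seq_len(n_per_group)),
               group = "control",
               ct_target = 24 + stats::rnorm(n_per_group, 0, sdv),
               ct_reference = 20 + stats::rnorm(n_per_group, 0, sdv),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("trt%d", seq_len(n_per_group)),
               group = "treated",
               ct_target = 24 + shift + stats::rnorm(n_per_group, 0, sdv),
               ct_reference = 20 + stats::rnorm(n_per_group, 0, sdv),
               stringsAsFactors = FALSE))
  attr(wells, "truth_knockdown") <- knockdown
  wells
}

#' Simulate a dual-luciferase reporter plate
#'
#' Reference-condition and treated wells with Firefly and Renilla
#' signals under multiplicative noise of CV `reporter_cv`; the treated
#' Renilla/Firefly ratio is scaled by `1 - knockdown`.
#'
#' @inheritParams simulate_qpcr_plate
#' @param n_per_condition Wells per condition.
#' @return Data frame consumable by [luciferase_normalize()], truth in
#'   attribute `truth_knockdown`.
#' @export
simulate_reporter_plate <- function(config, knockdown = 0.5,
                                    n_per_condition = config$n_wells,
                                    seed = config$seed + 202L) {
  stopifnot(inherits(config, "sim_config"), knockdown >= 0, knockdown <= 1)
  set.seed(seed)
  cv <- config$reporter_cv
  noise <- function(k) 1 + stats::rnorm(k, 0, cv)
  ff_ref <- 1e5 * noise(n_per_condition)
  ff_trt <- 1e5 * noise(n_per_condition)
  wells <- rbind(
    data.frame(sample_id = sprintf("ref%d", seq_len(n_per_condition)),
               condition = "untreated", firefly = ff_ref,
               renilla = 0.5 * ff_ref * noise(n_per_condition),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("trt%d", seq_len(n_per_condition)),
               condition = "treated", firefly = ff_trt,
               renilla = 0.5 * (1 - knockdown) * ff_trt * noise(n_per_condition),
               stringsAsFactors = FALSE))
  attr(wells, "truth_knockdown") <- knockdown
  wells
}

#' Write a complete simulated study bundle to disk
#'
#' Runs the generator end to end for one guide seed and writes
#' `utrs.fasta`, `truth.tsv`, one `de_dose<d>.tsv` per dose,
#' `melts/rep<i>.csv`, `qpcr.csv`, `reporter.csv` and a `config.tsv`
#' echo (key-value) into `dir`.
#'
#' @param config A [sim_config()].
#' @param sites Guide seed 7-mer or named site vector.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the `utr_simulation` object with an added
#'   `paths` element.
#' @export
simulate_study <- function(config, sites, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "melts"), showWarnings = FALSE)
  sim <- generate_utr_set(config, sites)
  paths <- list(utrs = file.path(dir, "utrs.fasta"),
                truth = file.path(dir, "truth.tsv"))
  write_utr_fasta(sim$utrs, paths$utrs)
  write_commented_tsv(sim$truth, paths$truth,
                      comment = paste0("seed=", config$seed,
                                       " config=", config_hash(config)))
  paths$de <- character(0)
  for (d in config$doses) {
    p <- file.path(dir, sprintf("de_dose%g.tsv", d))
    write_de_table(simulate_de_table(sim, d), p)
    paths$de <- c(paths$de, p)
  }
  curves <- simulate_melt_replicates(config)
  paths$melts <- character(0)
  for (i in seq_along(curves)) {
    p <- file.path(dir, "melts", sprintf("rep%d.csv", i))
    write_melt_csv(curves[[i]], p)
    paths$melts <- c(paths$melts, p)
  }
  top_kd <- config$kmax * hill_fraction(config, max(config$doses))
  qpcr <- simulate_qpcr_plate(config, knockdown = top_kd)
  utils::write.csv(qpcr, file.path(dir, "qpcr.csv"),
                   row.names = FALSE, quote = FALSE)
  paths$qpcr <- file.path(dir, "qpcr.csv")
  rep_plate <- simulate_reporter_plate(config)
  utils::write.csv(rep_plate, file.path(dir, "reporter.csv"),
                   row.names = FALSE, quote = FALSE)
  paths$reporter <- file.path(dir, "reporter.csv")
  cfg <- data.frame(key = c("seed", "n_transcripts", "sigma", "doses",
                            "beta", "p_plant", "ec50", "hill", "kmax"),
                    value = c(config$seed, config$n_transcripts, config$sigma,
                              paste(config$doses, collapse = ","),
                              paste(config$beta, collapse = ","),
                              paste(config$p_plant, collapse = ","),
                              config$ec50, config$hill, config$kmax),
                    stringsAsFactors = FALSE)
  write_commented_tsv(cfg, file.path(dir, "config.tsv"),
                      comment = paste0("config=", config_hash(config)))
  paths$config <- file.path(dir, "config.tsv")
  sim$paths <- paths
  invisible(sim)
}
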