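test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 21L, n_transcripts = 60L)
  a <- generate_utr_set(cfg, "UGUCGAU")
  b <- generate_utr_set(cfg, "UGUCGAU")
  expect_identical(a$utrs, b$utrs)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_utr_fasta(a$utrs, f1); write_utr_fasta(b$utrs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_plant = c(mer8 = 0.5, mer7m8 = 0.4, mer7A1 = 0.3)))
  expect_error(sim_config(sigma = 0))
  expect_error(sim_config(doses = c(0, 1)))
  expect_error(sim_config(kmax = 1.2))
})

test_that("planting intent is recorded and found on re-scan", {
  sim <- small_sim
  n <- sim$config$n_transcripts
  ## planted counts are a recorded Binomial(n, 0.1) draw per class:
  ## check they sit inside wide (4-sigma) binomial bounds
  rank <- function(cl) match(cl, site_class_levels())
  for (cl in c("mer8", "mer7m8", "mer7A1")) {
    k <- sum(sim$truth$planted_class[seq_len(n)] == cl)
    expect_lt(abs(k - n * 0.1), 4 * sqrt(n * 0.1 * 0.9))
    ## planting is always detected, possibly upgraded to a stronger
    ## class when a chance flanking base completes the longer site
    rows <- sim$truth[sim$truth$planted_class == cl, ]
    expect_true(all(rank(rows$strongest_class) <= rank(cl)), info = cl)
  }
  ## the on-target transcript carries the mer8 site
  ot <- sim$truth[sim$truth$transcript_id == "on_target", ]
  expect_gte(ot$n_mer8, 1L)
})

test_that("null DE tables are centred and dosed tables follow the Hill law", {
  cfg0 <- sim_config(seed = 3L, n_transcripts = 1000L,
                     beta = c(mer8 = 0, mer7m8 = 0, mer7A1 = 0))
  sim0 <- generate_utr_set(cfg0, "UGUCGAU")
  de0 <- simulate_de_table(sim0, 10)
  body <- de0$log2fc[de0$gene_id != "on_target"]
  expect_lt(abs(mean(body)), 3 * cfg0$sigma / sqrt(length(body)))

  ## saturating dose: foreground mean approaches -beta
  cfg1 <- sim_config(seed = 3L, n_transcripts = 2000L,
                     beta = c(mer8 = 1, mer7m8 = 0, mer7A1 = 0),
                     sigma = 0.2, doses = c(1000))
  sim1 <- generate_utr_set(cfg1, "UGUCGAU")
  de1 <- simulate_de_table(sim1, 1000)
  fg <- de1$log2fc[sim1$truth$strongest_class == "mer8" &
                     de1$gene_id != "on_target"]
  expect_gt(length(fg), 150)
  expect_lt(abs(mean(fg) + 1.0 * hill_fraction(cfg1, 1000)), 0.05)

  ## Hill midpoint: dose = EC50 gives half-maximal knockdown in truth
  cfg2 <- sim_config(seed = 4L, n_transcripts = 50L, doses = c(1), ec50 = 1,
                     kmax = 0.9)
  sim2 <- generate_utr_set(cfg2, "UGUCGAU")
  mu_ot <- sim2$truth$mu_1[sim2$truth$transcript_id == "on_target"]
  expect_equal(1 - 2^mu_ot, 0.45, tolerance = 1e-12)

  expect_error(simulate_de_table(sim2, 99), "unknown dose")
})

test_that("simulated qPCR plates recover the planted knockdown", {
  cfg <- sim_config(seed = 8L)
  plate <- simulate_qpcr_plate(cfg, knockdown = 0.87, n_per_group = 4L)
  r <- ddct_relative_expression(plate, control_group = "control")
  trt <- unname(attr(r, "group_means")["treated"])
  expect_equal(trt, 0.13, tolerance = 0.35)  # Ct noise of 0.15 cycles
  expect_equal(as.numeric(percent_silencing(trt)), 87, tolerance = 0.06)
})

test_that("zero-noise plates are exact", {
  cfg <- sim_config(seed = 8L, reporter_cv = 0, qpcr_ct_sd = 1e-12)
  plate <- simulate_reporter_plate(cfg, knockdown = 0.5)
  out <- luciferase_normalize(plate)
  expect_equal(unique(round(out$activity[out$condition == "treated"], 12)),
               0.5)
  q <- simulate_qpcr_plate(cfg, knockdown = 0.87)
  r <- ddct_relative_expression(q, control_group = "control")
  expect_equal(unname(attr(r, "group_means")["treated"]), 0.13,
               tolerance = 1e-6)
})

test_that("noiseless simulated melts match the direct curve fit", {
  cfg <- sim_config(seed = 2L, melt_noise_sd = 0)
  reps <- simulate_melt_replicates(cfg, n_replicates = 2L)
  direct <- tm_from_curve(simulate_melt_curve(cfg$melt))$tm
  expect_equal(tm_replicates(reps)$tm, direct, tolerance = 1e-9)
})

test_that("simulate_study writes a complete, rereadable bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 12L, n_transcripts = 40L)
  sim <- simulate_study(cfg, "UGUCGAU", dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  utrs <- read_utr_fasta(sim$paths$utrs)
  expect_equal(utrs$id, sim$utrs$id)
  de <- read_de_table(sim$paths$de[[3]])
  expect_equal(nrow(de), 41L)
  expect_length(read_melt_csv(sim$paths$melts[[1]]), 1L)
  ## provenance header on the truth table
  expect_match(readLines(sim$paths$truth, n = 1L), "^# seed=12")
})
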