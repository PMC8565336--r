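test_that("expression filter keeps rows at or above the threshold", {
  de <- data.frame(gene_id = paste0("g", 1:5), base_mean = c(1, 5, 10, 50, 100),
                   log2fc = 0, padj = 1)
  expect_message(out <- expression_filter(de, 0), "kept 5 of 5")
  expect_equal(out, de)
  suppressMessages(expect_warning(out2 <- expression_filter(de, 1000),
                                  "every gene"))
  expect_equal(nrow(out2), 0L)
  suppressMessages(expect_equal(nrow(expression_filter(de, 10)), 3L))
})

test_that("signed delta obeys its defining identities", {
  expect_equal(cdf_shift(c(1, 2, 2, 3), c(1, 2, 2, 3))$delta, 0)
  expect_equal(cdf_shift(c(-1, -1, -1), c(0, 0, 0))$delta, 1)
  expect_equal(cdf_shift(c(0, 0, 0), c(-1, -1, -1))$delta, -1)
  expect_error(cdf_shift(numeric(0), 1), "non-empty")
  expect_error(cdf_shift(c(1, NA), c(0, 0)), "non-finite")

  set.seed(31)
  for (i in 1:20) {
    fg <- rnorm(40, -0.3); bg <- rnorm(60)
    d <- cdf_shift(fg, bg)$delta
    expect_gte(d, -1); expect_lte(d, 1)
    ## swapping foreground and background negates the signed delta
    expect_equal(cdf_shift(bg, fg)$delta, -d)
    ## invariance under a strictly increasing transform
    expect_equal(cdf_shift(exp(fg), exp(bg))$delta, d)
    ## |delta| is the KS D statistic
    expect_equal(abs(d),
                 unname(suppressWarnings(ks.test(fg, bg)$statistic)))
  }
})

test_that("KS p-value equals exhaustive permutation enumeration when small", {
  set.seed(77)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    x <- rnorm(n1); y <- rnorm(n2)
    s <- cdf_shift(x, y)
    expect_equal(s$ks_p, perm_ks_p(x, y), tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("stratified shifts split by strongest class against background", {
  de <- data.frame(gene_id = paste0("g", 1:6), base_mean = 10,
                   log2fc = rnorm(6), padj = 1,
                   strongest_class = "none")
  out <- stratified_shifts(de)
  expect_s3_class(out, "seed_shift_table")
  expect_equal(out$flag, rep("not computable", 3))
  expect_true(all(is.na(out$delta)))

  de$strongest_class <- c("mer8", "mer8", "none", "none", "none", "none")
  out2 <- stratified_shifts(de, min_n = 10)
  expect_equal(out2$n_fg[out2$class == "mer8"], 2L)
  expect_equal(out2$flag[out2$class == "mer8"], "low n")

  de$strongest_class <- "mer8"
  expect_error(stratified_shifts(de), "no background")
})

test_that("repression only on mer8 yields the largest mer8 delta", {
  cfg <- sim_config(seed = 11L, n_transcripts = 2000L,
                    beta = c(mer8 = 0.5, mer7m8 = 0, mer7A1 = 0))
  sim <- generate_utr_set(cfg, "UGUCGAU")
  de <- simulate_de_table(sim, 50)
  de$strongest_class <- sim$truth$strongest_class
  de <- de[de$gene_id != cfg$on_target_id, ]
  out <- stratified_shifts(de)
  d <- setNames(out$delta, out$class)
  expect_gt(d[["mer8"]], d[["mer7m8"]])
  expect_gt(d[["mer8"]], d[["mer7A1"]])
})

test_that("BH adjustment acts across the three classes only on request", {
  de <- data.frame(log2fc = c(rnorm(50, -1), rnorm(30, -0.2), rnorm(200)),
                   strongest_class = c(rep("mer8", 50), rep("mer7m8", 30),
                                       rep("none", 200)))
  raw <- stratified_shifts(de)
  adj <- stratified_shifts(de, p_adjust = "BH")
  ok <- !is.na(raw$ks_p)
  expect_equal(adj$ks_p[ok], p.adjust(raw$ks_p, "BH")[ok])
})

test_that("dose profile handles single doses and mismatched dose sets", {
  single <- shift_dose_profile(data.frame(dose = 1, delta = 0.2),
                               data.frame(dose = 1, knockdown = 0.5))
  expect_true(is.na(single$spearman_rho))
  expect_equal(nrow(single$points), 1L)
  expect_error(
    shift_dose_profile(data.frame(dose = c(1, 10), delta = 0),
                       data.frame(dose = c(1, 50), knockdown = 0)),
    "dose sets differ")
  ## points come back sorted by dose with the correlation over all doses
  prof <- shift_dose_profile(
    data.frame(dose = c(10, 0.1, 1), delta = c(0.5, 0.05, 0.3)),
    data.frame(dose = c(0.1, 1, 10), knockdown = c(0.1, 0.5, 0.9)))
  expect_equal(prof$points$dose, c(0.1, 1, 10))
  expect_equal(prof$spearman_rho, 1)
})
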