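test_that("two-state equilibrium honours the closed-form midpoint", {
  p <- melt_params(dH = -300, tm = 65, CT = 1e-6)
  expect_equal(two_state_tm(p), 65, tolerance = 1e-9)
  expect_equal(melt_fraction_ss(p, 65), 0.5, tolerance = 1e-6)
  ## doubling the strand concentration moves the midpoint per the
  ## closed form Tm = dH / (dS + R log(CT/4))
  p2 <- melt_params(dH = -300, dS = p$dS, CT = 2e-6)
  shift_pred <- two_state_tm(p2) - two_state_tm(p)
  expect_gt(shift_pred, 0)
  expect_equal(melt_fraction_ss(p2, two_state_tm(p2)), 0.5, tolerance = 1e-6)
  ## self-complementary variant has its own midpoint convention
  psc <- melt_params(dH = -300, tm = 65, CT = 1e-6, self_complementary = TRUE)
  expect_equal(melt_fraction_ss(psc, two_state_tm(psc)), 0.5, tolerance = 1e-6)
})

test_that("flat equal baselines give a constant curve", {
  p <- melt_params(lower_intercept = 0.7, lower_slope = 0,
                   upper_intercept = 0.7, upper_slope = 0)
  cv <- simulate_melt_curve(p)
  expect_true(all(abs(cv$absorbance - 0.7) < 1e-12))
})

test_that("smoothing contracts: identity, constants, noise reduction", {
  cv <- simulate_melt_curve(melt_params())
  expect_equal(smooth_curve(cv, window = 1L), cv)
  const <- melt_curve(1:20, rep(2, 20))
  expect_equal(smooth_curve(const, 11L)$absorbance, rep(2, 20))
  expect_error(smooth_curve(cv, window = 10L), "odd")
  expect_error(smooth_curve(melt_curve(1:11, 1:11), window = 13L), "longer")
  ## white noise on a sigmoid: smoothing must reduce the residual sd
  set.seed(5)
  noisy <- melt_curve(cv$temperature,
                      cv$absorbance + rnorm(length(cv$temperature), 0, 0.003))
  sm <- smooth_curve(noisy, window = 11L)
  expect_lt(sd(sm$absorbance - cv$absorbance),
            sd(noisy$absorbance - cv$absorbance))
})

test_that("a symmetric logistic melts at its midpoint", {
  tg <- seq(40, 90, by = 0.1)
  cv <- melt_curve(tg, 1 / (1 + exp(-(tg - 65) / 2)))
  fit <- tm_from_curve(cv)
  expect_equal(fit$tm, 65, tolerance = 0.05)
})

test_that("the estimator recovers the true derivative maximum", {
  p <- melt_params()
  cv <- simulate_melt_curve(p, temperature = seq(15, 90, by = 0.5))
  fit <- tm_from_curve(cv)
  ## oracle: argmax of dA/dT on the exact model, fine grid + optimize
  model_a <- function(tc)
    (p$lower_intercept + p$lower_slope * tc) +
      melt_fraction_ss(p, tc) *
        ((p$upper_intercept + p$upper_slope * tc) -
           (p$lower_intercept + p$lower_slope * tc))
  f <- function(tc) {
    eps <- 1e-4
    (model_a(tc + eps) - model_a(tc - eps)) / (2 * eps)
  }
  grid <- seq(60, 72, by = 0.05)
  coarse <- grid[which.max(vapply(grid, f, numeric(1)))]
  true_tmax <- stats::optimize(f, c(coarse - 0.1, coarse + 0.1),
                               maximum = TRUE)$maximum
  expect_equal(fit$tm, true_tmax, tolerance = 0.05)
})

test_that("Tm is invariant under affine transforms and shared baselines", {
  cv <- simulate_melt_curve(melt_params())
  tm0 <- tm_from_curve(cv)$tm
  aff <- melt_curve(cv$temperature, 3.2 * cv$absorbance + 10)
  expect_equal(tm_from_curve(aff)$tm, tm0, tolerance = 1e-6)
  ## a linear baseline added to the whole trace shifts dA/dT by a
  ## constant and leaves the maximum where it was
  based <- melt_curve(cv$temperature,
                      cv$absorbance + 0.05 + 4e-4 * cv$temperature)
  expect_equal(tm_from_curve(based)$tm, tm0, tolerance = 1e-6)
})

test_that("uncaptured transitions and derivative ties are handled", {
  tg <- seq(15, 90, by = 0.5)
  rising <- melt_curve(tg, 1 / (1 + exp(-(tg - 14) / 2)))
  expect_error(tm_from_curve(rising), "transition not captured")
  ## two ramps of identical slope: tie resolves to the lower temperature
  tg2 <- 1:30
  a <- pmin(pmax(tg2 - 5, 0), 3) + pmin(pmax(tg2 - 20, 0), 3)
  cv2 <- melt_curve(tg2, a)
  expect_message(fit <- tm_from_curve(cv2, window = 1L), "lower temperature")
  expect_lt(fit$tm, 10)
})

test_that("replicate averaging equals the single-curve value on copies", {
  cv <- simulate_melt_curve(melt_params())
  single <- tm_from_curve(cv)$tm
  reps <- tm_replicates(list(cv, cv))
  expect_equal(reps$tm, single)
  expect_equal(reps$replicates, c(single, single))
})

test_that("noisy replicates stay close to the noiseless estimate", {
  p <- melt_params()
  clean <- tm_from_curve(simulate_melt_curve(p))$tm
  cfg <- sim_config(seed = 1L)
  tms <- vapply(1:50, function(i) {
    cv <- simulate_melt_replicates(cfg, n_replicates = 1L, params = p,
                                   seed = 1000L + i)[[1L]]
    tm_from_curve(cv)$tm
  }, numeric(1))
  expect_lt(abs(mean(tms) - clean), 0.1)
  expect_lt(sd(tms), 0.5)
})

test_that("fixture Tm values reproduce the printed delta columns", {
  tab <- delta_tm_table(fixture_tm)
  d <- setNames(tab$delta_tm_r, tab$duplex_id)
  expect_equal(unname(d[c("D2", "D3", "D5", "D6", "D8", "D9", "D11", "D12")]),
               c(-7.9, -5.4, -7.0, -3.7, -8.0, -6.0, -6.0, -2.7))
  dd <- setNames(tab$ddelta_tm_r, tab$duplex_id)
  expect_equal(unname(dd[c("D3", "D6", "D9", "D12")]),
               c(+2.5, +3.3, +2.0, +3.3))
  expect_true(all(is.na(tab$delta_tm[tab$duplex_id %in%
                                       c("D1", "D4", "D7", "D10")])))
  ## ddelta(iso) - 0 = delta(iso) - delta(native), exactly
  for (pair in list(c("D3", "D2"), c("D6", "D5"),
                    c("D9", "D8"), c("D12", "D11")))
    expect_equal(dd[[pair[1]]],
                 round(d[[pair[1]]] - d[[pair[2]]], 1))
})

test_that("delta table errors and edge cases", {
  expect_error(
    delta_tm_table(data.frame(duplex_id = "X", tm_c = 60,
                              parent_id = "missing")),
    "missing parent Tm for duplex X")
  same <- delta_tm_table(data.frame(duplex_id = c("P", "M"),
                                    tm_c = c(60, 60),
                                    parent_id = c(NA, "P")))
  expect_equal(same$delta_tm[same$duplex_id == "M"], 0)
  solo <- delta_tm_table(data.frame(duplex_id = "P", tm_c = 60,
                                    parent_id = NA))
  expect_true(is.na(solo$delta_tm))
})
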