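test_that("rolling deviation is exact on simple profiles", {
  expect_true(all(rolling_deviation(rep(340, 10))$dev == 0))
  expect_equal(rolling_deviation(c(1, 2, 3))$dev, 0)  # linear ramp
  d <- 340; delta <- 20
  p <- rep(c(d + delta, d - delta), 10)
  dev <- rolling_deviation(p)$dev
  expect_equal(abs(dev), rep(4 * delta / 3, 18))
  expect_error(rolling_deviation(c(1, 2)), "at least 3")
})

test_that("deviations are invariant to offsets and linear trends", {
  set.seed(1)
  w <- rnorm(100, 340, 30)
  d0 <- rolling_deviation(w)$dev
  expect_equal(rolling_deviation(w + 123)$dev, d0)
  expect_equal(rolling_deviation(w + 0.7 * seq_along(w))$dev, d0)
})

test_that("iid thicknesses give the analytic -2/3 deviation correlation", {
  set.seed(2)
  ac <- adjacent_correlation(rolling_deviation(rnorm(1e5, 340, 50)))
  expect_lt(abs(ac$r - (-2 / 3)), 0.01)
  expect_equal(ac$r2, ac$r^2)
  expect_lt(ac$p, 1e-20)
})

test_that("estimator bias at n = 1000 is small (Monte Carlo)", {
  set.seed(3)
  rs <- vapply(1:40, function(i) {
    adjacent_correlation(rolling_deviation(rnorm(1000, 340, 50)))$r
  }, 0)
  expect_lt(abs(mean(rs) - (-2 / 3)), 0.01)
})

test_that("strictly alternating profiles give r = -1", {
  ac <- adjacent_correlation(rolling_deviation(rep(c(360, 320), 30)))
  expect_equal(ac$r, -1)
})

test_that("degenerate and short inputs error clearly", {
  expect_error(adjacent_correlation(rolling_deviation(rep(340, 50))),
               "degenerate")
  expect_error(adjacent_correlation(rolling_deviation(rnorm(8))),
               "at least 10")
})

test_that("flagged layers create gaps with no spanning pairs", {
  set.seed(4)
  w <- rnorm(50, 340, 30)
  fl <- rep("ok", 50); fl[25] <- "merged_excluded"
  dv <- rolling_deviation(thickness_profile(w, fl))
  expect_true(all(is.na(dv$dev[dv$layer %in% 24:26])))
  expect_false(anyNA(dv$dev[dv$layer %in% c(20, 30)]))
})

test_that("bias-aware lag-1 autocorrelation is near zero for iid input", {
  set.seed(5)
  l1 <- lag1_autocorrelation(thickness_profile(rnorm(2e4, 340, 50)))
  expect_lt(abs(l1$r), 0.06)
})

test_that("measured deviation correlation is monotone in phi", {
  set.seed(6)
  mean_r <- vapply(c(-0.6, -0.3, 0), function(phi) {
    mean(vapply(1:20, function(i) {
      p <- make_thickness_profile(growth_spec(
        1000, 340, sigma_local = 30, phi = phi, sigma_env = 0,
        seed = sample.int(1e6, 1)))
      adjacent_correlation(rolling_deviation(p))$r
    }, 0))
  }, 0)
  expect_true(all(diff(mean_r) > 0))
})

test_that("stage statistics recover the preset parameters", {
  pe <- make_thickness_profile(preset_growth("early", n_layers = 2e4,
                                             seed = 7))
  pm <- make_thickness_profile(preset_growth("mature", n_layers = 2e4,
                                             seed = 8))
  st <- stage_statistics(
    thickness_profile(c(pe$thickness, pm$thickness)),
    windows = list(c(1, 2e4), c(2e4 + 1, 4e4)),
    labels = c("early", "mature"))
  expect_lt(abs(st$stages$mean[1] / 500 - 1), 0.03)
  expect_lt(abs(st$stages$sd[1] / 300 - 1), 0.05)
  expect_lt(abs(st$stages$mean[2] / 340 - 1), 0.03)
  expect_lt(abs(st$stages$sd[2] / 120 - 1), 0.05)
  # maturation: ~30% thinner, ~40% less variance
  expect_lt(abs(st$mean_ratio - 0.68), 0.05)
  expect_lt(abs(st$variance_ratio - 0.16), 0.05)
})

test_that("stage statistics handle constant profiles and bad windows", {
  p <- thickness_profile(rep(340, 100))
  st <- stage_statistics(p, list(c(1, 100)))
  expect_equal(st$stages$sd, 0)
  expect_error(stage_statistics(p, list(c(1, 200))), "outside")
})

test_that("growth rate reproduces the layers-per-lifetime arithmetic", {
  gr <- growth_rate(2615, 548, mean_thickness_nm = 340)
  expect_equal(gr$tablets_per_day, 2615 / 548)
  expect_true(gr$tablets_per_day > 4 && gr$tablets_per_day < 5)
  expect_true(gr$microns_per_day > 1.4 && gr$microns_per_day < 1.7)
  expect_equal(growth_rate(0, 100)$tablets_per_day, 0)
  expect_error(growth_rate(100, 0), "days")
})
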