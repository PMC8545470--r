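test_that("perfect lattice concentrates all pair mass on lattice bins", {
  pos <- (0:100) * 340
  pc <- pair_correlation(pos, bw = 10, x_max = 3000)
  hot <- floor((340 * (1:8)) / 10) + 1
  expect_true(all(pc$g[-hot][pc$x[-hot] > 5] == 0))
  expect_true(all(pc$g[hot] > 0))
})

test_that("histogram normalization identity holds exactly", {
  set.seed(1)
  w <- pmax(rnorm(2000, 340, 30), 50)
  pc <- pair_correlation(c(0, cumsum(w)))
  expect_equal(sum(pc$g) * pc$bw * pc$k, pc$n_pairs)
})

test_that("uniformly random positions give a flat correlogram", {
  set.seed(2)
  pos <- sort(runif(3000, 0, 1e5))
  pc <- pair_correlation(pos, bw = 1.5, x_max = 900)
  sel <- pc$x > 50  # skip the self-exclusion region near zero
  expect_lt(sd(pc$g[sel]) / mean(pc$g[sel]), 0.2)
})

test_that("g is translation invariant and scales with units", {
  set.seed(3)
  w <- pmax(rnorm(500, 340, 30), 50)
  pos <- c(0, cumsum(w))
  pc1 <- pair_correlation(pos, bw = 17, x_max = 3400)
  pc2 <- pair_correlation(pos + 12345, bw = 17, x_max = 3400)
  expect_equal(pc1$g, pc2$g)
  pc3 <- pair_correlation(pos / 1000, bw = 0.017, x_max = 3.4)
  expect_equal(pc3$g, pc1$g * 1000, tolerance = 1e-12)
})

test_that("bin widths that cannot resolve the spacing are rejected", {
  pos <- (0:50) * 340
  expect_error(pair_correlation(pos, bw = 400), "resolve")
})

test_that("n-th neighbor spacing SD follows sigma1 sqrt(n) (data oracle)", {
  set.seed(4)
  w <- pmax(rnorm(1e4, 340, 30), 50)
  pos <- c(0, cumsum(w))
  for (n in c(1, 2, 4, 9)) {
    s_n <- sd(pos[-seq_len(n)] - pos[seq_len(length(pos) - n)])
    expect_lt(abs(s_n / (30 * sqrt(n)) - 1), 0.05)
  }
})

test_that("fitted peak widths recover the paracrystal broadening law", {
  set.seed(5)
  w <- pmax(rnorm(1e5, 340, 30), 50)
  pc <- pair_correlation(c(0, cumsum(w)), bw = 340 / 40)
  pf <- fit_peaks(pc, n_max = 9)
  expect_true(pf$converged)
  expect_lt(abs(pf$peaks$sigma[4] / pf$peaks$sigma[1] - 2), 0.1)
  bc <- broadening_curve(pf)
  expect_lt(abs(bc$beta - 0.5), 0.05)
  expect_equal(bc$classification, "ideal-paracrystal")
  # correlation length against the first-harmonic envelope oracle:
  # exp(-2 pi^2 sigma1^2 (n-1)/d^2) < 0.1 at n = 16 for sigma1/d = 0.088
  cl <- correlation_length(pc)
  expect_true(abs(cl$layers - 16) <= 2)
  expect_equal(cl$nm, cl$layers * pc$mean_spacing)
})

test_that("perfect lattice peaks sit at the resolution floor", {
  pos <- (0:2000) * 340
  pc <- pair_correlation(pos, bw = 17)
  pf <- fit_peaks(pc, n_max = 6)
  expect_true(all(pf$peaks$sigma < 2 * pc$bw))
  bc <- broadening_curve(pf)
  expect_equal(bc$classification, "crystal-like")
  cl <- correlation_length(pc)
  expect_true(cl$censored)
})

test_that("anticorrective stacking broadens slower than sqrt(n)", {
  set.seed(6)
  eps <- rnorm(3e4, sd = 30)
  car <- as.numeric(stats::filter(eps, -0.6, method = "recursive"))
  w <- pmax(340 + car, 50)
  pc <- pair_correlation(c(0, cumsum(w)), bw = 340 / 40)
  pf <- fit_peaks(pc, n_max = 9)
  expect_lt(broadening_curve(pf)$beta, 0.45)
})

test_that("flagged layers break the profile into independent segments", {
  w <- rep(340, 30)
  fl <- rep("ok", 30); fl[15] <- "merged_excluded"
  p <- thickness_profile(w, fl)
  pc <- pair_correlation(p, bw = 17, x_max = 3400)
  # no pair spans the flagged layer: max separation within a segment is 14*340
  expect_equal(max(pc$x[pc$g > 0]), 14 * 340 + pc$bw / 2, tolerance = 20)
})
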