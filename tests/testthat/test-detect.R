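test_that("minima prominence matches a brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    x <- cumsum(rnorm(200))
    mins <- nacremeso:::local_minima_idx(x)
    if (!length(mins)) next
    expect_equal(nacremeso:::minima_prominence(x, mins),
                 brute_minima_prominence(x, mins))
  }
})

test_that("vertical transect through horizontal layers equals the column", {
  s <- flat_sample(n_layers = 15, width = 32, noise_sd = 0.02, seed = 2)
  H <- nrow(s$image)
  tr <- extract_transect(s$image, 3, line = c(10, 1, 10, H))
  expect_equal(tr$intensity, s$image[, 10])
  expect_equal(tr$position_nm, (seq_len(H) - 1) * 3)
})

test_that("positions scale with pixel size; intensities do not", {
  s <- flat_sample(n_layers = 10, width = 16, seed = 3)
  H <- nrow(s$image)
  t1 <- extract_transect(s$image, 3, line = c(5, 1, 5, H))
  t2 <- extract_transect(s$image, 6, line = c(5, 1, 5, H))
  expect_equal(t2$position_nm, 2 * t1$position_nm)
  expect_equal(t2$intensity, t1$intensity)
})

test_that("degenerate transect lines and NaN intensities are rejected", {
  s <- flat_sample(n_layers = 10, width = 16, seed = 3)
  expect_error(extract_transect(s$image, 3, line = c(5, 5, 5, 5)),
               "degenerate")
  tr <- column_transect(s$image, 4)
  tr$intensity[10] <- NA
  expect_error(detect_sheaths(tr), "NA")
})

test_that("flat and pure-noise transects yield empty interface sets", {
  flat <- structure(list(position_nm = (0:499) * 3,
                         intensity = rep(0.7, 500)), class = "transect")
  expect_equal(nrow(detect_sheaths(flat)), 0)
  set.seed(1)
  noisy <- structure(list(position_nm = (0:499) * 3,
                          intensity = 0.7 + rnorm(500, sd = 0.02)),
                     class = "transect")
  expect_equal(nrow(detect_sheaths(noisy, min_prominence = 0.3)), 0)
})

test_that("detection is invariant to affine intensity transforms", {
  s <- flat_sample(n_layers = 20, thick_sd = 50, noise_sd = 0.03,
                   blur_sd = 2, seed = 4)
  tr <- column_transect(s$image, 8)
  i1 <- detect_sheaths(tr, min_prominence = 0.1)
  tr2 <- tr
  tr2$intensity <- 0.5 * tr$intensity + 0.2
  i2 <- detect_sheaths(tr2, min_prominence = 0.05)
  expect_equal(i2$position, i1$position)
})

test_that("thickness differencing follows the interface-position arithmetic", {
  expect_equal(thickness_from_interfaces(c(0, 340, 680))$thickness,
               c(340, 340))
  expect_equal(thickness_from_interfaces(c(0, 200, 700))$thickness,
               c(200, 500))
  expect_error(thickness_from_interfaces(c(100)), "insufficient")
})

test_that("detected thickness on noisy renders matches ground truth", {
  prof <- make_thickness_profile(preset_growth("mature", n_layers = 400,
                                               seed = 5))
  s <- render_transect(prof, render_spec(), seed = 6)
  th <- thickness_from_interfaces(detect_sheaths(s$transect))
  expect_equal(nrow(th), 400)
  expect_lt(abs(mean(th$thickness) / mean(prof$thickness) - 1), 0.02)
})

test_that("merged-layer flagging: uniform profiles get no flags", {
  p <- thickness_profile(rep(340, 50))
  expect_true(all(flag_merged_layers(p)$flag == "ok"))
})

test_that("a deleted interface is flagged exactly once", {
  set.seed(7)
  w <- rnorm(120, 340, 34)
  pos <- c(0, cumsum(w))
  pos <- pos[-60]  # delete one interior interface -> one doubled layer
  p <- thickness_from_interfaces(pos)
  fl <- flag_merged_layers(p)
  expect_equal(sum(fl$flag == "merged_excluded"), 1)
  expect_equal(which(fl$flag == "merged_excluded"), 59)
})

test_that("false-flag rate on clean moderate-dispersion data is below 0.5%", {
  set.seed(8)
  p <- thickness_profile(rnorm(5000, 340, 34))
  fl <- flag_merged_layers(p)
  expect_lt(mean(fl$flag != "ok"), 0.005)
})

test_that("auto-perpendicular transects are rotation invariant", {
  prof <- make_thickness_profile(preset_growth("mature", n_layers = 30,
                                               seed = 8))
  rs <- render_spec(orientation_halfwidth = 0, image_width = 400,
                    noise_sd = 0.03)
  f <- make_interface_field(prof, rs, seed = 1)
  s <- render_micrograph(f, seed = 2)
  th0 <- thickness_from_interfaces(detect_sheaths(extract_transect(s$image,
                                                                   3)))
  rot <- EBImage::rotate(EBImage::Image(t(s$image)), 30,
                         filter = "bilinear", bg.col = 0.8)
  img_r <- t(as.matrix(rot))
  tr1 <- extract_transect(img_r, 3)
  th1 <- thickness_from_interfaces(detect_sheaths(tr1))
  expect_equal(nrow(th1), nrow(th0))
  expect_lt(abs(mean(th1$thickness) / mean(th0$thickness) - 1), 0.01)
})

test_that("recall is monotone in noise and high at moderate noise", {
  prof <- make_thickness_profile(preset_growth("mature", n_layers = 300,
                                               seed = 5))
  recalls <- vapply(c(0.03, 0.09, 0.15), function(ns) {
    s <- render_transect(prof, render_spec(noise_sd = ns), seed = 7)
    match_interfaces(detect_sheaths(s$transect), s$truth_interfaces,
                     tol_nm = 25)$recall
  }, 0)
  expect_true(all(diff(recalls) <= 1e-9))
  expect_gte(recalls[2], 0.99)  # noise at 15% of contrast
})

test_that("thickness map is constant on flat noise-free samples", {
  s <- flat_sample(n_layers = 20, width = 128, seed = 9)
  tm <- build_thickness_map(s$image, 3, n_transects = 8)
  expect_equal(tm$unmatched_fraction, 0)
  expect_true(all(abs(tm$thickness - 340) < 3, na.rm = TRUE))
})

test_that("thickness map shows a localized thin band at a dislocation", {
  p <- make_thickness_profile(growth_spec(40, 340, sigma_local = 0,
                                          sigma_env = 0, seed = 1))
  rs <- render_spec(orientation_halfwidth = 0, image_width = 512)
  f <- make_interface_field(p, rs, seed = 1)
  area_m2 <- (512 * 3e-9) *
    ((max(f$y[nrow(f$y), ]) - min(f$y[1, ])) * 1e-9)
  f2 <- insert_dislocations(f, density = 1 / area_m2,
                            thinning_fraction = 0.28,
                            decay_length = 300, seed = 3)
  s <- render_micrograph(f2, seed = 4)
  tm <- build_thickness_map(s$image, 3, n_transects = 24)
  expect_lt(min(tm$thickness, na.rm = TRUE),
            0.75 * mean(tm$thickness, na.rm = TRUE))
})

test_that("map cell-wise mean agrees with the transect-profile mean", {
  s <- simulate_nacre("mature", n_layers = 60, seed = 11)
  tm <- build_thickness_map(s$image, 3, n_transects = 12)
  tr <- column_transect(s$image, ncol(s$image) %/% 2)
  th <- thickness_from_interfaces(detect_sheaths(tr))
  expect_lt(abs(mean(tm$thickness, na.rm = TRUE) /
                  mean(th$thickness) - 1), 0.01)
})
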