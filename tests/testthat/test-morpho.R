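test_that("defect density is the exact count/area with Poisson SE", {
  dm <- defect_centers(1e-3, 1e-3, density = 5.9e8, mode = "exact",
                      seed = 1)
  dd <- defect_density(dm)
  expect_equal(dd$count[dd$view == "all"], 590)
  expect_equal(dd$density_m2[dd$view == "all"], 5.9e8)
  dm2 <- defect_centers(1e-3, 1e-3, density = 5.3e8, mode = "exact",
                       seed = 2)
  dd2 <- defect_density(dm2)
  expect_equal(dd2$poisson_se_m2[1], sqrt(530) / 1e-6)
})

test_that("empty fields have zero density and zero area errors", {
  dm <- defect_map(numeric(0), numeric(0), character(0), 1e-3, 1e-3)
  expect_equal(defect_density(dm)$density_m2, 0)
  expect_error(defect_map(0.5e-3, 0.5e-3, "plan", 0, 1e-3), "width_m")
})

test_that("density is linear in count and inverse-linear in area", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(10:500, 1)
    wds <- runif(1, 1e-4, 1e-3)
    hts <- runif(1, 1e-4, 1e-3)
    dm <- defect_map(runif(n, 0, wds), runif(n, 0, hts),
                     rep("plan", n), wds, hts)
    dd <- defect_density(dm)
    expect_equal(dd$density_m2[dd$view == "all"], n / (wds * hts))
  }
})

test_that("centers outside the field are rejected", {
  expect_error(defect_map(2e-3, 0.5e-3, "plan", 1e-3, 1e-3), "outside")
})

test_that("per-view densities are reported separately", {
  dm <- defect_map(c(1e-4, 2e-4, 3e-4), c(1e-4, 2e-4, 3e-4),
                   c("plan", "plan", "cross-section"), 1e-3, 1e-3)
  dd <- defect_density(dm)
  expect_equal(dd$count[dd$view == "plan"], 2)
  expect_equal(dd$count[dd$view == "cross-section"], 1)
})

test_that("flat layers measure at the angular resolution floor", {
  av <- simulate_angular_views("mature", seed = 5, n_tiles = 2,
                               orientation_halfwidth = 0)
  a <- angular_spread(av$images, av$pixel_size, d_mean = av$d_mean_nm)
  expect_lt(a$half_width_deg, 1)
  expect_lt(abs(a$peak_azimuth_deg - 90), 1)
})

test_that("angular spread is invariant under image rotation", {
  # uniformly tilted stack: rotating the image moves the peak, not the width
  prof <- make_thickness_profile(growth_spec(120, 340, sigma_local = 0,
                                             sigma_env = 0, seed = 1))
  rs <- render_spec(pixel_size = 24, blur_sd = 1, noise_sd = 0.02,
                    orientation_halfwidth = 0, image_width = 1400)
  f <- make_interface_field(prof, rs, seed = 1)
  slope <- tan(10 * pi / 180)
  f$y <- f$y + matrix(rep(f$x_nm * slope, each = nrow(f$y)), nrow = nrow(f$y))
  h_px <- floor((min(f$y[nrow(f$y), ]) - max(f$y[1, ]) - 400) / 24)
  s <- render_micrograph(f, seed = 2, y_offset_nm = max(f$y[1, ]) + 200,
                         height_px = h_px)
  a0 <- angular_spread(s$image, 24, d_mean = 340)
  rot <- EBImage::rotate(EBImage::Image(t(s$image)), -20,
                         filter = "bilinear", output.dim = dim(t(s$image)),
                         bg.col = 0.8)
  a1 <- angular_spread(t(as.matrix(rot)), 24, d_mean = 340)
  expect_lt(abs(a1$half_width_deg - a0$half_width_deg), 0.5)
  expect_lt(abs(abs(a1$peak_azimuth_deg - a0$peak_azimuth_deg) - 20), 1.5)
})

test_that("mean spacing can be estimated from the radial power peak", {
  av <- simulate_angular_views("mature", seed = 7, n_tiles = 2,
                               orientation_halfwidth = 2)
  a <- angular_spread(av$images[[1]], av$pixel_size)  # d_mean = NULL
  expect_lt(abs(a$d_mean / av$d_mean_nm - 1), 0.25)
  expect_lt(abs(a$peak_azimuth_deg - 90), 5)
})
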