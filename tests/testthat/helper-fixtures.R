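# shared fixtures and independent oracles

# brute-force prominence of minima: walk outward until strictly higher
# ground (on the inverted signal) or the signal edge
brute_minima_prominence <- function(x, mins) {
  y <- -x
  vapply(mins, function(p) {
    h <- y[p]
    lmin <- h
    i <- p
    while (i > 1) {
      i <- i - 1
      if (y[i] > h) break
      lmin <- min(lmin, y[i])
    }
    rmin <- h
    i <- p
    while (i < length(y)) {
      i <- i + 1
      if (y[i] > h) break
      rmin <- min(rmin, y[i])
    }
    h - max(lmin, rmin)
  }, 0)
}

# small noise-free flat-layer sample for detection tests
flat_sample <- function(n_layers = 30, width = 64, noise_sd = 0,
                        blur_sd = 0, seed = 1, thick_sd = 0) {
  prof <- make_thickness_profile(growth_spec(
    n_layers, 340, sigma_local = thick_sd, phi = 0, sigma_env = 0,
    seed = seed))
  rs <- render_spec(orientation_halfwidth = 0, image_width = width,
                    noise_sd = noise_sd, blur_sd = blur_sd)
  field <- make_interface_field(prof, rs, seed = seed)
  render_micrograph(field, seed = seed + 1)
}

column_transect <- function(image, col, pixel_size = 3) {
  structure(list(position_nm = (seq_len(nrow(image)) - 1) * pixel_size,
                 intensity = image[, col],
                 direction_deg = 90, source = "column"),
            class = "transect")
}
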